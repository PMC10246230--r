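#' Survival evaluation of risk scores and groups
#'
#' Kaplan-Meier curves per risk group, multi-group log-rank test, per-group
#' hazard ratios relative to the lowest group, concordance index of the
#' continuous score, an optional covariate-adjusted Cox model, and a
#' Schoenfeld-residual proportional-hazards check. Groups with no members are
#' omitted with a warning; a single non-empty group is an error (log-rank
#' undefined).
#'
#' @param scores continuous risk scores.
#' @param groups risk-group factor.
#' @param time,event outcome.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list of class \code{"hips_eval"}: \code{km} (survfit),
#'   \code{logrank_chisq, logrank_df, logrank_p}, \code{group_hr} (data.frame),
#'   \code{cindex}, \code{adjusted} (coxph or NULL), \code{ph_check}
#'   (cox.zph or NULL).
#' @export
evaluate_risk_groups <- function(scores, groups, time, event,
                                 covariates = NULL) {
  groups <- droplevels(factor(groups))
  empty <- setdiff(levels(factor(groups)), unique(as.character(groups)))
  if (length(empty) > 0) warning("empty groups omitted: ",
                                 paste(empty, collapse = ", "))
  if (nlevels(groups) < 2) stop("log-rank undefined with a single group")
  y <- survival::Surv(time, event)
  km <- survival::survfit(y ~ groups)
  sd0 <- survival::survdiff(y ~ groups)
  lr_df <- length(sd0$n) - 1
  lr_p <- stats::pchisq(sd0$chisq, lr_df, lower.tail = FALSE)
  cox_g <- survival::coxph(y ~ groups, ties = "breslow")
  cg <- summary(cox_g)$coefficients
  group_hr <- data.frame(group = sub("^groups", "", rownames(cg)),
                         hr = exp(cg[, "coef"]),
                         lo = exp(cg[, "coef"] - 1.96 * cg[, "se(coef)"]),
                         hi = exp(cg[, "coef"] + 1.96 * cg[, "se(coef)"]),
                         p = cg[, "Pr(>|z|)"], row.names = NULL)
  cindex <- tryCatch(
    survival::concordance(y ~ scores, reverse = TRUE)$concordance,
    error = function(e) NA_real_)
  adjusted <- NULL; ph <- NULL
  if (!is.null(covariates)) {
    df <- data.frame(time = time, event = event, score = scores,
                     covariates, check.names = TRUE)
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ score +",
      paste(setdiff(names(df), c("time", "event", "score")),
            collapse = " + ")))
    adjusted <- survival::coxph(fml, data = df, ties = "breslow")
  }
  fit_for_ph <- if (!is.null(adjusted)) adjusted else cox_g
  ph <- tryCatch(survival::cox.zph(fit_for_ph), error = function(e) NULL)
  structure(list(km = km, logrank_chisq = sd0$chisq, logrank_df = lr_df,
                 logrank_p = lr_p, group_hr = group_hr, cindex = cindex,
                 adjusted = adjusted, ph_check = ph,
                 groups = groups),
            class = "hips_eval")
}

#' @export
print.hips_eval <- function(x, ...) {
  cat("Risk-group survival evaluation\n")
  cat(sprintf("  log-rank: chisq = %.2f on %d df, p = %.3g\n",
              x$logrank_chisq, x$logrank_df, x$logrank_p))
  cat("  hazard ratios vs lowest group:\n")
  for (i in seq_len(nrow(x$group_hr)))
    cat(sprintf("    %s: HR = %.2f [%.2f, %.2f], p = %.3g\n",
                x$group_hr$group[i], x$group_hr$hr[i], x$group_hr$lo[i],
                x$group_hr$hi[i], x$group_hr$p[i]))
  cat(sprintf("  concordance index of the continuous score: %.3f\n",
              x$cindex))
  if (!is.null(x$ph_check))
    cat(sprintf("  PH check (global Schoenfeld p): %.3g\n",
                x$ph_check$table["GLOBAL", "p"]))
  invisible(x)
}

#' @export
plot.hips_eval <- function(x, col = c("#2c7fb8", "#feb24c", "#de2d26"),
                           ...) {
  graphics::plot(x$km, col = col[seq_len(nlevels(x$groups))], lwd = 2,
                 xlab = "Years", ylab = "Survival", ...)
  graphics::legend("bottomleft", legend = levels(x$groups),
                   col = col[seq_len(nlevels(x$groups))], lwd = 2, bty = "n")
  invisible(x)
}
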