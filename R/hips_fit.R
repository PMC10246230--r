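#' Univariable Cox screening of histomic features
#'
#' One-covariate Cox proportional hazards fit per feature (partial likelihood,
#' Breslow tie handling) on z-scored features. Non-converging or constant
#' features are flagged and excluded from later selection.
#'
#' @param X data.frame/matrix of (z-scored) features.
#' @param time,event survival outcome (years, 0/1).
#' @return data.frame: \code{feature, loghr, se, p, flagged}.
#' @export
univariable_screen <- function(X, time, event) {
  X <- as.data.frame(X)
  res <- lapply(names(X), function(f) {
    v <- X[[f]]
    ok <- is.finite(v) & is.finite(time)
    if (sum(ok) < 10 || stats::sd(v[ok]) == 0 || sum(event[ok]) < 2)
      return(data.frame(feature = f, loghr = NA_real_, se = NA_real_,
                        p = NA_real_, flagged = TRUE))
    fit <- tryCatch(
      survival::coxph(survival::Surv(time[ok], event[ok]) ~ v[ok],
                      ties = "breslow"),
      error = function(e) NULL, warning = function(w) {
        tryCatch(suppressWarnings(
          survival::coxph(survival::Surv(time[ok], event[ok]) ~ v[ok],
                          ties = "breslow")), error = function(e) NULL)
      })
    if (is.null(fit) || !is.finite(stats::coef(fit)[1]) ||
        abs(stats::coef(fit)[1]) > 20)
      return(data.frame(feature = f, loghr = NA_real_, se = NA_real_,
                        p = NA_real_, flagged = TRUE))
    s <- summary(fit)
    data.frame(feature = f, loghr = unname(stats::coef(fit)[1]),
               se = s$coefficients[1, "se(coef)"],
               p = s$coefficients[1, "Pr(>|z|)"], flagged = FALSE)
  })
  do.call(rbind, res)
}

#' Select the most prognostic feature per subtheme
#'
#' Within each of the 26 subthemes, the feature with the smallest univariable
#' Wald p is admitted; ties break to the larger |log HR|, then lexicographic
#' name. A subtheme whose features are all flagged is dropped with a warning.
#'
#' @param screen output of \code{\link{univariable_screen}}.
#' @param manifest the feature manifest.
#' @return character vector of selected feature names (one per surviving
#'   subtheme).
#' @export
select_per_subtheme <- function(screen, manifest = hips_manifest()) {
  sel <- character(0)
  for (st in unique(manifest$subtheme)) {
    cand <- merge(screen, manifest[manifest$subtheme == st, c("name", "subtheme")],
                  by.x = "feature", by.y = "name")
    cand <- cand[!cand$flagged & is.finite(cand$p), , drop = FALSE]
    if (nrow(cand) == 0) {
      warning("subtheme ", st, " has no usable feature; dropped")
      next
    }
    ord <- order(cand$p, -abs(cand$loghr), cand$feature)
    sel <- c(sel, cand$feature[ord[1]])
  }
  sel
}

#' Elastic-net Cox fit over a hyperparameter grid
#'
#' Penalized Cox partial-likelihood maximization via glmnet. The grid crosses
#' penalty strengths (glmnet lambda) with L1 ratios (glmnet alpha); the pair
#' maximizing the mean cross-validated concordance is chosen and the final
#' model is refit on all data at that choice.
#'
#' @param X numeric matrix of model inputs (z-scored or binary).
#' @param time,event outcome.
#' @param cv_folds folds for cross-validation.
#' @param lambda_grid penalty strengths (10 log-spaced over 1e-4..10).
#' @param l1_grid L1 mixing ratios.
#' @param seed fold-assignment seed.
#' @return list: \code{beta} (named), \code{cv_choice} (alpha = penalty,
#'   l1_ratio), \code{cv_cindex} (grid of mean CV concordance).
#' @export
fit_elasticnet_cox <- function(X, time, event, cv_folds = 5,
                               lambda_grid = 10^seq(-4, 1, length.out = 10),
                               l1_grid = c(0.1, 0.5, 0.9), seed = 1) {
  X <- as.matrix(X)
  if (sum(event) == 0) stop("all observations censored")
  y <- survival::Surv(time, event)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  # glmnet needs at least two lambdas on its path
  lambda_cv <- if (length(lambda_grid) == 1)
    c(lambda_grid * 1.0001, lambda_grid) else lambda_grid
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
  cvc <- matrix(NA_real_, length(lambda_grid), length(l1_grid),
                dimnames = list(sprintf("%.3g", lambda_grid),
                                sprintf("%.2g", l1_grid)))
  for (j in seq_along(l1_grid)) {
    cv <- tryCatch(
      glmnet::cv.glmnet(X, y, family = "cox", alpha = l1_grid[j],
                        lambda = lambda_cv, foldid = folds,
                        type.measure = "C", standardize = FALSE),
      error = function(e) NULL)
    if (is.null(cv)) next
    idx <- match(signif(cv$lambda, 6), signif(lambda_grid, 6))
    cvc[idx[!is.na(idx)], j] <- cv$cvm[!is.na(idx)]
  }
  if (all(!is.finite(cvc))) stop("cross-validation failed on the whole grid")
  best <- which(cvc == max(cvc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  lam <- lambda_grid[best[1]]; l1 <- l1_grid[best[2]]
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = l1,
                        lambda = lambda_cv, standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lam))
  names(beta) <- colnames(X)
  list(beta = beta, cv_choice = c(alpha = lam, l1_ratio = l1),
       cv_cindex = cvc)
}

# ---- Gaussian mixture thresholds -------------------------------------------

#' Crossing point of two weighted Gaussian densities
#'
#' Solves w1 N(x; m1, s1) = w2 N(x; m2, s2) in closed form (quadratic in x)
#' and returns the root lying between the two means; if no root falls in that
#' interval, the midpoint of the means is returned.
#'
#' @param w1,m1,s1,w2,m2,s2 weights, means, sds of the two components
#'   (m1 < m2 expected).
#' @return scalar crossing point.
#' @export
gaussian_crossing <- function(w1, m1, s1, w2, m2, s2) {
  lo <- min(m1, m2); hi <- max(m1, m2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return((lo + hi) / 2)
    x <- -cc / b
    return(if (x > lo && x < hi) x else (lo + hi) / 2)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return((lo + hi) / 2)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > lo & roots < hi]
  if (length(inside) == 0) return((lo + hi) / 2)
  inside[1]
}

#' Data-driven risk-group thresholds from a 3-Gaussian mixture
#'
#' Models the training score distribution as a mixture of three Gaussians
#' (low-, intermediate-, high-risk populations) fitted by EM, sorts components
#' by mean, and takes the crossing points of the weighted component densities
#' (between consecutive means) as the two group cut-offs. A degenerate fit
#' (tiny component weight, or no spread in the scores) falls back to tertile
#' cuts with a warning.
#'
#' @param scores numeric training scores.
#' @param seed RNG seed for the EM initialization.
#' @return c(t1, t2), attributes \code{"components"} (data.frame weight/mean/
#'   sd) and \code{"fallback"}.
#' @export
fit_gmm_thresholds <- function(scores, seed = 1) {
  scores <- scores[is.finite(scores)]
  fallback <- function(msg) {
    warning("Gaussian mixture degenerate (", msg, "); using tertile cuts")
    q <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
    structure(c(t1 = q[1], t2 = q[2]), fallback = TRUE)
  }
  if (length(unique(scores)) < 5 || stats::sd(scores) < 1e-8)
    return(fallback("no spread"))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller env
  fit <- with_seed(seed, tryCatch(
    suppressWarnings(mclust::Mclust(scores, G = 3, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL))
  if (is.null(fit)) return(fallback("EM failure"))
  w <- fit$parameters$pro
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 3)
  if (any(w < 1e-3) || any(!is.finite(sg)) || any(sg < 1e-8))
    return(fallback("component collapse"))
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sg <- sg[ord]
  t1 <- gaussian_crossing(w[1], mu[1], sg[1], w[2], mu[2], sg[2])
  t2 <- gaussian_crossing(w[2], mu[2], sg[2], w[3], mu[3], sg[3])
  structure(c(t1 = unname(t1), t2 = unname(t2)),
            components = data.frame(weight = w, mean = mu, sd = sg),
            fallback = FALSE)
}

#' Released HiPS grouping thresholds
#'
#' The published cut-offs: scores below 3.6 are H1, scores of 6 or more are
#' H3.
#' @export
hips_released_thresholds <- function() c(t1 = 3.6, t2 = 6.0)

#' Assign risk groups from scores and thresholds
#'
#' Intervals are [0, t1) -> group 1, [t1, t2) -> group 2, [t2, 10] -> group 3
#' (boundaries inclusive upward).
#'
#' @param score numeric scores.
#' @param thresholds c(t1, t2).
#' @param prefix group label prefix ("H" for HiPS, "C" for the control model).
#' @return factor with levels prefix1..prefix3.
#' @export
assign_group <- function(score, thresholds = hips_released_thresholds(),
                         prefix = "H") {
  g <- ifelse(score < thresholds[1], 1L, ifelse(score < thresholds[2], 2L, 3L))
  factor(paste0(prefix, g), levels = paste0(prefix, 1:3))
}

# ---- the HiPS fit -----------------------------------------------------------

ihc_inputs <- function(clinical) {
  er <- clinical$er; pr <- clinical$pr; her2 <- clinical$her2
  tnbc <- if ("tnbc" %in% names(clinical)) clinical$tnbc else
    ifelse(is.na(er) | is.na(pr) | is.na(her2), NA_integer_,
           as.integer(er == 0 & pr == 0 & her2 == 0))
  cbind(ER = er, PR = pr, HER2 = her2, TNBC = tnbc)
}

#' Fit the Histomic Prognostic Signature
#'
#' The central model fit: z-scores the feature matrix against itself (storing
#' the reference statistics), imputes missing cells by 10-nearest-neighbor
#' reference imputation, screens all manifest features by univariable Cox
#' regression, admits the most prognostic feature per subtheme (26 with the
#' full manifest), adds the four IHC panel inputs (ER, PR, HER2, TNBC; 30
#' inputs in total), fits an elastic-net Cox model with cross-validated
#' hyperparameters, scales the training log partial hazard affinely to
#' [0, 10], and derives three risk groups from the crossings of a 3-component
#' Gaussian mixture over the training scores. Thematic subscores partition
#' the score over six groups (the five feature themes plus IHC) and sum
#' exactly to it.
#'
#' @param features data.frame from \code{\link{run_extract}} (patient_id +
#'   feature columns).
#' @param clinical data.frame with \code{patient_id, time, event, er, pr,
#'   her2} (and optionally \code{tnbc}).
#' @param manifest the feature manifest.
#' @param themes optional subset of themes to use (e.g. "epithelial" for the
#'   epithelial-only variant).
#' @param cv_folds,lambda_grid,l1_grid,seed passed to
#'   \code{\link{fit_elasticnet_cox}}.
#' @param knn_k neighbors for imputation.
#' @return object of class \code{"hips"}: selected features, reference
#'   z-statistics, Cox weights, score scaler, thresholds, theme partition,
#'   training scores/groups.
#' @export
hips <- function(features, clinical, manifest = hips_manifest(),
                 themes = NULL, cv_folds = 5,
                 lambda_grid = 10^seq(-4, 1, length.out = 10),
                 l1_grid = c(0.1, 0.5, 0.9), knn_k = 10, seed = 1) {
  stopifnot("patient_id" %in% names(features))
  if (!is.null(themes))
    manifest <- manifest[manifest$theme %in% themes, , drop = FALSE]
  idx <- match(clinical$patient_id, features$patient_id)
  if (anyNA(idx)) stop("clinical patients missing from the feature table")
  X0 <- features[idx, intersect(manifest$name, names(features)),
                 drop = FALSE]
  zs <- suppressWarnings(zscore_features(X0))
  Xz <- knn_impute(zs$X, k = knn_k)
  scr <- univariable_screen(Xz, clinical$time, clinical$event)
  selected <- select_per_subtheme(scr, manifest[manifest$name %in% names(Xz), ])
  ihc <- ihc_inputs(clinical)
  X <- cbind(as.matrix(Xz[, selected, drop = FALSE]), ihc)
  en <- fit_elasticnet_cox(X, clinical$time, clinical$event,
                           cv_folds = cv_folds, lambda_grid = lambda_grid,
                           l1_grid = l1_grid, seed = seed)
  eta <- drop(X %*% en$beta)
  rng <- range(eta)
  a <- if (diff(rng) > 0) 10 / diff(rng) else 0
  b <- -a * rng[1]
  score <- a * eta + b
  thr <- suppressWarnings(fit_gmm_thresholds(score, seed = seed))
  theme_of <- stats::setNames(manifest$theme, manifest$name)
  partition <- ifelse(colnames(X) %in% c("ER", "PR", "HER2", "TNBC"),
                      "ihc", theme_of[colnames(X)])
  obj <- structure(list(
    selected_features = selected,
    beta = en$beta, cv_choice = en$cv_choice, cv_cindex = en$cv_cindex,
    scaler = c(a = a, b = b),
    thresholds = thr,
    theme_partition = stats::setNames(partition, colnames(X)),
    reference_stats = zs$stats,
    reference_matrix = Xz,
    manifest = manifest, knn_k = knn_k, seed = seed,
    screen = scr,
    train = data.frame(patient_id = clinical$patient_id,
                       eta = eta, score = score,
                       group = assign_group(score, thr),
                       stringsAsFactors = FALSE),
    outcome = clinical[, c("patient_id", "time", "event")]
  ), class = "hips")
  obj$train_subscores <- subscores(obj, X)
  obj
}

# model matrix for new data (z-score by reference, impute, select, bind IHC)
hips_model_matrix <- function(object, features, clinical) {
  idx <- match(clinical$patient_id, features$patient_id)
  if (anyNA(idx)) stop("patients missing from the feature table")
  cols <- names(object$reference_stats$mu)
  cols <- intersect(cols, names(features))
  X0 <- features[idx, cols, drop = FALSE]
  zs <- suppressWarnings(zscore_features(X0, object$reference_stats))
  Xz <- knn_impute(zs$X, reference = object$reference_matrix[, names(zs$X)],
                   k = object$knn_k)
  miss <- setdiff(object$selected_features, names(Xz))
  if (length(miss) > 0)
    stop("model inputs missing after imputation: ",
         paste(miss, collapse = ", "))
  cbind(as.matrix(Xz[, object$selected_features, drop = FALSE]),
        ihc_inputs(clinical))
}

#' Thematic subscores
#'
#' Decomposes the (unclamped) score \code{a * eta + b} over the six theme
#' groups: subscore_g = a * sum_{j in g} beta_j x_j + b/6, so the six
#' subscores sum exactly to the score.
#'
#' @param object a fitted \code{hips} model.
#' @param X model input matrix (columns = model inputs).
#' @return matrix n x 6 with theme columns (epithelial, stromal, tils,
#'   necrosis, interactions, ihc; absent themes contribute only b/6).
#' @export
subscores <- function(object, X) {
  groups <- c("epithelial", "stromal", "tils", "necrosis", "interactions",
              "ihc")
  a <- object$scaler[["a"]]; b <- object$scaler[["b"]]
  out <- matrix(b / 6, nrow(X), length(groups),
                dimnames = list(rownames(X), groups))
  for (g in groups) {
    j <- names(object$theme_partition)[object$theme_partition == g]
    j <- intersect(j, colnames(X))
    if (length(j) > 0)
      out[, g] <- out[, g] +
        a * drop(X[, j, drop = FALSE] %*% object$beta[j])
  }
  out
}

#' @export
predict.hips <- function(object, features, clinical,
                         type = c("score", "group", "lp", "subscores"),
                         thresholds = NULL, ...) {
  type <- match.arg(type)
  X <- hips_model_matrix(object, features, clinical)
  eta <- drop(X %*% object$beta)
  if (type == "lp") return(eta)
  score_raw <- object$scaler[["a"]] * eta + object$scaler[["b"]]
  score <- pmin(pmax(score_raw, 0), 10)
  if (type == "score") return(score)
  if (type == "subscores") return(subscores(object, X))
  if (is.null(thresholds)) thresholds <- object$thresholds
  assign_group(score, thresholds)
}

#' @export
coef.hips <- function(object, ...) object$beta

#' @export
print.hips <- function(x, ...) {
  cat("Histomic Prognostic Signature (elastic-net Cox)\n")
  cat(sprintf("  inputs: %d (%d histomic + %d IHC)\n", length(x$beta),
              length(x$selected_features),
              length(x$beta) - length(x$selected_features)))
  cat(sprintf("  cv choice: penalty %.4g, L1 ratio %.2g\n",
              x$cv_choice[["alpha"]], x$cv_choice[["l1_ratio"]]))
  cat(sprintf("  score range [0, 10]; thresholds t1 = %.2f, t2 = %.2f%s\n",
              x$thresholds[["t1"]], x$thresholds[["t2"]],
              if (isTRUE(attr(x$thresholds, "fallback"))) " (tertile fallback)"
              else ""))
  cat("  training groups:",
      paste(sprintf("%s=%d", levels(x$train$group), table(x$train$group)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.hips <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  cat("Histomic Prognostic Signature\n\n")
  cat("Nonzero coefficients (log hazard per z-unit):\n")
  print(round(sort(nz, decreasing = TRUE), 4))
  cat(sprintf("\nSelected %d subtheme features + %d IHC inputs; %d nonzero.\n",
              length(object$selected_features),
              length(object$beta) - length(object$selected_features),
              length(nz)))
  cat(sprintf("Thresholds: t1 = %.2f, t2 = %.2f\n",
              object$thresholds[["t1"]], object$thresholds[["t2"]]))
  invisible(object)
}

#' @export
plot.hips <- function(x, breaks = 40, ...) {
  s <- x$train$score
  graphics::hist(s, breaks = breaks, freq = FALSE, col = "grey85",
                 border = "white", xlab = "HiPS score",
                 main = "Training score distribution")
  comp <- attr(x$thresholds, "components")
  if (!is.null(comp)) {
    xx <- seq(0, 10, length.out = 400)
    for (i in seq_len(nrow(comp)))
      graphics::lines(xx, comp$weight[i] *
                        stats::dnorm(xx, comp$mean[i], comp$sd[i]),
                      col = c("#2c7fb8", "#feb24c", "#de2d26")[i], lwd = 2)
  }
  graphics::abline(v = x$thresholds, lty = 2)
  invisible(x)
}

#' Fit the Nottingham + IHC control model
#'
#' The benchmark scoring pipeline fitted to grade (ordinal 1-3) and the IHC
#' panel (ER, PR, HER2, TNBC) with the same elastic-net Cox and 0-10 scaling
#' machinery. Because grade is discrete the score histogram is discrete, so
#' instead of mixture thresholds the score range is divided into three equal
#' intervals (cuts 10/3 and 20/3) to define groups C1-C3.
#'
#' @param clinical data.frame with \code{time, event, grade, er, pr, her2}.
#' @inheritParams hips
#' @return object of class \code{"hips_control"}.
#' @export
fit_control_model <- function(clinical, cv_folds = 5,
                              lambda_grid = 10^seq(-4, 1, length.out = 10),
                              l1_grid = c(0.1, 0.5, 0.9), seed = 1) {
  stopifnot(all(clinical$grade %in% 1:3))
  X <- cbind(Grade = as.numeric(clinical$grade), ihc_inputs(clinical))
  en <- fit_elasticnet_cox(X, clinical$time, clinical$event,
                           cv_folds = cv_folds, lambda_grid = lambda_grid,
                           l1_grid = l1_grid, seed = seed)
  eta <- drop(X %*% en$beta)
  rng <- range(eta)
  a <- if (diff(rng) > 0) 10 / diff(rng) else 0
  b <- -a * rng[1]
  score <- a * eta + b
  thr <- c(t1 = 10 / 3, t2 = 20 / 3)
  structure(list(beta = en$beta, cv_choice = en$cv_choice,
                 scaler = c(a = a, b = b), thresholds = thr,
                 train = data.frame(patient_id = clinical$patient_id,
                                    score = score,
                                    group = assign_group(score, thr, "C"))),
            class = "hips_control")
}

#' @export
predict.hips_control <- function(object, clinical,
                                 type = c("score", "group"), ...) {
  type <- match.arg(type)
  X <- cbind(Grade = as.numeric(clinical$grade), ihc_inputs(clinical))
  score <- pmin(pmax(object$scaler[["a"]] * drop(X %*% object$beta) +
                       object$scaler[["b"]], 0), 10)
  if (type == "score") score else assign_group(score, object$thresholds, "C")
}

#' @export
print.hips_control <- function(x, ...) {
  cat("Control model (Nottingham grade + IHC panel)\n")
  cat("  beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                       collapse = " "), "\n")
  cat("  equal-interval cuts at 10/3 and 20/3\n")
  invisible(x)
}

#' Fit the epithelial-only HiPS variant
#'
#' Identical pipeline restricted to epithelial-theme subthemes plus the four
#' IHC inputs; used to quantify the added value of stromal/immune/interaction
#' features.
#'
#' @inheritParams hips
#' @return a \code{"hips"} object whose selected features all carry the
#'   epithelial theme.
#' @export
fit_epithelial_variant <- function(features, clinical,
                                   manifest = hips_manifest(), ...) {
  hips(features, clinical, manifest = manifest, themes = "epithelial", ...)
}
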