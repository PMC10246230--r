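test_that("univariable screening is calibrated and recovers effects", {
  withr::local_seed(6)
  n <- 400
  # 120 pure-noise features against one outcome: Wald p-values ~ uniform
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
  X <- as.data.frame(matrix(rnorm(n * 120), n))
  scr <- univariable_screen(X, time, event)
  expect_gt(ks.test(scr$p, "punif")$p.value, 0.01)
  # a feature with true log HR 0.5 at n = 1000 is recovered within 0.15
  n2 <- 1000
  z <- rnorm(n2)
  t2 <- rexp(n2, 0.1 * exp(0.5 * z))
  cens <- rexp(n2, 0.04)
  scr2 <- univariable_screen(data.frame(z = z), pmin(t2, cens),
                             as.integer(t2 <= cens))
  expect_lt(abs(scr2$loghr - 0.5), 0.15)
  # a constant feature is flagged
  scr3 <- univariable_screen(data.frame(k = rep(1, n)), time, event)
  expect_true(scr3$flagged)
})

test_that("per-subtheme selection picks the smallest p with stated ties", {
  man <- data.frame(name = c("A", "B", "C", "D"),
                    theme = "epithelial",
                    subtheme = c("s1", "s1", "s2", "s2"),
                    aggregation = "wsi-direct", quoted = FALSE)
  scr <- data.frame(feature = c("A", "B", "C", "D"),
                    loghr = c(0.4, 0.2, 0.4, 0.2),
                    se = 0.1, p = c(0.01, 0.2, 0.05, 0.05),
                    flagged = FALSE)
  expect_setequal(select_per_subtheme(scr, man), c("A", "C"))
  # exact p tie -> larger |logHR| wins
  scr$p <- c(0.05, 0.05, 0.05, 0.05)
  expect_true("A" %in% select_per_subtheme(scr, man))
  # all-flagged subtheme dropped with a warning
  scr$flagged <- c(TRUE, TRUE, FALSE, FALSE)
  expect_warning(sel <- select_per_subtheme(scr, man), "s1")
  expect_equal(sel, "C")
})

test_that("elastic-net Cox honors penalty limits and recovers signals", {
  withr::local_seed(7)
  n <- 2000
  X <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("f", 1:30)))
  beta_true <- c(rep(0.6, 3), rep(-0.5, 2), rep(0, 25))
  t_ev <- rexp(n, 0.1 * exp(drop(X %*% beta_true)))
  cens <- rexp(n, 0.03)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  # a huge penalty shrinks everything to zero
  f0 <- fit_elasticnet_cox(X, time, event, lambda_grid = c(1000), seed = 1)
  expect_true(all(f0$beta == 0))
  # lasso with a strong penalty is sparse but non-degenerate
  fl <- fit_elasticnet_cox(X, time, event, lambda_grid = c(0.05),
                           l1_grid = 1, seed = 1)
  expect_gt(sum(fl$beta == 0), 5)
  expect_gt(sum(fl$beta != 0), 0)
  # cross-validated fit ranks >= 4 of the 5 true inputs above all nulls
  fit <- fit_elasticnet_cox(X, time, event, seed = 1)
  ab <- abs(fit$beta)
  expect_gte(sum(ab[1:5] > max(ab[6:30])), 4)
})

test_that("Gaussian crossings match a numeric root finder", {
  cases <- list(c(0.3, 2, 0.6, 0.4, 5, 0.9),
                c(0.5, 1, 0.5, 0.5, 4, 0.5),
                c(0.2, 3, 0.4, 0.6, 6, 1.2))
  for (cs in cases) {
    cf <- gaussian_crossing(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    f <- function(x) cs[1] * dnorm(x, cs[2], cs[3]) -
      cs[4] * dnorm(x, cs[5], cs[6])
    nr <- uniroot(f, c(cs[2] + 1e-9, cs[5] - 1e-9), tol = 1e-12)$root
    expect_equal(cf, nr, tolerance = 1e-6)
  }
  # equal-weight equal-sd components cross at the midpoint
  expect_equal(gaussian_crossing(0.5, 2, 0.5, 0.5, 5, 0.5), 3.5)
})

test_that("mixture thresholds are recovered for separated populations", {
  withr::local_seed(8)
  sc <- c(rnorm(1000, 2, 0.5), rnorm(1000, 5, 0.5), rnorm(1000, 8, 0.5))
  th <- fit_gmm_thresholds(sc, seed = 1)
  # equal-weight equal-sd components cross midway: 3.5 and 6.5
  expect_lt(abs(th[["t1"]] - 3.5), 0.2)
  expect_lt(abs(th[["t2"]] - 6.5), 0.2)
  expect_false(attr(th, "fallback"))
  expect_equal(nrow(attr(th, "components")), 3)
  # identical scores trigger the tertile fallback
  expect_warning(thf <- fit_gmm_thresholds(rep(5, 200)), "degenerate")
  expect_true(attr(thf, "fallback"))
})

test_that("group assignment uses the released boundary conventions", {
  thr <- hips_released_thresholds()
  expect_equal(thr, c(t1 = 3.6, t2 = 6.0))
  expect_equal(as.character(assign_group(3.5, thr)), "H1")
  expect_equal(as.character(assign_group(6.0, thr)), "H3")
  expect_equal(as.character(assign_group(3.6, thr)), "H2")  # inclusive upward
  expect_equal(as.character(assign_group(9.9, thr)), "H3")
})

test_that("the fitted signature has 30 inputs, a [0,10] score and subscores
          that sum to it", {
  co <- make_feature_cohort(n = 160, seed = 10,
                            signal = c(GlobalCAFDensity = 0.7,
                                       CFOD = 0.5,
                                       GlobalTILsDensity = -0.4))
  fit <- hips(co$features, co$clinical, seed = 1)
  expect_length(fit$selected_features, 26)
  expect_length(fit$beta, 30)
  expect_setequal(names(fit$beta)[27:30], c("ER", "PR", "HER2", "TNBC"))
  # training scores span exactly [0, 10]
  expect_equal(min(fit$train$score), 0, tolerance = 1e-9)
  expect_equal(max(fit$train$score), 10, tolerance = 1e-9)
  # subscores: six per patient, summing to the score
  ss <- fit$train_subscores
  expect_equal(ncol(ss), 6)
  expect_equal(unname(rowSums(ss)), fit$train$score, tolerance = 1e-9)
  # zero input vector decomposes into six equal intercept shares
  X0 <- matrix(0, 1, 30, dimnames = list(NULL, names(fit$beta)))
  s0 <- subscores(fit, X0)
  expect_equal(unname(s0[1, ]), rep(fit$scaler[["b"]] / 6, 6))
  # zeroing one theme's inputs changes only that subscore
  Xr <- matrix(rnorm(30), 1, dimnames = list(NULL, names(fit$beta)))
  Xz <- Xr; Xz[, names(fit$theme_partition)[
    fit$theme_partition == "ihc"]] <- 0
  d <- subscores(fit, Xr) - subscores(fit, Xz)
  expect_true(all(abs(d[1, setdiff(colnames(d), "ihc")]) < 1e-12))
  # prediction on shifted data is clamped to [0, 10]
  shifted <- co$features
  shifted$GlobalCAFDensity <- shifted$GlobalCAFDensity + 50
  ps <- predict(fit, shifted, co$clinical)
  expect_true(all(ps >= 0 & ps <= 10))
  # determinism: refitting with the same seed reproduces the model
  fit2 <- hips(co$features, co$clinical, seed = 1)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$thresholds, fit2$thresholds)
})

test_that("the control model uses equal-interval groups and tracks grade", {
  withr::local_seed(11)
  n <- 500
  grade <- sample(1:3, n, replace = TRUE)
  er <- rbinom(n, 1, 0.8); pr <- rbinom(n, 1, 0.7)
  her2 <- rbinom(n, 1, 0.15)
  t_ev <- rexp(n, 0.05 * exp(0.6 * (grade - 2)))
  cens <- rexp(n, 0.02)
  clin <- data.frame(patient_id = paste0("p", 1:n),
                     time = pmin(t_ev, cens),
                     event = as.integer(t_ev <= cens),
                     er = er, pr = pr, her2 = her2,
                     tnbc = as.integer(er == 0 & pr == 0 & her2 == 0),
                     grade = grade)
  ctrl <- fit_control_model(clin, seed = 1)
  expect_equal(unname(ctrl$thresholds), c(10 / 3, 20 / 3))
  expect_equal(as.character(assign_group(3.0, ctrl$thresholds, "C")), "C1")
  expect_equal(as.character(assign_group(10, ctrl$thresholds, "C")), "C3")
  # with a grade-driven hazard the fitted grade weight is positive and the
  # score is monotone in grade at fixed IHC
  expect_gte(ctrl$beta[["Grade"]], 0)
  newc <- data.frame(patient_id = c("a", "b", "c"), grade = 1:3,
                     er = 1, pr = 1, her2 = 0, tnbc = 0)
  sc <- predict(ctrl, newc)
  expect_true(all(diff(sc) >= 0))
})

test_that("the epithelial-only variant restricts its features by theme", {
  co <- make_feature_cohort(n = 140, seed = 12,
                            signal = c(ChromatinClumpingOfEpithNuclei = 0.8))
  fit <- fit_epithelial_variant(co$features, co$clinical, seed = 1)
  man <- hips_manifest()
  themes <- man$theme[match(fit$selected_features, man$name)]
  expect_true(all(themes == "epithelial"))
  expect_setequal(names(fit$beta)[-seq_along(fit$selected_features)],
                  c("ER", "PR", "HER2", "TNBC"))
})

test_that("survival evaluation recovers hazard ratios and rejects degenerate
          groupings", {
  withr::local_seed(13)
  n <- 1000
  g <- factor(sample(c("H1", "H2"), n, replace = TRUE))
  t_ev <- rexp(n, 0.08 * ifelse(g == "H2", 2, 1))
  cens <- rexp(n, 0.03)
  ev <- evaluate_risk_groups(as.numeric(g), g, pmin(t_ev, cens),
                             as.integer(t_ev <= cens))
  hr <- ev$group_hr$hr[ev$group_hr$group == "H2"]
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
  expect_lt(ev$logrank_p, 0.001)
  expect_gt(ev$cindex, 0.5)
  # a single group has no log-rank statistic
  expect_error(evaluate_risk_groups(rep(1, 10), factor(rep("H1", 10)),
                                    rexp(10), rep(1, 10)), "single group")
  # shuffled groups are not significant most of the time
  ps <- vapply(1:20, function(i) {
    gs <- sample(g)
    evaluate_risk_groups(as.numeric(gs), gs, pmin(t_ev, cens),
                         as.integer(t_ev <= cens))$logrank_p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.3)
})
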