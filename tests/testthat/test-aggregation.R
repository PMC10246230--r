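test_that("the feature manifest has the published structure", {
  m <- hips_manifest()
  expect_equal(nrow(m), 109)
  expect_equal(length(unique(m$subtheme)), 26)
  expect_setequal(unique(m$theme),
                  c("epithelial", "stromal", "tils", "necrosis",
                    "interactions"))
  expect_equal(anyDuplicated(m$name), 0)
  expect_true(all(table(m$subtheme) >= 1))
  # every feature named in the source catalogue is present
  for (nm in c("LocalTILsDensity32uM", "TILsDensityWithin32uMOfEpithCell",
               "CAFDensityAtEpithNestMargin", "NoOfLowGradeNucleiPerEpithNest",
               "PeriCAFMatrixHeteroIn512uMROI",
               "ChromatinClumpingOfEpithNuclei", "CFOD"))
    expect_true(nm %in% m$name, info = nm)
  # each feature sits in exactly one subtheme, each subtheme in one theme
  expect_equal(nrow(unique(m[, c("subtheme", "theme")])),
               length(unique(m$subtheme)))
})

test_that("region-to-WSI aggregation gives mean and population sd", {
  expect_equal(aggregate_regions_to_wsi(c(2, 4)), c(mean = 3, sd = 1))
  a1 <- aggregate_regions_to_wsi(5)
  expect_equal(a1[["mean"]], 5)
  expect_true(is.na(a1[["sd"]]))
  a0 <- aggregate_regions_to_wsi(numeric(0))
  expect_true(all(is.na(a0)))
  # oracle recomputation on random values
  v <- withr::with_seed(2, rnorm(40))
  a <- aggregate_regions_to_wsi(v)
  expect_equal(a[["mean"]], mean(v))
  expect_equal(a[["sd"]], sqrt(mean((v - mean(v))^2)))
})

test_that("saliency-weighted aggregation honors weights and top-k", {
  # equal saliencies reduce to the unweighted aggregate exactly
  x <- c(1, 2, 3, 4)
  eq <- saliency_weighted_aggregate(x, rep(2, 4), top_k = 10)
  expect_equal(eq[["wmean"]], mean(x))
  expect_equal(eq[["wsd"]], sqrt(mean((x - mean(x))^2)))
  # w = {1, 3}, x = {0, 4} -> wmean 3, wsd sqrt(3)
  a <- saliency_weighted_aggregate(c(0, 4), c(1, 3), top_k = 2)
  expect_equal(a[["wmean"]], 3)
  expect_equal(a[["wsd"]], sqrt(3))
  # 200 ROIs with top_k = 128: only the 128 most salient contribute
  withr::local_seed(3)
  xx <- rnorm(200); ww <- runif(200)
  keep <- order(ww, decreasing = TRUE)[1:128]
  manual <- sum(ww[keep] * xx[keep]) / sum(ww[keep])
  expect_equal(saliency_weighted_aggregate(xx, ww, 128)[["wmean"]], manual)
  # all-zero saliencies fall back to the unweighted mean with a warning
  expect_warning(z <- saliency_weighted_aggregate(c(1, 3), c(0, 0), 10),
                 "saliencies")
  expect_equal(z[["wmean"]], 2)
  # missing values drop out with their weights
  b <- saliency_weighted_aggregate(c(1, NA, 3), c(1, 100, 1), 10)
  expect_equal(b[["wmean"]], 2)
})

test_that("patient-level averaging ignores missing per-slide values", {
  expect_equal(unname(patient_level(rbind(c(1, 2)))), c(1, 2))
  expect_equal(unname(patient_level(rbind(c(1, NA), c(3, 4)))), c(2, 4))
  expect_true(is.na(patient_level(rbind(c(NA, 1), c(NA, 2)))[1]))
})

test_that("z-scoring is exact in-sample and reusable out-of-sample", {
  withr::local_seed(4)
  X <- data.frame(a = rnorm(50, 5, 2), b = rnorm(50, -1, 0.5))
  z <- zscore_features(X)
  expect_equal(unname(colMeans(z$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(vapply(z$X, sd, numeric(1))), c(1, 1),
               tolerance = 1e-12)
  # reuse of reference stats
  z2 <- zscore_features(data.frame(a = 5, b = -1), z$stats)
  expect_equal(unname(unlist(z2$X)),
               unname(c((5 - z$stats$mu["a"]) / z$stats$sigma["a"],
                        (-1 - z$stats$mu["b"]) / z$stats$sigma["b"])))
  # constant features are dropped with a warning
  Xc <- cbind(X, const = 1)
  expect_warning(zc <- zscore_features(Xc), "constant")
  expect_false("const" %in% names(zc$X))
  # unknown feature against a reference is an error
  expect_error(zscore_features(data.frame(zzz = 1), z$stats), "missing")
})

test_that("k-NN imputation fills from the nearest reference rows only", {
  withr::local_seed(5)
  ref <- as.data.frame(matrix(rnorm(40 * 4), 40))
  names(ref) <- c("a", "b", "c", "d")
  # a row duplicating reference row 7 except one missing cell
  q <- ref[7, ]; q$c <- NA
  imp <- knn_impute(q, ref, k = 1)
  expect_equal(imp$c, ref$c[7])
  # k = 10: mean of the 10 nearest neighbors' values
  q2 <- ref[7, ]; q2$d <- NA
  d2 <- rowMeans((ref[, 1:3] - matrix(unlist(ref[7, 1:3]), 40, 3,
                                      byrow = TRUE))^2)
  nn <- order(d2)[1:10]
  expect_equal(knn_impute(q2, ref, k = 10)$d, mean(ref$d[nn]))
  # a complete matrix is unchanged, observed cells never altered
  expect_identical(knn_impute(ref, ref, k = 10), ref)
  q3 <- ref[1:3, ]; q3$a[2] <- NA
  imp3 <- knn_impute(q3, ref, k = 5)
  expect_identical(imp3[-2, ], q3[-2, ])
  expect_identical(imp3$b, q3$b)
  # an all-missing row is an error
  qa <- ref[1, ]; qa[] <- NA
  expect_error(knn_impute(qa, ref), "all features missing")
})
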