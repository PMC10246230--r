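test_that("slide simulation is reproducible from its seed", {
  p <- slide_sim_params(canvas_um = 256, n_nests = 2,
                        nest_radius_um = c(50, 5), seed = 11)
  s1 <- simulate_slide(p)
  s2 <- simulate_slide(p)
  expect_identical(s1$region_mask, s2$region_mask)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_identical(s1$image, s2$image)
})

test_that("necrosis fraction zero leaves the necrosis label absent", {
  s <- simulate_slide(slide_sim_params(canvas_um = 256, n_nests = 2,
                                       nest_radius_um = c(50, 5),
                                       necrosis_frac = 0, seed = 3,
                                       render_image = FALSE))
  expect_false(rc[["necrosis"]] %in% unique(as.vector(s$region_mask)))
  s2 <- simulate_slide(slide_sim_params(canvas_um = 256, n_nests = 2,
                                        nest_radius_um = c(50, 5),
                                        necrosis_frac = 1, seed = 3,
                                        render_image = FALSE))
  expect_true(rc[["necrosis"]] %in% unique(as.vector(s2$region_mask)))
})

test_that("infeasible nest geometry is rejected", {
  expect_error(slide_sim_params(canvas_um = 200, nest_radius_um = c(120, 10)),
               "infeasible")
})

test_that("a Thomas CAF process shows clustering beyond chance at 64 um", {
  s <- simulate_slide(slide_sim_params(
    canvas_um = 512, n_nests = 0, n_til_regions = 0, render_image = FALSE,
    caf_process = list(type = "thomas", parent_rate = 15, cluster_sd = 20,
                       offspring_mean = 10), seed = 21))
  ca <- as.matrix(s$nuclei[s$nuclei$superclass == "stromal",
                           c("x_um", "y_um")])
  area <- sum(s$region_mask != rc[["background"]])
  expect_gt(clustering_ratio(ca, ca, 64, area, same_class = TRUE), 1)
})

test_that("empirical point-process intensity matches the requested rate", {
  # 20 replicates of a homogeneous Poisson process; the mean count must sit
  # within 3 standard errors of rate * area
  rate <- 400; reps <- 20
  counts <- withr::with_seed(5, vapply(seq_len(reps), function(i)
    nrow(hips:::rpoisson_pp(rate, 1000, 1000)), numeric(1)))
  expected <- rate * 1
  se <- sqrt(expected / reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("cohort censoring behaves as requested", {
  cp <- cohort_sim_params(n_patients = 120, censor_rate = 0, seed = 2)
  co <- simulate_cohort(cp, make_slides = FALSE)
  expect_true(all(co$clinical$event == 1))
  cp2 <- cohort_sim_params(n_patients = 400, censor_rate = 0.5, seed = 2)
  co2 <- simulate_cohort(cp2, make_slides = FALSE)
  expect_gt(mean(co2$clinical$event == 0), 0.3)
  expect_lt(mean(co2$clinical$event == 0), 0.7)
  expect_true(all(co2$clinical$time > 0))
  expect_true(all(co2$clinical$tnbc ==
                    (co2$clinical$er == 0 & co2$clinical$pr == 0 &
                       co2$clinical$her2 == 0)))
})

test_that("null generative effects give calibrated log-rank type I error", {
  cp0 <- function(seed) cohort_sim_params(
    n_patients = 150, true_beta = c(caf = 0), censor_rate = 0.3, seed = seed)
  pvals <- vapply(1:40, function(i) {
    co <- simulate_cohort(cp0(100 + i), make_slides = FALSE)
    g <- co$latent$caf > stats::median(co$latent$caf)
    sd0 <- survival::survdiff(
      survival::Surv(co$clinical$time, co$clinical$event) ~ g)
    stats::pchisq(sd0$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  # under the null the p-values are uniform
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.25)
})

test_that("a positive CAF effect is recovered with the right sign", {
  cp <- cohort_sim_params(n_patients = 400, true_beta = c(caf = 0.7),
                          censor_rate = 0.2, seed = 9)
  co <- simulate_cohort(cp, make_slides = FALSE)
  fit <- survival::coxph(
    survival::Surv(co$clinical$time, co$clinical$event) ~ co$latent$caf,
    ties = "breslow")
  expect_gt(coef(fit)[1], 0.4)
})

test_that("the worked-example slide matches its hand-computed geometry", {
  s <- worked_example_slide()
  # exact 100 um-side square nest at 1 um/px: raw region area 10,000 um^2
  sq <- s$region_mask[51:150, 51:150]
  expect_equal(sum(sq == rc[["epithelium"]]), 10000)
  # exactly 5 TILs within 32 um of the single epithelial cell
  ep <- as.matrix(s$nuclei[s$nuclei$superclass == "epithelial",
                           c("x_um", "y_um")])
  ti <- as.matrix(s$nuclei[s$nuclei$superclass == "tils", c("x_um", "y_um")])
  expect_equal(local_density(ep, ti, 32), 5)
  expect_equal(local_density(ep, ti, 8), 0)
  # the circular nest has circularity ~ 1 through the region pipeline
  m2 <- hips:::downsample_mask(s$region_mask, 2L)
  inst <- extract_region_instances(m2, rc[["epithelium"]], mpp = 2)
  circ <- vapply(inst, function(i) region_shape_features(i)[["circularity"]],
                 numeric(1))
  expect_true(any(abs(circ - 1) < 0.07))
})
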