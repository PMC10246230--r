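#' Slide simulation parameters
#'
#' Parameters of the synthetic-slide generator. The generator emulates the
#' structures the feature catalogue measures: epithelial nests of controllable
#' size/circularity embedded in stroma, optional necrotic nest cores and
#' TILs-dense aggregates, multi-class nucleus point processes (homogeneous
#' Poisson or Thomas/Neyman-Scott for controllable clustering), and a rendered
#' grayscale H&E-like image with oriented collagen texture (fiber orientations
#' von-Mises distributed with concentration \code{collagen_kappa}; fibroblast
#' nuclei share the same orientation field).
#'
#' @param canvas_um side of the square slide in microns.
#' @param n_nests number of epithelial nests.
#' @param nest_radius_um length-2 vector (mean, sd) of nest radii.
#' @param nest_circularity target circularity in (0, 1]; lower values add
#'   boundary waviness.
#' @param necrosis_frac fraction of nests carrying a central necrotic core.
#' @param caf_process,til_process list: either
#'   \code{list(type = "poisson", rate = <per mm^2>)} or
#'   \code{list(type = "thomas", parent_rate = <per mm^2>, cluster_sd = <um>,
#'   offspring_mean = <count>)}.
#' @param collagen_kappa von Mises concentration of collagen fiber (and CAF
#'   nucleus) orientations; 0 = uniform (disordered), large = parallel.
#' @param epith_density_per_mm2 epithelial nucleus intensity within nests.
#' @param epith_atypia probability an epithelial nucleus is dominantly
#'   classified cancer (vs normal/benign-appearing) epithelial.
#' @param cell_intensity_by_class named mean gray levels of nucleus classes.
#' @param seed integer seed; identical seeds give identical slides.
#' @return list of class \code{"slide_sim_params"}.
#' @export
slide_sim_params <- function(canvas_um = 1024, n_nests = 6,
                             nest_radius_um = c(85, 12),
                             nest_circularity = 0.9,
                             necrosis_frac = 0.15,
                             n_til_regions = 1,
                             til_region_radius_um = 80,
                             epith_density_per_mm2 = 2500,
                             epith_atypia = 0.8,
                             plasma_frac = 0.3,
                             caf_process = list(type = "thomas",
                                                parent_rate = 25,
                                                cluster_sd = 25,
                                                offspring_mean = 8),
                             til_process = list(type = "thomas",
                                                parent_rate = 20,
                                                cluster_sd = 20,
                                                offspring_mean = 10),
                             collagen_kappa = 4,
                             fibers_per_mm2 = 250,
                             fiber_length_um = c(15, 45),
                             cell_intensity_by_class = c(epithelial = 0.30,
                                                         stromal = 0.35,
                                                         tils = 0.15),
                             chromatin_speckle = c(epithelial = 0.14,
                                                   stromal = 0.08,
                                                   tils = 0.05),
                             noise_sd = 0.02,
                             image_mpp = 0.5,
                             render_image = TRUE,
                             seed = NULL) {
  p <- as.list(environment())
  stopifnot(p$necrosis_frac >= 0, p$necrosis_frac <= 1,
            p$n_nests >= 0, p$epith_density_per_mm2 >= 0)
  for (proc in list(p$caf_process, p$til_process)) {
    stopifnot(proc$type %in% c("poisson", "thomas"))
    if (proc$type == "poisson") stopifnot(proc$rate >= 0)
    else stopifnot(proc$parent_rate >= 0, proc$cluster_sd > 0,
                   proc$offspring_mean >= 0)
  }
  if (p$n_nests > 0 && 2 * (p$nest_radius_um[1] + 2 * p$nest_radius_um[2]) >
        p$canvas_um)
    stop("infeasible geometry: nests larger than canvas")
  class(p) <- "slide_sim_params"
  p
}

# von Mises sampler on [0, 2*pi) (Best & Fisher rejection); kappa = 0 uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# Homogeneous Poisson point process on a w x h micron window.
rpoisson_pp <- function(rate_per_mm2, w_um, h_um) {
  n <- stats::rpois(1, rate_per_mm2 * w_um * h_um / 1e6)
  cbind(x = stats::runif(n, 0, w_um), y = stats::runif(n, 0, h_um))
}

# Thomas (Neyman-Scott) cluster process; parents simulated on an expanded
# window to avoid edge deficits.
rthomas_pp <- function(parent_rate_per_mm2, cluster_sd_um, offspring_mean,
                       w_um, h_um) {
  pad <- 4 * cluster_sd_um
  parents <- rpoisson_pp(parent_rate_per_mm2, w_um + 2 * pad, h_um + 2 * pad)
  if (nrow(parents) == 0) return(cbind(x = numeric(0), y = numeric(0)))
  parents[, 1] <- parents[, 1] - pad
  parents[, 2] <- parents[, 2] - pad
  n_off <- stats::rpois(nrow(parents), offspring_mean)
  if (sum(n_off) == 0) return(cbind(x = numeric(0), y = numeric(0)))
  cx <- rep(parents[, 1], n_off) + stats::rnorm(sum(n_off), 0, cluster_sd_um)
  cy <- rep(parents[, 2], n_off) + stats::rnorm(sum(n_off), 0, cluster_sd_um)
  keep <- cx >= 0 & cx < w_um & cy >= 0 & cy < h_um
  cbind(x = cx[keep], y = cy[keep])
}

run_point_process <- function(proc, w_um, h_um) {
  if (proc$type == "poisson") rpoisson_pp(proc$rate, w_um, h_um)
  else rthomas_pp(proc$parent_rate, proc$cluster_sd, proc$offspring_mean,
                  w_um, h_um)
}

# Rasterize a wavy ellipse (nest) into an existing mask; returns pixel indices.
blob_pixels <- function(dim_xy, cx, cy, r_um, mpp, axis_ratio = 1,
                        theta = 0, wobble_amp = 0, wobble_k = 5,
                        wobble_phase = 0) {
  rmax <- r_um * (1 + abs(wobble_amp)) / min(axis_ratio, 1)
  x0 <- max(1L, floor((cx - rmax) / mpp)); x1 <- min(dim_xy[1], ceiling((cx + rmax) / mpp))
  y0 <- max(1L, floor((cy - rmax) / mpp)); y1 <- min(dim_xy[2], ceiling((cy + rmax) / mpp))
  if (x1 < x0 || y1 < y0) return(integer(0))
  xs <- (x0:x1 - 0.5) * mpp - cx
  ys <- (y0:y1 - 0.5) * mpp - cy
  dx <- matrix(xs, length(xs), length(ys))
  dy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rho <- sqrt((u / r_um)^2 + (v / (r_um * axis_ratio))^2)
  phi <- atan2(v, u)
  inside <- rho <= 1 + wobble_amp * cos(wobble_k * phi + wobble_phase)
  ij <- which(inside, arr.ind = TRUE)
  (ij[, 2] + y0 - 2L) * dim_xy[1] + (ij[, 1] + x0 - 1L)
}

#' Simulate a synthetic slide
#'
#' Builds a region label mask at 1 um/px, places nuclei by the requested point
#' processes with near-one-hot probability vectors (dominant class probability
#' drawn from [0.7, 0.99]), and optionally renders a grayscale image with
#' per-class nuclear intensities, oriented collagen texture, and Gaussian
#' noise. Fully reproducible from \code{params$seed}. Ground truth used by
#' tests (nest geometry, fiber orientations, process settings) is attached as
#' attribute \code{"sim_truth"}.
#'
#' @param params a \code{\link{slide_sim_params}}.
#' @param slide_id,patient_id identifiers.
#' @return A \code{\link{slide_panoptic}}.
#' @export
simulate_slide <- function(params = slide_sim_params(), slide_id = "sim",
                           patient_id = slide_id) {
  p <- params
  with_seed(p$seed, {
    schema <- hips_schema()
    rc <- schema$region_classes
    W <- as.integer(p$canvas_um)      # mask at 1 um/px
    mask <- matrix(rc[["stroma"]], W, W)

    # epithelial nests
    nests <- NULL
    if (p$n_nests > 0) {
      r <- pmax(15, stats::rnorm(p$n_nests, p$nest_radius_um[1],
                                 p$nest_radius_um[2]))
      cx <- stats::runif(p$n_nests, r, p$canvas_um - r)
      cy <- stats::runif(p$n_nests, r, p$canvas_um - r)
      wob <- 0.8 * (1 - p$nest_circularity)
      q <- stats::runif(p$n_nests, 0.75, 1)
      th <- stats::runif(p$n_nests, 0, pi)
      ph <- stats::runif(p$n_nests, 0, 2 * pi)
      nests <- data.frame(cx = cx, cy = cy, r = r, axis_ratio = q,
                          theta = th, necrotic = FALSE)
      for (i in seq_len(p$n_nests)) {
        px <- blob_pixels(c(W, W), cx[i], cy[i], r[i], 1, q[i], th[i],
                          wob, 5, ph[i])
        mask[px] <- rc[["epithelium"]]
      }
      n_necro <- round(p$necrosis_frac * p$n_nests)
      if (n_necro > 0) {
        idx <- seq_len(n_necro)
        nests$necrotic[idx] <- TRUE
        for (i in idx) {
          px <- blob_pixels(c(W, W), cx[i], cy[i], 0.45 * r[i], 1, q[i], th[i])
          mask[px] <- rc[["necrosis"]]
        }
      }
    }

    # TILs-dense aggregates in stroma
    if (p$n_til_regions > 0) {
      for (i in seq_len(p$n_til_regions)) {
        rr <- p$til_region_radius_um
        tx <- stats::runif(1, rr, p$canvas_um - rr)
        ty <- stats::runif(1, rr, p$canvas_um - rr)
        px <- blob_pixels(c(W, W), tx, ty, rr, 1,
                          stats::runif(1, 0.8, 1), stats::runif(1, 0, pi))
        px <- px[mask[px] == rc[["stroma"]]]
        mask[px] <- rc[["tils_dense"]]
      }
    }

    # shared orientation field for collagen and fibroblasts
    fiber_mu <- stats::runif(1, 0, pi)

    # ---- nuclei ----
    sample_in_class <- function(n_or_pts, class_codes) {
      # place points either by count within a class (pixel sampling) or filter
      # pre-generated process points by underlying class
      ok <- which(matrix(mask %in% class_codes, W, W))
      if (is.matrix(n_or_pts)) {
        pts <- n_or_pts
        if (nrow(pts) == 0) return(pts)
        px <- floor(pts[, 1]) + 1L
        py <- floor(pts[, 2]) + 1L
        keep <- mask[cbind(px, py)] %in% class_codes
        pts[keep, , drop = FALSE]
      } else {
        if (length(ok) == 0 || n_or_pts == 0)
          return(cbind(x = numeric(0), y = numeric(0)))
        idx <- sample(ok, n_or_pts, replace = TRUE)
        cbind(x = (idx - 1) %% W + stats::runif(n_or_pts),
              y = (idx - 1) %/% W + stats::runif(n_or_pts))
      }
    }

    epith_area_mm2 <- sum(mask == rc[["epithelium"]]) / 1e6
    n_epith <- stats::rpois(1, p$epith_density_per_mm2 * epith_area_mm2)
    epith_xy <- sample_in_class(n_epith, rc[["epithelium"]])
    caf_xy <- sample_in_class(run_point_process(p$caf_process,
                                                p$canvas_um, p$canvas_um),
                              rc[["stroma"]])
    til_xy <- sample_in_class(run_point_process(p$til_process,
                                                p$canvas_um, p$canvas_um),
                              c(rc[["stroma"]], rc[["tils_dense"]]))
    til_dense_area_mm2 <- sum(mask == rc[["tils_dense"]]) / 1e6
    if (til_dense_area_mm2 > 0) {
      extra <- stats::rpois(1, 2000 * til_dense_area_mm2)
      til_xy <- rbind(til_xy, sample_in_class(extra, rc[["tils_dense"]]))
    }

    make_probs <- function(n, dominant) {
      P <- matrix(0, n, 6, dimnames = list(NULL, prob_cols(schema)))
      if (n == 0) return(P)
      u <- stats::runif(n, 0.7, 0.99)
      P[] <- (1 - u) / 5
      P[cbind(seq_len(n), match(paste0("prob_", dominant),
                                colnames(P)))] <- u
      P
    }

    mk <- function(xy, subclass_fun, major, minor, orient_fun, prefix) {
      n <- nrow(xy)
      if (n == 0) return(NULL)
      sub <- subclass_fun(n)
      df <- data.frame(nucleus_id = paste0(prefix, seq_len(n)),
                       x_um = xy[, 1], y_um = xy[, 2],
                       stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(make_probs(n, sub)))
      df$major_um <- pmax(2, stats::rnorm(n, major, 0.08 * major))
      df$minor_um <- pmin(df$major_um,
                          pmax(1.5, stats::rnorm(n, minor, 0.08 * minor)))
      df$orient_deg <- orient_fun(n)
      df
    }

    nuclei <- rbind(
      mk(epith_xy,
         function(n) ifelse(stats::runif(n) < p$epith_atypia,
                            "cancer_epith", "normal_epith"),
         major = 7.0, minor = 5.6,
         orient_fun = function(n) stats::runif(n, 0, 180), prefix = "e"),
      mk(caf_xy, function(n) rep("fibroblast", n),
         major = 9.5, minor = 3.6,
         orient_fun = function(n)
           (rvonmises(n, 2 * fiber_mu, p$collagen_kappa) / 2) * 180 / pi,
         prefix = "f"),
      mk(til_xy,
         function(n) ifelse(stats::runif(n) < p$plasma_frac,
                            "plasma", "lymphocyte"),
         major = 5.2, minor = 4.6,
         orient_fun = function(n) stats::runif(n, 0, 180), prefix = "t")
    )
    if (is.null(nuclei)) nuclei <- data.frame()

    # ---- image ----
    img <- NULL
    fiber_angles <- numeric(0)
    if (p$render_image) {
      impp <- p$image_mpp
      WI <- as.integer(round(p$canvas_um / impp))
      base <- c(0.97, 0.55, 0.62, 0.58, 0.80, 0.60)  # by class code 0..5
      upscale <- mask[pmin(W, floor((seq_len(WI) - 0.5) * impp) + 1L),
                      pmin(W, floor((seq_len(WI) - 0.5) * impp) + 1L)]
      img <- matrix(base[upscale + 1L], WI, WI)

      # collagen fibers: dark oriented segments in stroma
      stroma_mm2 <- sum(mask == rc[["stroma"]]) / 1e6
      nf <- stats::rpois(1, p$fibers_per_mm2 * stroma_mm2)
      if (nf > 0) {
        fc <- sample_in_class(nf, rc[["stroma"]])
        nf <- nrow(fc)
        fiber_angles <- (rvonmises(nf, 2 * fiber_mu, p$collagen_kappa) / 2)
        flen <- stats::runif(nf, p$fiber_length_um[1], p$fiber_length_um[2])
        for (i in seq_len(nf)) {
          tseq <- seq(-flen[i] / 2, flen[i] / 2, by = impp / 2)
          fx <- floor((fc[i, 1] + tseq * cos(fiber_angles[i])) / impp) + 1L
          fy <- floor((fc[i, 2] + tseq * sin(fiber_angles[i])) / impp) + 1L
          keep <- fx >= 1 & fx <= WI & fy >= 1 & fy <= WI
          idx <- cbind(fx[keep], fy[keep])
          inside <- mask[cbind(pmin(W, floor((fx[keep] - 0.5) * impp) + 1L),
                               pmin(W, floor((fy[keep] - 0.5) * impp) + 1L))] ==
            rc[["stroma"]]
          img[idx[inside, , drop = FALSE]] <- 0.45
        }
      }

      # nuclei: dark ellipses with chromatin speckle
      if (nrow(nuclei) > 0) {
        lab <- rasterize_nuclei(nuclei, c(WI, WI), impp)
        sc <- nuclei$superclass <- nucleus_superclass(
          nuclei[, prob_cols(schema)])
        ci <- p$cell_intensity_by_class
        sp <- p$chromatin_speckle
        base_i <- ifelse(sc %in% names(ci), ci[sc], 0.3)
        spk <- ifelse(sc %in% names(sp), sp[sc], 0.08)
        on <- which(lab > 0)
        img[on] <- base_i[lab[on]] +
          (stats::runif(length(on)) < 0.3) * spk[lab[on]] *
            sign(stats::runif(length(on)) - 0.35)
      }
      img <- pmin(pmax(img + stats::rnorm(length(img), 0, p$noise_sd), 0), 1)
    }

    slide <- slide_panoptic(slide_id, 1, mask, nuclei, image = img,
                            image_mpp = p$image_mpp, patient_id = patient_id)
    attr(slide, "sim_truth") <- list(
      params = p, nests = nests, fiber_mu_deg = fiber_mu * 180 / pi,
      fiber_angles_deg = fiber_angles * 180 / pi)
    slide
  })
}

#' Synthetic two-stain RGB mixture with known stain vectors
#'
#' Renders an RGB field as \code{exp(-C S)} in optical density space, for
#' exercising stain-vector recovery in Macenko normalization.
#'
#' @param dim image side in pixels.
#' @param stains 2x3 matrix of unit stain OD vectors (rows).
#' @param max_conc length-2 maximum concentrations.
#' @param seed RNG seed.
#' @return list(image, stains, conc).
#' @export
simulate_stain_mixture <- function(dim = 120,
                                   stains = rbind(
                                     h = c(0.65, 0.70, 0.29),
                                     e = c(0.07, 0.99, 0.11)),
                                   max_conc = c(1.2, 0.9),
                                   min_conc = 0.005, seed = 1) {
  with_seed(seed, {
    stains <- stains / sqrt(rowSums(stains^2))
    c1 <- matrix(stats::runif(dim * dim, min_conc, max_conc[1]), dim)
    c2 <- matrix(stats::runif(dim * dim, min_conc, max_conc[2]), dim)
    od <- array(0, c(dim, dim, 3))
    for (k in 1:3) od[, , k] <- c1 * stains[1, k] + c2 * stains[2, k]
    list(image = exp(-od), stains = stains, conc = list(c1 = c1, c2 = c2))
  })
}

#' Cohort simulation parameters
#'
#' @param n_patients cohort size.
#' @param true_beta named log hazard ratios per standardized latent generative
#'   parameter (names among \code{caf, til, collagen_disorder, atypia,
#'   necrosis}) and optionally per IHC marker (\code{er, pr, her2}).
#' @param baseline_hazard constant exponential hazard per year.
#' @param censor_rate target independent-censoring fraction in [0, 1].
#' @param seed integer seed.
#' @export
cohort_sim_params <- function(n_patients = 200,
                              true_beta = c(caf = 0.6,
                                            collagen_disorder = 0.45,
                                            til = -0.35),
                              baseline_hazard = 0.06,
                              censor_rate = 0.3,
                              seed = 1) {
  stopifnot(censor_rate >= 0, censor_rate <= 1, baseline_hazard > 0,
            n_patients >= 1)
  structure(list(n_patients = n_patients, true_beta = true_beta,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, seed = seed),
            class = "cohort_sim_params")
}

# Default mapping from standardized latents to slide generator settings.
default_slide_sampler <- function(latent, canvas_um = 512,
                                  render_image = TRUE, seed = NULL) {
  slide_sim_params(
    canvas_um = canvas_um,
    n_nests = max(2L, stats::rpois(1, 3)),
    nest_radius_um = c(85, 10),
    nest_circularity = plogis(2 - 0.6 * latent[["atypia"]]),
    necrosis_frac = plogis(-1.2 + latent[["necrosis"]]),
    epith_atypia = plogis(1.2 + 0.9 * latent[["atypia"]]),
    caf_process = list(type = "thomas",
                       parent_rate = 25 * exp(0.35 * latent[["caf"]]),
                       cluster_sd = 25, offspring_mean = 8),
    til_process = list(type = "thomas",
                       parent_rate = 20 * exp(0.35 * latent[["til"]]),
                       cluster_sd = 20, offspring_mean = 10),
    collagen_kappa = exp(1.4 - 1.0 * latent[["collagen_disorder"]]),
    render_image = render_image,
    seed = seed)
}

#' Simulate a synthetic survival cohort with paired slides
#'
#' Per patient, standardized latent generative parameters are drawn i.i.d.
#' N(0,1), mapped to slide-generator settings by \code{slide_param_sampler},
#' and survival times are drawn from an exponential hazard
#' \code{h0 * exp(sum(beta * latent))} with independent exponential censoring
#' calibrated to \code{censor_rate}. IHC statuses are sampled with realistic
#' prevalences (ER 80\%, PR conditional on ER, HER2 15\%); Nottingham grade is
#' derived from the atypia latent tertiles.
#'
#' @param cparams a \code{\link{cohort_sim_params}}.
#' @param slide_param_sampler function(latent, seed) returning
#'   \code{slide_sim_params} for one patient.
#' @param render_image render slide images (needed for intensity features).
#' @param canvas_um slide canvas passed to the default sampler.
#' @param make_slides set FALSE to return outcomes/latents only (cheap, for
#'   survival-side calibration studies).
#' @return list with \code{slides} (list of \code{slide_panoptic}),
#'   \code{clinical} (data.frame: patient_id, time, event, er, pr, her2, tnbc,
#'   grade) and \code{latent} (the generative ground truth).
#' @export
simulate_cohort <- function(cparams = cohort_sim_params(),
                            slide_param_sampler = NULL,
                            render_image = TRUE, canvas_um = 512,
                            make_slides = TRUE) {
  n <- cparams$n_patients
  latents <- c("caf", "til", "collagen_disorder", "atypia", "necrosis")
  with_seed(cparams$seed, {
    Z <- matrix(stats::rnorm(n * length(latents)), n,
                dimnames = list(NULL, latents))
    er <- stats::rbinom(n, 1, 0.80)
    pr <- stats::rbinom(n, 1, ifelse(er == 1, 0.85, 0.30))
    her2 <- stats::rbinom(n, 1, 0.15)
    tnbc <- as.integer(er == 0 & pr == 0 & her2 == 0)
    grade <- as.integer(cut(Z[, "atypia"],
                            stats::qnorm(c(0, 1 / 3, 2 / 3, 1)),
                            labels = FALSE, include.lowest = TRUE))
    beta <- cparams$true_beta
    lp <- rep(0, n)
    for (nm in names(beta)) {
      lp <- lp + beta[[nm]] * switch(nm,
        er = er, pr = pr, her2 = her2, Z[, nm])
    }
    h <- cparams$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, h)
    if (cparams$censor_rate > 0) {
      rate_c <- cparams$baseline_hazard * cparams$censor_rate /
        (1 - cparams$censor_rate + 1e-12)
      t_cens <- stats::rexp(n, rate_c)
    } else t_cens <- rep(Inf, n)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(pmin(t_event, t_cens), 1e-3)
    clinical <- data.frame(
      patient_id = sprintf("p%03d", seq_len(n)),
      time = time, event = event, er = er, pr = pr, her2 = her2,
      tnbc = tnbc, grade = grade, stringsAsFactors = FALSE)
    slide_seeds <- vapply(seq_len(n), function(i)
      child_seed(cparams$seed, i), integer(1))
    slides <- if (!make_slides) NULL else lapply(seq_len(n), function(i) {
      lat <- as.list(Z[i, ])
      sp <- if (is.null(slide_param_sampler)) {
        default_slide_sampler(lat, canvas_um = canvas_um,
                              render_image = render_image,
                              seed = slide_seeds[i])
      } else slide_param_sampler(lat, seed = slide_seeds[i])
      simulate_slide(sp, slide_id = clinical$patient_id[i])
    })
    list(slides = slides, clinical = clinical,
         latent = as.data.frame(Z))
  })
}

#' Deterministic worked-example slide
#'
#' A tiny hand-placed slide whose feature values can be computed by hand:
#' an exact 100 um-side square epithelial nest (area 10,000 um^2), a circular
#' nest (circularity ~ 1), a single isolated epithelial nucleus with exactly
#' five TILs within 32 um, and two distant fibroblasts. No necrosis, no image.
#'
#' @return A \code{\link{slide_panoptic}} at 1 um/px over 512 x 512 um.
#' @export
worked_example_slide <- function() {
  rc <- hips_schema()$region_classes
  W <- 512L
  mask <- matrix(rc[["stroma"]], W, W)
  # square nest: x in [50,150), y in [50,150)  -> pixels 51:150 x 51:150
  mask[51:150, 51:150] <- rc[["epithelium"]]
  # circular nest radius 80 um at (350, 120)
  px <- blob_pixels(c(W, W), 350, 120, 80, 1)
  mask[px] <- rc[["epithelium"]]
  probs_one_hot <- function(cls) {
    P <- rep(0.02, 6)
    names(P) <- prob_cols()
    P[paste0("prob_", cls)] <- 0.9
    P / sum(P)
  }
  ang <- 2 * pi * (0:4) / 5
  d <- c(10, 15, 20, 25, 30)
  nuclei <- data.frame(
    nucleus_id = c("epi1", paste0("til", 1:5), "caf1", "caf2"),
    x_um = c(256, 256 + d * cos(ang), 60, 470),
    y_um = c(400, 400 + d * sin(ang), 300, 460),
    stringsAsFactors = FALSE)
  P <- rbind(probs_one_hot("cancer_epith"),
             matrix(probs_one_hot("lymphocyte"), 5, 6, byrow = TRUE,
                    dimnames = list(NULL, prob_cols())),
             probs_one_hot("fibroblast"), probs_one_hot("fibroblast"))
  nuclei <- cbind(nuclei, as.data.frame(P))
  nuclei$major_um <- c(7, rep(5, 5), 9.5, 9.5)
  nuclei$minor_um <- c(5.6, rep(4.5, 5), 3.6, 3.6)
  nuclei$orient_deg <- c(0, rep(0, 5), 30, 30)
  slide_panoptic("worked_example", 1, mask, nuclei)
}
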