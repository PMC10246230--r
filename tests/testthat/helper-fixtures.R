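# Shared fixture builders (everything is generated in code; no binary data).

rc <- hips_schema()$region_classes

# one-hot-ish probability row for a subclass
probs_row <- function(cls, dominant = 0.9) {
  p <- rep((1 - dominant) / 5, 6)
  names(p) <- paste0("prob_", hips_schema()$nucleus_subclasses)
  p[paste0("prob_", cls)] <- dominant
  p
}

# minimal nuclei table from centroids and subclasses
make_nuclei <- function(x, y, cls, major = 6, minor = 5, orient = 0) {
  n <- length(x)
  if (n == 0)
    return(make_nuclei(1, 1, "lymphocyte")[0, ])
  df <- data.frame(nucleus_id = paste0("n", seq_len(n)), x_um = x, y_um = y,
                   stringsAsFactors = FALSE)
  P <- t(vapply(cls, probs_row, numeric(6)))
  df <- cbind(df, as.data.frame(P))
  df$major_um <- rep_len(major, n)
  df$minor_um <- rep_len(minor, n)
  df$orient_deg <- rep_len(orient, n)
  df
}

# uniform stroma slide with nuclei
make_slide <- function(nuclei, side = 256, mask_value = rc[["stroma"]],
                       image = NULL, image_mpp = 1) {
  slide_panoptic("fx", 1, matrix(mask_value, side, side), nuclei,
                 image = image, image_mpp = image_mpp)
}

# synthetic fiber table with given orientations (degrees) and lengths
make_fibers <- function(orient, length_um = 20, axis_ratio = 0.1) {
  data.frame(x_um = seq_along(orient), y_um = seq_along(orient),
             length_um = rep_len(length_um, length(orient)),
             orientation_deg = orient %% 180,
             axis_ratio = rep_len(axis_ratio, length(orient)),
             waviness = 0, n_px = 50L,
             straight = rep_len(axis_ratio, length(orient)) < 0.2)
}

# synthetic patient-level feature matrix carrying the manifest names;
# `signal` names get a linear effect on the log hazard
make_feature_cohort <- function(n = 150, signal = c(GlobalCAFDensity = 0.8),
                                baseline = 0.08, censor = 0.3, seed = 1) {
  withr::local_seed(seed)
  man <- hips_manifest()
  X <- matrix(rnorm(n * nrow(man)), n, dimnames = list(NULL, man$name))
  lp <- drop(X[, names(signal), drop = FALSE] %*% unname(signal))
  t_ev <- rexp(n, baseline * exp(lp))
  t_c <- if (censor > 0) rexp(n, baseline * censor / (1 - censor)) else Inf
  features <- data.frame(patient_id = sprintf("p%03d", 1:n), X,
                         check.names = FALSE, stringsAsFactors = FALSE)
  er <- rbinom(n, 1, 0.8); pr <- rbinom(n, 1, 0.7); her2 <- rbinom(n, 1, 0.15)
  clinical <- data.frame(
    patient_id = features$patient_id,
    time = pmax(pmin(t_ev, t_c), 1e-3), event = as.integer(t_ev <= t_c),
    er = er, pr = pr, her2 = her2,
    tnbc = as.integer(er == 0 & pr == 0 & her2 == 0),
    grade = sample(1:3, n, replace = TRUE), stringsAsFactors = FALSE)
  list(features = features, clinical = clinical)
}
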