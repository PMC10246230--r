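#' Peri-CAF stromal matrix heterogeneity
#'
#' For each fibroblast in a 512 um ROI, the mean image intensity in a thin rim
#' (4 um) around the nucleus restricted to stromal matrix (stroma mask minus
#' all nuclei) is computed; the statistic is the population variance of these
#' per-CAF rim means across the ROI. High values capture interface changes
#' such as desmoplasia. Requires at least two CAFs with non-empty rims.
#'
#' @param caf_rim_means numeric vector of per-CAF rim mean intensities
#'   (NA entries, from empty rims, are dropped).
#' @return variance, or NA when fewer than two valid CAFs.
#' @export
peri_caf_matrix_heterogeneity <- function(caf_rim_means) {
  v <- caf_rim_means[is.finite(caf_rim_means)]
  if (length(v) < 2) return(NA_real_)
  mean((v - mean(v))^2)   # population variance
}

#' Detect collagen fibers in a stromal ROI
#'
#' Operates on 256 um ROIs at 0.5 um/px that pass the admission filter (at
#' least 30\% stroma and 20\% tumor). Nuclei are masked out, Canny edges are
#' taken on the stromal compartment, 8-connected components of at least
#' \code{min_px} pixels become fibers, and each fiber's length, orientation
#' and minor/major axis ratio come from its second moments. Waviness is
#' 1 - (endpoint chord length / arc length).
#'
#' @param img intensity matrix of the ROI at \code{mpp} um/px.
#' @param stroma_mask logical matrix (stroma pixels).
#' @param nuclei_mask logical matrix of nucleus pixels to exclude.
#' @param mpp microns per pixel (0.5 standard).
#' @param min_px minimum component size in pixels.
#' @param sigma_px Canny smoothing sigma.
#' @return data.frame: \code{length_um, orientation_deg} (in [0, 180)),
#'   \code{axis_ratio, waviness, n_px, straight} (axis_ratio < 0.2).
#' @export
detect_collagen_fibers <- function(img, stroma_mask, nuclei_mask = NULL,
                                   mpp = 0.5, min_px = 10, sigma_px = 1.5) {
  comp <- stroma_mask
  if (!is.null(nuclei_mask) && any(nuclei_mask)) {
    # exclude a ~2 um halo around nuclei so nuclear-boundary gradients do not
    # dominate the edge threshold
    halo <- max(1L, round(2 / mpp))
    nuclei_mask <- EBImage::dilate(nuclei_mask,
                                   EBImage::makeBrush(2L * halo + 1L,
                                                      "disc")) > 0
    comp <- comp & !nuclei_mask
  }
  if (!any(comp)) return(empty_fibers())
  edges <- canny_edges(img, sigma_px = sigma_px, mask = comp)
  if (!any(edges)) return(empty_fibers())
  lab <- label8(edges)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) return(empty_fibers())
  on_idx <- which(lab > 0)
  pix_by_lab <- split(on_idx, lab[on_idx])
  nr_lab <- nrow(lab)
  rows <- lapply(keep, function(i) {
    pix <- pix_by_lab[[as.character(i)]]
    ij <- cbind((pix - 1L) %% nr_lab + 1L, (pix - 1L) %/% nr_lab + 1L)
    cx <- ij[, 1] - mean(ij[, 1]); cy <- ij[, 2] - mean(ij[, 2])
    cxx <- mean(cx^2); cyy <- mean(cy^2); cxy <- mean(cx * cy)
    tr <- cxx + cyy; det <- cxx * cyy - cxy^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
    theta <- 0.5 * atan2(2 * cxy, cxx - cyy)       # major-axis direction
    len <- 4 * sqrt(max(l1, 1e-12)) * mpp           # ~major axis length
    # centerline arc length: pixels binned along the major axis, mean
    # perpendicular offset per bin, polyline length through the bin means
    # (robust to the two-sided edge ribbon Canny produces per fiber)
    proj <- cx * cos(theta) + cy * sin(theta)
    perp <- -cx * sin(theta) + cy * cos(theta)
    bins <- floor((proj - min(proj)) / 3)
    um <- vapply(split(proj, bins), mean, numeric(1))
    vm <- vapply(split(perp, bins), mean, numeric(1))
    ordb <- order(um)
    arc <- sum(sqrt(diff(um[ordb])^2 + diff(vm[ordb])^2)) * mpp
    chord <- sqrt((um[ordb][length(um)] - um[ordb][1])^2 +
                    (vm[ordb][length(vm)] - vm[ordb][1])^2) * mpp
    data.frame(x_um = mean(ij[, 1]) * mpp, y_um = mean(ij[, 2]) * mpp,
               length_um = len,
               orientation_deg = (theta * 180 / pi) %% 180,
               axis_ratio = sqrt(max(l2, 0) / max(l1, 1e-12)),
               waviness = max(0, 1 - chord / max(arc, 1e-12)),
               n_px = nrow(ij))
  })
  out <- do.call(rbind, rows)
  out$straight <- out$axis_ratio < 0.2
  out
}

empty_fibers <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0),
             length_um = numeric(0), orientation_deg = numeric(0),
             axis_ratio = numeric(0), waviness = numeric(0),
             n_px = integer(0), straight = logical(0))
}

#' Collagen fiber orientation disorder (CFOD)
#'
#' Straight fibers (axis ratio < 0.2) are binned by orientation into
#' \code{nbins} bins over [0, 180). A length-weighted orientation
#' co-occurrence matrix accumulates \code{w_i * w_j} over all admitted fiber
#' pairs in the ROI; CFOD is the Shannon entropy of the normalized matrix
#' divided by \code{log(nbins^2)}, so it lies in [0, 1]: 0 for perfectly
#' parallel fibers, approaching 1 for uniformly distributed orientations.
#' Invariant to a common rescaling of the lengths.
#'
#' @param fibers data.frame from \code{\link{detect_collagen_fibers}} (only
#'   rows with \code{straight == TRUE} are used when the column is present).
#' @param nbins orientation bins (36, i.e. 5 degrees each).
#' @return CFOD in [0, 1]; NA with fewer than two straight fibers.
#' @export
cfod <- function(fibers, nbins = 36) {
  if (!is.null(fibers$straight)) fibers <- fibers[fibers$straight, , drop = FALSE]
  if (nrow(fibers) < 2) return(NA_real_)
  b <- pmin(floor(fibers$orientation_deg / (180 / nbins)) + 1L, nbins)
  w <- fibers$length_um
  # bin-level weight totals; pair co-occurrence M[a,b] = W_a W_b minus the
  # self-pair diagonal contribution sum(w_i^2)
  W <- vapply(split(w, factor(b, levels = seq_len(nbins))), sum, numeric(1))
  S2 <- vapply(split(w^2, factor(b, levels = seq_len(nbins))), sum, numeric(1))
  M <- outer(W, W)
  diag(M) <- diag(M) - S2
  tot <- sum(M)
  if (tot <= 0) return(0)
  p <- M[M > 0] / tot
  ent <- -sum(p * log(p))
  if (ent <= 0) 0 else ent / log(nbins^2)
}

#' Fibroblast orientation entropy
#'
#' For each CAF nucleus with a defined major axis, the orientations of other
#' CAFs within \code{radius_um} are collected; the statistic is the Shannon
#' entropy of the pooled binned orientation distribution normalized to [0, 1].
#' Near-circular nuclei (axis ratio above \code{max_axis_ratio}) have no
#' meaningful orientation and are excluded.
#'
#' @param cafs data.frame with \code{x_um, y_um, orient_deg} and optionally
#'   \code{major_um, minor_um}.
#' @param radius_um pairing radius (64 um default, the largest clustering
#'   radius).
#' @param nbins orientation bins over [0, 180).
#' @param max_axis_ratio exclusion threshold for circular nuclei.
#' @return entropy in [0, 1]; NA when all CAFs are isolated or fewer than two
#'   oriented CAFs exist.
#' @export
fibroblast_orientation_entropy <- function(cafs, radius_um = 64, nbins = 36,
                                           max_axis_ratio = 0.95) {
  if (is.null(cafs) || nrow(cafs) < 2) return(NA_real_)
  if (all(c("major_um", "minor_um") %in% names(cafs))) {
    ar <- cafs$minor_um / pmax(cafs$major_um, 1e-9)
    cafs <- cafs[is.finite(cafs$orient_deg) & ar <= max_axis_ratio, ,
                 drop = FALSE]
  } else cafs <- cafs[is.finite(cafs$orient_deg), , drop = FALSE]
  if (nrow(cafs) < 2) return(NA_real_)
  pts <- as.matrix(cafs[, c("x_um", "y_um")])
  pooled <- integer(nbins)
  found <- FALSE
  r2 <- radius_um^2
  for (i in seq_len(nrow(pts))) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    nb <- which(d2 <= r2)
    nb <- nb[nb != i]
    if (length(nb) == 0) next
    found <- TRUE
    b <- pmin(floor((cafs$orient_deg[nb] %% 180) / (180 / nbins)) + 1L, nbins)
    pooled <- pooled + tabulate(b, nbins)
  }
  if (!found) return(NA_real_)
  p <- pooled[pooled > 0] / sum(pooled)
  -sum(p * log(p)) / log(nbins)
}
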