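#' Macenko stain normalization
#'
#' Deconvolution-based color normalization. Stain vectors are estimated from
#' the optical density of tissue pixels by the Macenko percentile-on-plane
#' procedure: project ODs onto the plane of the two largest principal
#' components, take the robust extreme angles (alpha / 100-alpha percentiles),
#' and map the two resulting unit vectors to the reference hematoxylin/eosin
#' vectors. Concentrations are remapped so their 99th percentiles match the
#' reference maxima, and the image is reconstructed in the reference stain
#' basis.
#'
#' @param image x-by-y-by-3 RGB array in (0, 1].
#' @param tissue_mask optional logical matrix restricting estimation to tissue
#'   pixels (computed with \code{\link{compute_tissue_mask}} if NULL).
#' @param ref_stains 2x3 reference unit stain OD matrix (rows: H, E).
#' @param ref_max_conc reference 99th-percentile concentrations.
#' @param alpha angle percentile (Macenko's robust extreme).
#' @param beta minimum OD for a pixel to enter estimation.
#' @return normalized image, same shape, clipped to [0, 1]; the estimated
#'   stain matrix is attached as attribute \code{"stains"}. A degenerate OD
#'   covariance (single-color image or too few tissue pixels) falls back to
#'   returning the input unchanged with a warning.
#' @export
macenko_normalize <- function(image, tissue_mask = NULL,
                              ref_stains = rbind(h = c(0.65, 0.70, 0.29),
                                                 e = c(0.07, 0.99, 0.11)),
                              ref_max_conc = c(1.9705, 1.0308),
                              alpha = 1, beta = 0.15) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (is.null(tissue_mask)) tissue_mask <- compute_tissue_mask(image)
  dims <- dim(image)
  V <- matrix(image, ncol = 3)
  od <- -log(pmax(V, 1 / 256))
  idx <- which(as.vector(tissue_mask) & matrixStats_rowMax(od) > beta)
  if (length(idx) < 100) {
    warning("too few tissue pixels for stain estimation; returning input")
    return(image)
  }
  odt <- od[idx, , drop = FALSE]
  cv <- stats::cov(odt)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1e-12)) {
    warning("degenerate optical-density covariance; returning input")
    return(image)
  }
  plane <- ev$vectors[, 1:2]
  # orient basis so projections are mostly positive
  for (j in 1:2) if (sum(odt %*% plane[, j]) < 0) plane[, j] <- -plane[, j]
  proj <- odt %*% plane
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  v1 <- plane %*% c(cos(q[1]), sin(q[1]))
  v2 <- plane %*% c(cos(q[2]), sin(q[2]))
  # hematoxylin = the vector closer to the reference H direction
  refh <- ref_stains[1, ] / sqrt(sum(ref_stains[1, ]^2))
  if (sum(v1 * refh) >= sum(v2 * refh)) He <- cbind(v1, v2) else He <- cbind(v2, v1)
  He <- apply(He, 2, function(v) pmax(v, 0))
  He <- sweep(He, 2, sqrt(colSums(He^2)), "/")
  # concentrations for all pixels: solve od' = He %*% C  (least squares)
  C <- qr.solve(He, t(od))                       # 2 x npix
  mx <- apply(C, 1, stats::quantile, probs = 0.99)
  mx[mx <= 0] <- 1
  C <- C * (ref_max_conc / mx)
  S <- ref_stains / sqrt(rowSums(ref_stains^2))
  od_new <- t(S) %*% C                           # 3 x npix
  out <- array(pmin(pmax(exp(-t(od_new)), 0), 1), dims)
  attr(out, "stains") <- t(He)
  out
}

# rowMaxs without matrixStats
matrixStats_rowMax <- function(m) pmax(m[, 1], m[, 2], m[, 3])
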