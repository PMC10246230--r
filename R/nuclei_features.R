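#' Rasterize nuclei into a label image
#'
#' Each nucleus is drawn from its ellipse geometry (\code{major_um, minor_um,
#' orient_deg}, axis lengths in microns), from a \code{wkt_polygon}, or as a
#' 5 um-diameter disk when no geometry is given. Label i corresponds to row i
#' of the nuclei table; every nucleus covers at least its centroid pixel.
#'
#' @param nuclei nuclei table with \code{x_um, y_um} and optional geometry.
#' @param dim_xy integer c(width, height) of the target raster in pixels.
#' @param mpp microns per pixel of the target raster.
#' @return integer matrix of nucleus labels (0 = background).
#' @export
rasterize_nuclei <- function(nuclei, dim_xy, mpp) {
  lab <- matrix(0L, dim_xy[1], dim_xy[2])
  if (nrow(nuclei) == 0) return(lab)
  has_ellipse <- all(c("major_um", "minor_um") %in% names(nuclei))
  has_wkt <- "wkt_polygon" %in% names(nuclei)
  for (i in seq_len(nrow(nuclei))) {
    cx <- nuclei$x_um[i]; cy <- nuclei$y_um[i]
    if (has_wkt && !is.na(nuclei$wkt_polygon[i]) &&
        nzchar(nuclei$wkt_polygon[i])) {
      poly <- parse_wkt_polygon(nuclei$wkt_polygon[i])
      x0 <- max(1L, floor(min(poly[, 1]) / mpp))
      x1 <- min(dim_xy[1], ceiling(max(poly[, 1]) / mpp) + 1L)
      y0 <- max(1L, floor(min(poly[, 2]) / mpp))
      y1 <- min(dim_xy[2], ceiling(max(poly[, 2]) / mpp) + 1L)
      if (x1 < x0 || y1 < y0) next
      gx <- ((x0:x1) - 0.5) * mpp
      gy <- ((y0:y1) - 0.5) * mpp
      pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
      inside <- point_in_polygon(pts, poly)
      idx <- which(matrix(inside, length(gx)), arr.ind = TRUE)
      if (nrow(idx) > 0)
        lab[cbind(idx[, 1] + x0 - 1L, idx[, 2] + y0 - 1L)] <- i
    } else {
      a <- if (has_ellipse) nuclei$major_um[i] / 2 else 2.5
      b <- if (has_ellipse) nuclei$minor_um[i] / 2 else 2.5
      th <- if ("orient_deg" %in% names(nuclei) &&
                !is.na(nuclei$orient_deg[i]))
        nuclei$orient_deg[i] * pi / 180 else 0
      x0 <- max(1L, floor((cx - a) / mpp)); x1 <- min(dim_xy[1], ceiling((cx + a) / mpp) + 1L)
      y0 <- max(1L, floor((cy - a) / mpp)); y1 <- min(dim_xy[2], ceiling((cy + a) / mpp) + 1L)
      if (x1 < x0 || y1 < y0) next
      xs <- ((x0:x1) - 0.5) * mpp - cx
      ys <- ((y0:y1) - 0.5) * mpp - cy
      dx <- matrix(xs, length(xs), length(ys))
      dy <- matrix(ys, length(xs), length(ys), byrow = TRUE)
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      idx <- which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
      if (nrow(idx) > 0)
        lab[cbind(idx[, 1] + x0 - 1L, idx[, 2] + y0 - 1L)] <- i
    }
    px <- min(max(floor(cx / mpp) + 1L, 1L), dim_xy[1])
    py <- min(max(floor(cy / mpp) + 1L, 1L), dim_xy[2])
    if (lab[px, py] == 0L) lab[px, py] <- i
  }
  lab
}

# Even-odd rule point-in-polygon, vectorized over points.
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_thresh <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2 || max(v) <= min(v)) return(Inf)
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = 257),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# shift a matrix by (dx, dy), zero fill (block copy; fast)
shift_mat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  sx <- max(1L, 1L + dx):min(nr, nr + dx)
  sy <- max(1L, 1L + dy):min(nc, nc + dy)
  if (length(sx) < 1 || length(sy) < 1) return(out)
  out[sx - dx, sy - dy] <- m[sx, sy]
  out
}

# separable 1-D convolution along rows (axis 1) or columns (axis 2);
# compiled kernel (zero padding)
conv1d <- function(m, k, axis = 1) conv_sep(m, k, as.integer(axis))

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-threshold hysteresis. The high
#' threshold is the Otsu split of the gradient magnitudes (within \code{mask}
#' if given); the low threshold is \code{low_ratio} times the high.
#' Convolutions are separable shift-and-add passes (fast for the small
#' kernels involved).
#'
#' @param img numeric matrix in [0, 1].
#' @param sigma_px Gaussian smoothing sigma in pixels.
#' @param mask optional logical matrix restricting threshold estimation and
#'   output.
#' @param low_ratio low/high hysteresis threshold ratio.
#' @param min_grad absolute floor on the high threshold (gradient units), so
#'   featureless noise produces no edges.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma_px = 1, mask = NULL, low_ratio = 0.5,
                        min_grad = 0.03) {
  g <- gauss_kernel1d(sigma_px)
  sm <- conv1d(conv1d(img, g, 1), g, 2)
  gx <- conv1d(conv1d(sm, c(-1, 0, 1), 1), c(1, 2, 1) / 4, 2)
  gy <- conv1d(conv1d(sm, c(-1, 0, 1), 2), c(1, 2, 1) / 4, 1)
  mag <- sqrt(gx^2 + gy^2)
  nr <- nrow(mag); nc <- ncol(mag)
  # zero-fill convolution makes spurious ridges along the frame; blank a
  # kernel-radius margin
  mrg <- ceiling(3 * sigma_px) + 2L
  if (nr > 2 * mrg && nc > 2 * mrg) {
    mag[c(seq_len(mrg), nr - seq_len(mrg) + 1L), ] <- 0
    mag[, c(seq_len(mrg), nc - seq_len(mrg) + 1L)] <- 0
  }
  vals <- if (is.null(mask)) mag[mag > 0] else mag[mask & mag > 0]
  # the absolute floor keeps pure sensor noise from defining the Otsu split
  hi <- max(otsu_thresh(vals), min_grad)
  lo <- low_ratio * hi
  # candidate pixels, then non-maximum suppression only there: compare with
  # the two neighbors along the gradient direction, quantized to 4 sectors
  cand <- mag >= lo
  if (!is.null(mask)) cand <- cand & mask
  idx <- which(cand)
  if (length(idx) == 0) return(matrix(FALSE, nr, nc))
  sec <- (floor((atan2(gy[idx], gx[idx]) %% pi + pi / 8) / (pi / 4)) %% 4) + 1
  offs <- c(1, 1 + nr, nr, nr - 1)  # flat-index offsets for sectors 1..4
  off <- offs[sec]
  m0 <- mag[idx]
  keep <- m0 >= mag[pmin(pmax(idx + off, 1L), nr * nc)] &
    m0 >= mag[pmin(pmax(idx - off, 1L), nr * nc)]
  weak <- matrix(FALSE, nr, nc)
  weak[idx[keep]] <- TRUE
  strong_idx <- idx[keep][m0[keep] >= hi]
  if (length(strong_idx) == 0) return(matrix(FALSE, nr, nc))
  lab <- label8(weak)
  keep_lab <- unique(lab[strong_idx])
  weak & matrix(lab %in% keep_lab, nr, nc)
}

#' Deep-classifier conformity ratios
#'
#' From the subclass probability vector: TILs activation = p(plasma) over
#' p(TILs superclass); epithelial atypia = p(cancer) over p(epithelial
#' superclass); CAF epithelialization = p(fibroblast) over p(fibroblast) +
#' p(cancer). A zero denominator yields NA. Ratios are invariant to rescaling
#' the probability vector by a positive constant.
#'
#' @param probs data.frame/matrix with the six \code{prob_*} columns (or bare
#'   subclass-named columns in schema order).
#' @return data.frame with columns \code{tils_activation, epithelial_atypia,
#'   caf_epithelialization}, one row per input row.
#' @export
deep_ratios <- function(probs) {
  probs <- as.data.frame(probs)
  pc <- prob_cols()
  if (!all(pc %in% names(probs))) names(probs) <- pc
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    tils_activation = safe_div(probs$prob_plasma,
                               probs$prob_plasma + probs$prob_lymphocyte),
    epithelial_atypia = safe_div(probs$prob_cancer_epith,
                                 probs$prob_cancer_epith +
                                   probs$prob_normal_epith),
    caf_epithelialization = safe_div(probs$prob_fibroblast,
                                     probs$prob_fibroblast +
                                       probs$prob_cancer_epith))
}

# Align computeFeatures output (rows for present labels only) to 1..n.
align_labels <- function(mat, present, n) {
  out <- matrix(NA_real_, n, ncol(mat), dimnames = list(NULL, colnames(mat)))
  out[present, ] <- mat
  out
}

#' Standard per-nucleus morphology features
#'
#' Size/shape statistics from the rasterized instance masks; intensity mean
#' and sd, chromatin clumping (fraction of Canny edge pixels inside the
#' nucleus), and Haralick texture statistics (contrast, correlation, energy,
#' homogeneity, entropy; 32 gray levels, distance 1) when an image is given.
#' Nuclei rasterizing below 10 pixels get shape-only features (texture NA).
#'
#' @param nuclei nuclei table.
#' @param lab nucleus label image from \code{\link{rasterize_nuclei}}.
#' @param image intensity matrix co-registered with \code{lab} (hematoxylin
#'   proxy), or NULL for shape-only features.
#' @param mpp microns per pixel of \code{lab}.
#' @param edge_map optional precomputed Canny edge map (logical matrix); if
#'   NULL and an image is present it is computed with sigma 1 px.
#' @return data.frame, one row per nucleus.
#' @export
nucleus_standard_features <- function(nuclei, lab, image = NULL, mpp = 0.5,
                                      edge_map = NULL) {
  n <- nrow(nuclei)
  if (n == 0) return(data.frame())
  present <- sort(unique(lab[lab > 0]))
  relab <- lab
  relab[lab > 0] <- match(lab[lab > 0], present)
  sf <- EBImage::computeFeatures.shape(relab)
  mf <- EBImage::computeFeatures.moment(relab)
  npx <- tabulate(lab[lab > 0], nbins = n)
  out <- data.frame(
    area_um2 = align_labels(sf, present, n)[, "s.area"] * mpp^2,
    perimeter_um = align_labels(sf, present, n)[, "s.perimeter"] * mpp)
  mom <- align_labels(mf, present, n)
  out$major_um <- mom[, "m.majoraxis"] * mpp
  out$eccentricity <- mom[, "m.eccentricity"]
  out$minor_um <- out$major_um * sqrt(pmax(1 - out$eccentricity^2, 0))
  out$orient_deg <- (-mom[, "m.theta"] %% pi) * 180 / pi
  # solidity and boundary fractal dimension per nucleus (small crops);
  # pixel lists computed in one pass over the label image
  out$solidity <- NA_real_
  out$fractal_dim <- NA_real_
  on_idx <- which(lab > 0)
  pix_by_lab <- split(on_idx, lab[on_idx])
  nr_lab <- nrow(lab)
  for (i in present) {
    pix <- pix_by_lab[[as.character(i)]]
    ij <- cbind((pix - 1L) %% nr_lab + 1L, (pix - 1L) %/% nr_lab + 1L)
    if (nrow(ij) < 3) next
    hull <- grDevices::chull(ij)
    hp <- ij[hull, , drop = FALSE]
    ha <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                    c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2 +
      nrow(hp) / 2 + 1   # pixel-hull area correction
    out$solidity[i] <- min(nrow(ij) / ha, 1)
    if (nrow(ij) >= 12) {
      crop <- matrix(FALSE, diff(range(ij[, 1])) + 3,
                     diff(range(ij[, 2])) + 3)
      crop[cbind(ij[, 1] - min(ij[, 1]) + 2, ij[, 2] - min(ij[, 2]) + 2)] <- TRUE
      out$fractal_dim[i] <- fractal_dimension(crop)
    }
  }
  if (!is.null(image)) {
    bf <- align_labels(EBImage::computeFeatures.basic(relab, image),
                       present, n)
    out$intensity_mean <- bf[, "b.mean"]
    out$intensity_sd <- bf[, "b.sd"]
    if (is.null(edge_map)) edge_map <- canny_edges(image, sigma_px = 1)
    edge_counts <- tabulate(lab[edge_map & lab > 0], nbins = n)
    out$chromatin_clumping <- ifelse(npx > 0, edge_counts / npx, NA_real_)
    hf <- align_labels(
      EBImage::computeFeatures.haralick(relab, image,
                                        haralick.nbins = 32,
                                        haralick.scales = 1),
      present, n)
    out$haralick_contrast <- hf[, "h.con.s1"]
    out$haralick_correlation <- hf[, "h.cor.s1"]
    out$haralick_energy <- hf[, "h.asm.s1"]
    out$haralick_homogeneity <- hf[, "h.idm.s1"]
    out$haralick_entropy <- hf[, "h.ent.s1"]
    small <- npx < 10
    tex_cols <- c("intensity_sd", "chromatin_clumping", "haralick_contrast",
                  "haralick_correlation", "haralick_energy",
                  "haralick_homogeneity", "haralick_entropy")
    out[small, tex_cols] <- NA_real_
  }
  out
}

# Exclusive rim label image: pixel belongs to nucleus i iff background, within
# rim_um of nucleus i, and within rim_um of no other nucleus (pixels reachable
# from two nuclei are excluded from both). Uses grayscale min/max dilation.
exclusive_rims <- function(lab, mpp, rim_um = 4, allowed = NULL) {
  r <- max(1L, round(rim_um / mpp))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  M <- max(lab)
  if (M == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  dmax <- as.matrix(EBImage::dilate(EBImage::Image(lab / M), brush)) * M
  inv <- ifelse(lab > 0, (M + 1 - lab), 0)
  dinv <- as.matrix(EBImage::dilate(EBImage::Image(inv / (M + 1)), brush)) *
    (M + 1)
  dmin <- ifelse(dinv > 0.5, M + 1 - dinv, 0)
  rim <- ifelse(lab == 0 & dmax > 0.5 & abs(dmax - dmin) < 0.25,
                round(dmax), 0L)
  if (!is.null(allowed)) rim[!allowed] <- 0L
  matrix(as.integer(rim), nrow(lab), ncol(lab))
}

#' Cytoplasmic rim texture and staining
#'
#' Intensity statistics within \code{rim_um} of each nuclear boundary
#' (dilated mask minus the nucleus), excluding pixels of other nuclei and
#' pixels reachable from more than one nucleus. Empty rims yield NA.
#'
#' @param nuclei nuclei table.
#' @param lab nucleus label image.
#' @param image intensity matrix.
#' @param mpp microns per pixel.
#' @param rim_um rim width (4 um default).
#' @param allowed optional logical matrix restricting rims (e.g. to stromal
#'   matrix).
#' @param rim_owner optional precomputed exclusive-rim label matrix (reused
#'   across calls with different \code{allowed} masks).
#' @param haralick compute rim Haralick statistics (skip for intensity-only
#'   uses).
#' @return data.frame with \code{rim_mean, rim_sd, rim_haralick_contrast,
#'   rim_haralick_homogeneity, rim_npx}, one row per nucleus.
#' @export
cytoplasmic_rim_features <- function(nuclei, lab, image, mpp = 0.5,
                                     rim_um = 4, allowed = NULL,
                                     rim_owner = NULL, haralick = TRUE) {
  n <- nrow(nuclei)
  if (n == 0) return(data.frame())
  rim <- if (is.null(rim_owner)) exclusive_rims(lab, mpp, rim_um, allowed)
         else rim_owner
  if (!is.null(allowed) && !is.null(rim_owner)) rim[!allowed] <- 0L
  npx <- tabulate(rim[rim > 0], nbins = n)
  sums <- rep(0, n); sqs <- rep(0, n)
  on <- rim > 0
  if (any(on)) {
    v <- image[on]; l <- rim[on]
    sums <- vapply(split(v, factor(l, levels = seq_len(n))), sum, numeric(1))
    sqs <- vapply(split(v^2, factor(l, levels = seq_len(n))), sum, numeric(1))
  }
  mean_i <- ifelse(npx > 0, sums / npx, NA_real_)
  var_i <- ifelse(npx > 1, pmax(sqs / npx - mean_i^2, 0), NA_real_)
  out <- data.frame(rim_mean = unname(mean_i),
                    rim_sd = unname(sqrt(var_i)),
                    rim_npx = npx)
  present <- sort(unique(rim[rim > 0]))
  out$rim_haralick_contrast <- NA_real_
  out$rim_haralick_homogeneity <- NA_real_
  if (haralick && length(present) > 0) {
    rrel <- rim
    rrel[rim > 0] <- match(rim[rim > 0], present)
    hf <- try(EBImage::computeFeatures.haralick(rrel, image,
                                                haralick.nbins = 32,
                                                haralick.scales = 1),
              silent = TRUE)
    if (!inherits(hf, "try-error") && !is.null(hf)) {
      hfa <- align_labels(hf, present, n)
      out$rim_haralick_contrast <- hfa[, "h.con.s1"]
      out$rim_haralick_homogeneity <- hfa[, "h.idm.s1"]
    }
  }
  out
}
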