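#' Point pattern over the analyzed tissue
#'
#' @param points two-column matrix/data.frame of (x, y) in microns.
#' @param area_um2 tissue area over which densities are normalized (must be
#'   positive).
#' @return list of class \code{"point_pattern"}.
#' @export
point_pattern <- function(points, area_um2) {
  stopifnot(area_um2 > 0)
  points <- as.matrix(points)
  structure(list(points = points, area_um2 = area_um2),
            class = "point_pattern")
}

# Count, for each center, the neighbors within distance r (inclusive).
# Grid-bucket implementation; exact, matches brute force including ties.
count_within <- function(centers, neighbors, r, exclude_self = FALSE) {
  nc <- nrow(centers)
  if (nc == 0) return(integer(0))
  nn <- nrow(neighbors)
  if (nn == 0) return(integer(nc))
  cell <- function(p) cbind(floor(p[, 1] / r), floor(p[, 2] / r))
  ncell <- cell(neighbors)
  key <- paste(ncell[, 1], ncell[, 2])
  buckets <- split(seq_len(nn), key)
  ccell <- cell(centers)
  counts <- integer(nc)
  r2 <- r * r
  for (i in seq_len(nc)) {
    cnt <- 0L
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(ccell[i, 1] + dx, ccell[i, 2] + dy)]]
      if (is.null(b)) next
      d2 <- (neighbors[b, 1] - centers[i, 1])^2 +
        (neighbors[b, 2] - centers[i, 2])^2
      cnt <- cnt + sum(d2 <= r2)
    }
    if (exclude_self) cnt <- cnt - 1L  # center counted against itself
    counts[i] <- cnt
  }
  counts
}

#' Global cell density
#'
#' Count of cells of a class normalized to the analyzed tissue area.
#'
#' @param pp a \code{\link{point_pattern}} of the class of interest.
#' @return cells per mm^2.
#' @export
global_density <- function(pp) {
  if (pp$area_um2 <= 0) stop("zero tissue area")
  nrow(pp$points) / (pp$area_um2 / 1e6)
}

#' Local cell density
#'
#' Mean, over cells of the center class, of the number of neighbor-class cells
#' within radius r (inclusive distance comparison). When center and neighbor
#' classes coincide the center cell is excluded from its own count.
#'
#' @param centers,neighbors (x, y) matrices in microns.
#' @param r radius in microns (16, 32 or 64 in the standard catalogue).
#' @param same_class logical; TRUE when the two sets are the same cells.
#' @return mean neighbor count; NA if there are no center cells.
#' @export
local_density <- function(centers, neighbors, r, same_class = FALSE) {
  centers <- as.matrix(centers); neighbors <- as.matrix(neighbors)
  if (nrow(centers) == 0) return(NA_real_)
  mean(count_within(centers, neighbors, r, exclude_self = same_class))
}

#' Single-radius clustering ratio against complete spatial randomness
#'
#' Ripley-K-style statistic at one distance: the mean local neighbor count is
#' normalized by its expectation under complete spatial randomness (CSR),
#' \code{lambda * pi * r^2}, with \code{lambda} the global neighbor intensity
#' over the analyzed tissue area. Equals 1 in expectation under CSR; values
#' above 1 indicate clustering beyond chance. No edge correction is applied
#' (a small negative bias near borders, documented, as tissue extent is large
#' relative to r <= 64 um).
#'
#' @param centers,neighbors (x, y) matrices in microns.
#' @param r radius in microns.
#' @param area_um2 analyzed tissue area.
#' @param same_class exclude the center cell from its own count.
#' @return ratio; NA when there are no centers or the neighbor intensity is 0.
#' @export
clustering_ratio <- function(centers, neighbors, r, area_um2,
                             same_class = FALSE) {
  centers <- as.matrix(centers); neighbors <- as.matrix(neighbors)
  if (nrow(centers) == 0 || nrow(neighbors) == 0) return(NA_real_)
  n_eff <- if (same_class) nrow(neighbors) - 1L else nrow(neighbors)
  lambda <- n_eff / area_um2
  if (lambda <= 0) return(NA_real_)
  local_density(centers, neighbors, r, same_class) / (lambda * pi * r^2)
}
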