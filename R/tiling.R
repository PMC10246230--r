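#' Tissue mask from an intensity image
#'
#' Excludes near-white background (all channels above a luminosity threshold)
#' and saturated pen-color markings (red/green/blue felt pen). Grayscale input
#' is thresholded on luminosity only.
#'
#' @param image matrix (grayscale) or x-by-y-by-3 array in [0, 1].
#' @param white_thresh luminosity above which a pixel counts as background.
#' @param pen_sat_thresh chroma (max-min channel spread relative to max) above
#'   which a pixel counts as pen marking.
#' @return logical matrix, TRUE = tissue.
#' @export
compute_tissue_mask <- function(image, white_thresh = 0.88,
                                pen_sat_thresh = 0.5) {
  if (length(dim(image)) == 3) {
    mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
    mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
    white <- mn > white_thresh
    pen <- (mx - mn) / pmax(mx, 1e-6) > pen_sat_thresh
    !(white | pen)
  } else {
    image < white_thresh
  }
}

#' Tile a slide into square ROIs
#'
#' Non-overlapping grid tiles from the slide origin. Tissue fraction is the
#' non-background area of the region mask over the tile's true area (partial
#' edge tiles are kept and evaluated on their true area); tiles below
#' \code{min_tissue_frac} are dropped (comparison is inclusive, >=). Each
#' retained tile carries per-class areas and a saliency score.
#'
#' @param slide a \code{\link{slide_panoptic}}.
#' @param side_um tile side (512 for nuclear-morphology ROIs, 256 for
#'   stromal-matrix ROIs).
#' @param min_tissue_frac minimum tissue composition to retain a tile.
#' @param band_um width of the epithelium-adjacent stromal band entering the
#'   saliency score.
#' @param keep_all if TRUE, return dropped tiles too (flagged by
#'   \code{retained}).
#' @return data.frame with one row per tile: \code{x0_um, y0_um, w_um, h_um,
#'   tissue_frac, area_<class>_um2 ..., saliency, retained}.
#' @export
tile_slide <- function(slide, side_um = 512, min_tissue_frac = 0.5,
                       band_um = 32, keep_all = FALSE) {
  schema <- slide$schema %||% hips_schema()
  rc <- schema$region_classes
  mask <- slide$region_mask
  mpp <- slide$mpp
  side_px <- side_um / mpp
  nx <- ceiling(nrow(mask) / side_px)
  ny <- ceiling(ncol(mask) / side_px)
  # stroma within band_um of epithelium, computed slide-wide so adjacency
  # across tile borders counts
  epith <- mask == rc[["epithelium"]]
  near_epith <- if (any(epith)) {
    dt <- EBImage::distmap(!epith)  # distance (px) to nearest epithelium
    dt > 0 & dt <= band_um / mpp
  } else matrix(FALSE, nrow(mask), ncol(mask))
  stroma_band <- near_epith & mask == rc[["stroma"]]

  rows <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    x0 <- (ix - 1L) * side_px + 1L
    y0 <- (iy - 1L) * side_px + 1L
    x1 <- min(nrow(mask), ix * side_px)
    y1 <- min(ncol(mask), iy * side_px)
    sub <- mask[x0:x1, y0:y1]
    npx <- length(sub)
    tab <- tabulate(as.vector(sub) + 1L, nbins = 6L)
    areas <- tab * mpp^2
    names(areas) <- paste0("area_", names(rc), "_um2")
    tissue_frac <- 1 - tab[1] / npx
    band_area <- sum(stroma_band[x0:x1, y0:y1]) * mpp^2
    tile_area <- npx * mpp^2
    nonnecro <- (sum(tab[-1]) - tab[rc[["necrosis"]] + 1L]) * mpp^2
    sal <- if (nonnecro <= 0) 0 else
      (band_area / tile_area) * (areas[["area_epithelium_um2"]] / tile_area) /
        (nonnecro / tile_area)
    k <- k + 1L
    rows[[k]] <- data.frame(
      tile_id = sprintf("t%d_%d", ix, iy),
      x0_um = (x0 - 1L) * mpp, y0_um = (y0 - 1L) * mpp,
      w_um = (x1 - x0 + 1L) * mpp, h_um = (y1 - y0 + 1L) * mpp,
      tissue_frac = tissue_frac, t(areas),
      stroma_band_um2 = band_area, saliency = unname(sal),
      retained = tissue_frac >= min_tissue_frac,
      stringsAsFactors = FALSE)
  }
  tiles <- do.call(rbind, rows)
  if (!keep_all) tiles <- tiles[tiles$retained, , drop = FALSE]
  rownames(tiles) <- NULL
  tiles
}

#' Saliency score of one ROI
#'
#' Saliency = (fraction of the tile that is stroma within \code{band_um} of an
#' epithelial nest x fraction that is epithelium) / (fraction that is
#' non-necrotic tissue). Zero when epithelium or adjacent stroma is absent and
#' when the tile is fully necrotic. Computed on tile area fractions, so the
#' score is dimensionless; a common scaling leaves rankings and normalized
#' weights unchanged.
#'
#' @param region_mask integer label matrix for the tile (or slide).
#' @param mpp microns per pixel.
#' @param band_um stromal band width.
#' @return nonnegative scalar.
#' @export
compute_saliency <- function(region_mask, mpp = 1, band_um = 32) {
  rc <- hips_schema()$region_classes
  epith <- region_mask == rc[["epithelium"]]
  tile_area <- length(region_mask)
  if (!any(epith)) return(0)
  dt <- EBImage::distmap(!epith)
  band <- dt > 0 & dt <= band_um / mpp & region_mask == rc[["stroma"]]
  nonnecro <- sum(region_mask != rc[["background"]] &
                    region_mask != rc[["necrosis"]]) / tile_area
  if (nonnecro <= 0) return(0)
  unname((sum(band) / tile_area) * (sum(epith) / tile_area) / nonnecro)
}
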