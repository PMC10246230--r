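# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally (connected components on the label-adjacency graph).
label8 <- function(binmask) {
  lab <- EBImage::bwlabel(binmask)
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  k1 <- a > 0 & b > 0 & a != b
  e1 <- cbind(a[k1], b[k1])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  k2 <- a > 0 & b > 0 & a != b
  edges <- rbind(e1, cbind(a[k2], b[k2]))
  if (nrow(edges) == 0) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(n)]
  relab <- match(memb, unique(memb))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Downsample a label mask by an integer factor (nearest neighbor on labels).
downsample_mask <- function(mask, factor = 2L) {
  mask[seq(1L, nrow(mask), by = factor), seq(1L, ncol(mask), by = factor)]
}

#' Extract admitted region instances of one class
#'
#' Per class: binary mask -> binary dilation with a 5x5 square element (at
#' 2 um/px, i.e. 10x10 um, removing small artifacts) -> fill holes smaller
#' than \code{min_hole_um2} -> 8-connected components -> drop components with
#' area <= \code{min_area_um2}. The hole count records the retained (large)
#' holes of each instance.
#'
#' @param region_mask integer label matrix, conventionally at 2 um/px
#'   (downsample a 1 um/px mask with \code{factor = 2} first).
#' @param class_code region class integer code.
#' @param mpp microns per pixel of \code{region_mask}.
#' @param min_area_um2 admission area filter (default 128^2 um^2).
#' @param min_hole_um2 holes below this area are filled (default 48^2 um^2).
#' @param dilate_px side of the square dilation element in pixels.
#' @return list of region instances: each a list with \code{instance_id,
#'   class_code, mask} (cropped logical matrix), \code{x0, y0} (pixel offset of
#'   the crop, 0-based), \code{area_um2, n_holes, mpp}.
#' @export
extract_region_instances <- function(region_mask, class_code, mpp = 2,
                                     min_area_um2 = 128^2,
                                     min_hole_um2 = 48^2, dilate_px = 5) {
  bin <- region_mask == class_code
  if (!any(bin)) return(list())
  kern <- matrix(1, dilate_px, dilate_px)
  bin <- EBImage::dilate(bin, kern) > 0
  lab <- label8(bin)
  out <- list()
  for (i in seq_len(max(lab))) {
    ij <- which(lab == i, arr.ind = TRUE)
    x0 <- min(ij[, 1]); x1 <- max(ij[, 1])
    y0 <- min(ij[, 2]); y1 <- max(ij[, 2])
    comp <- matrix(FALSE, x1 - x0 + 3L, y1 - y0 + 3L)  # 1px pad for holes
    comp[cbind(ij[, 1] - x0 + 2L, ij[, 2] - y0 + 2L)] <- TRUE
    # holes = background components not touching the pad border
    bg <- EBImage::bwlabel(!comp)
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    hole_labs <- setdiff(unique(as.vector(bg)), c(0L, border_labs))
    n_holes <- 0L
    for (h in hole_labs) {
      harea <- sum(bg == h) * mpp^2
      if (harea < min_hole_um2) comp[bg == h] <- TRUE else n_holes <- n_holes + 1L
    }
    area <- sum(comp) * mpp^2
    if (area <= min_area_um2) next
    out[[length(out) + 1L]] <- list(
      instance_id = sprintf("c%d_i%d", class_code, length(out) + 1L),
      class_code = class_code, mask = comp,
      x0 = x0 - 2L, y0 = y0 - 2L,   # crop offset (0-based), includes pad
      area_um2 = area, n_holes = n_holes, mpp = mpp)
  }
  out
}

#' Shape features of a region instance
#'
#' Area, perimeter, circularity \code{4*pi*A/P^2}, convexity (area over convex
#' hull area), major/minor axis lengths, hole count, and box-counting fractal
#' dimension of the boundary.
#'
#' @param inst a region instance from \code{\link{extract_region_instances}}.
#' @return named numeric vector (micron units).
#' @export
region_shape_features <- function(inst) {
  mpp <- inst$mpp
  m <- inst$mask
  mf <- EBImage::computeFeatures.moment(m * 1L)
  area <- sum(m) * mpp^2
  perim <- perimeter_px(m) * mpp
  ij <- which(m, arr.ind = TRUE)
  hull <- grDevices::chull(ij)
  hp <- ij[hull, , drop = FALSE]
  hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                         c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2 * mpp^2
  ecc <- mf[1, "m.eccentricity"]
  c(area_um2 = unname(area), perimeter_um = unname(perim),
    circularity = unname(4 * pi * area / perim^2),
    convexity = unname(min(area / max(hull_area, area), 1)),
    major_axis_um = unname(mf[1, "m.majoraxis"] * mpp),
    minor_axis_um = unname(mf[1, "m.majoraxis"] * sqrt(1 - ecc^2) * mpp),
    eccentricity = unname(ecc),
    n_holes = inst$n_holes,
    fractal_dim = fractal_dimension(m))
}

#' Box-counting fractal dimension
#'
#' Least-squares slope of log N(s) versus log(1/s) over dyadic box sizes,
#' where N(s) counts boxes of side s containing foreground. In
#' \code{"boundary"} mode the foreground is the one-pixel boundary of the
#' mask (dimension ~1 for smooth outlines, higher for jagged ones); in
#' \code{"area"} mode it is the filled mask (~2 for solid shapes).
#'
#' @param mask logical matrix.
#' @param mode "boundary" or "area".
#' @return scalar dimension estimate; NA if fewer than 8 foreground pixels.
#' @export
fractal_dimension <- function(mask, mode = c("boundary", "area")) {
  mode <- match.arg(mode)
  fg <- if (mode == "boundary") mask & !shrink1(mask) else mask
  ij <- which(fg, arr.ind = TRUE)
  if (nrow(ij) < 8) return(NA_real_)
  ij[, 1] <- ij[, 1] - min(ij[, 1]); ij[, 2] <- ij[, 2] - min(ij[, 2])
  extent <- max(max(ij[, 1]), max(ij[, 2])) + 1L
  smax <- 2^floor(log2(max(extent / 2, 2)))
  sizes <- 2^(0:round(log2(smax)))
  counts <- vapply(sizes, function(s)
    nrow(unique(cbind(ij[, 1] %/% s, ij[, 2] %/% s))), numeric(1))
  keep <- counts > 1 | sizes == 1
  if (sum(keep) < 2) return(NA_real_)
  stats::coef(stats::lm(log(counts[keep]) ~ log(1 / sizes[keep])))[[2]]
}

# Boundary length in pixels from chain adjacencies among boundary pixels:
# axial steps weight 1, diagonal steps 1.3 (calibrated so digital disks give
# their true circumference within ~2% and axis-aligned squares within ~1%).
perimeter_px <- function(m) {
  b <- m & !shrink1(m)
  if (!any(b)) return(0)
  Ea <- sum(b[-nrow(b), ] & b[-1, ]) + sum(b[, -ncol(b)] & b[, -1])
  Ed <- sum(b[-nrow(b), -ncol(b)] & b[-1, -1]) +
    sum(b[-nrow(b), -1] & b[-1, -ncol(b)])
  if (Ea + Ed == 0) return(sum(b))  # isolated pixels
  1.0 * Ea + 1.3 * Ed
}

# 4-neighbor erosion used for boundary extraction (cheap, no kernel object)
shrink1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -nc, drop = FALSE])
  m & up & dn & lf & rt
}

# Embed an instance's cropped mask into full-frame pixel coordinates.
inst_full_mask <- function(inst, dim_xy) {
  full <- matrix(FALSE, dim_xy[1], dim_xy[2])
  ij <- which(inst$mask, arr.ind = TRUE)
  px <- ij[, 1] + inst$x0
  py <- ij[, 2] + inst$y0
  keep <- px >= 1 & px <= dim_xy[1] & py >= 1 & py <= dim_xy[2]
  full[cbind(px[keep], py[keep])] <- TRUE
  full
}

#' Tissue and cellular composition around a region instance
#'
#' The instance mask is distance-dilated to \code{band_um} and the composition
#' of the annulus (dilated minus original) is reported: per-region-class area
#' fraction of the annulus, and per-superclass nucleus density (cells/mm^2,
#' centroid-in-annulus). Annuli clipped at the slide edge use the clipped area.
#'
#' @param inst region instance (at \code{inst$mpp}).
#' @param region_mask full label mask at the same resolution.
#' @param nuclei nuclei table with \code{x_um, y_um, superclass}.
#' @param bands_um annulus outer radii.
#' @return named numeric vector, names like
#'   \code{band128_frac_stroma}, \code{band128_density_stromal_per_mm2}.
#' @export
neighborhood_composition <- function(inst, region_mask, nuclei,
                                     bands_um = c(128, 256)) {
  mpp <- inst$mpp
  rc <- hips_schema()$region_classes
  full <- inst_full_mask(inst, dim(region_mask))
  dt <- EBImage::distmap(!full) * mpp       # um to the instance
  out <- numeric(0)
  scs <- c("epithelial", "stromal", "tils")
  for (b in bands_um) {
    ann <- dt > 0 & dt <= b
    ann_area_um2 <- sum(ann) * mpp^2
    vals <- as.vector(region_mask[ann])
    tab <- tabulate(vals + 1L, nbins = 6L)
    fr <- if (ann_area_um2 > 0) tab / sum(tab) else rep(NA_real_, 6)
    names(fr) <- sprintf("band%d_frac_%s", b, names(rc))
    dens <- rep(0, length(scs))
    names(dens) <- sprintf("band%d_density_%s_per_mm2", b, scs)
    if (nrow(nuclei) > 0 && ann_area_um2 > 0) {
      px <- pmin(nrow(region_mask), floor(nuclei$x_um / mpp) + 1L)
      py <- pmin(ncol(region_mask), floor(nuclei$y_um / mpp) + 1L)
      inside <- ann[cbind(px, py)]
      for (s in scs) {
        cnt <- sum(inside & nuclei$superclass == s)
        dens[sprintf("band%d_density_%s_per_mm2", b, s)] <-
          cnt / (ann_area_um2 / 1e6)
      }
    } else if (ann_area_um2 == 0) dens[] <- NA_real_
    out <- c(out, fr, dens)
  }
  out
}

#' Cellular composition of an epithelial nest
#'
#' Counts contained nuclei per subclass (centroid-in-mask convention), the
#' nuclear-to-cytoplasmic area proxy (total nuclear area over nest area) and
#' the cytoplasm amount (nest area minus nuclear area). Nuclear areas come
#' from the ellipse geometry columns when present, else from polygon areas,
#' else a 5 um-diameter default.
#'
#' @param inst region instance.
#' @param nuclei nuclei table.
#' @return named numeric vector: \code{n_nuclei, n_low_grade, nc_ratio,
#'   cytoplasm_um2}, plus \code{n_<subclass>} counts.
#' @export
region_composition <- function(inst, nuclei) {
  mpp <- inst$mpp
  schema <- hips_schema()
  res <- c(n_nuclei = 0, n_low_grade = 0, nc_ratio = 0,
           cytoplasm_um2 = unname(inst$area_um2))
  cnt <- rep(0, 6); names(cnt) <- paste0("n_", schema$nucleus_subclasses)
  if (nrow(nuclei) > 0) {
    px <- floor(nuclei$x_um / mpp) + 1L - inst$x0
    py <- floor(nuclei$y_um / mpp) + 1L - inst$y0
    ok <- px >= 1 & px <= nrow(inst$mask) & py >= 1 & py <= ncol(inst$mask)
    ok[ok] <- inst$mask[cbind(px[ok], py[ok])]
    inside <- nuclei[ok, , drop = FALSE]
    if (nrow(inside) > 0) {
      tab <- table(factor(inside$subclass, levels = schema$nucleus_subclasses))
      cnt[] <- as.numeric(tab)
      narea <- nucleus_area_um2(inside)
      res["n_nuclei"] <- nrow(inside)
      res["n_low_grade"] <- sum(inside$subclass == "normal_epith")
      res["nc_ratio"] <- min(sum(narea) / inst$area_um2, 1)
      res["cytoplasm_um2"] <- max(inst$area_um2 - sum(narea), 0)
    }
  }
  c(res, cnt)
}

# Per-nucleus area from geometry columns.
nucleus_area_um2 <- function(nuclei) {
  if (all(c("major_um", "minor_um") %in% names(nuclei))) {
    pi * (nuclei$major_um / 2) * (nuclei$minor_um / 2)
  } else if ("wkt_polygon" %in% names(nuclei)) {
    vapply(nuclei$wkt_polygon, function(w) {
      if (is.na(w)) return(pi * 2.5^2)
      p <- parse_wkt_polygon(w)
      abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                c(p[-1, 1], p[1, 1]) * p[, 2])) / 2
    }, numeric(1), USE.NAMES = FALSE)
  } else rep(pi * 2.5^2, nrow(nuclei))
}
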