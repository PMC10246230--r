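#' Construct a validated slide-panoptic object
#'
#' Bundles one slide's semantic region mask, nuclei table, optional
#' co-registered intensity image, and resolution metadata. Probability vectors
#' are renormalized to sum to one and superclasses derived.
#'
#' Conventions: image/mask arrays are indexed \code{[x, y]} with the origin at
#' the top-left, x rightward, y downward; coordinates are in microns and the
#' pixel containing a point is \code{floor(coord / mpp) + 1} (half-open pixel
#' intervals).
#'
#' @param slide_id,patient_id identifiers.
#' @param mpp microns per pixel of \code{region_mask} (positive).
#' @param region_mask integer matrix of region class codes (see
#'   \code{\link{hips_schema}}).
#' @param nuclei data.frame with columns \code{nucleus_id}, \code{x_um},
#'   \code{y_um} and the six \code{prob_*} columns; optional ellipse geometry
#'   columns \code{major_um}, \code{minor_um}, \code{orient_deg}, or a
#'   \code{wkt_polygon} column.
#' @param image optional intensity array (matrix for grayscale or x-by-y-by-3
#'   for RGB) covering the same field of view at resolution \code{image_mpp}.
#' @param image_mpp microns per pixel of \code{image}.
#' @return An object of class \code{"slide_panoptic"}.
#' @export
slide_panoptic <- function(slide_id, mpp, region_mask, nuclei, image = NULL,
                           image_mpp = mpp, patient_id = slide_id) {
  schema <- hips_schema()
  stopifnot(is.numeric(mpp), length(mpp) == 1L, mpp > 0)
  region_mask <- matrix(as.integer(region_mask), nrow = nrow(region_mask))
  bad_codes <- setdiff(unique(as.vector(region_mask)), unname(schema$region_classes))
  if (length(bad_codes) > 0)
    stop("region mask contains unknown class codes: ",
         paste(bad_codes, collapse = ", "))
  nuclei <- normalize_nuclei(nuclei, schema)
  w_um <- nrow(region_mask) * mpp
  h_um <- ncol(region_mask) * mpp
  if (nrow(nuclei) > 0) {
    out <- nuclei$x_um < 0 | nuclei$x_um >= w_um |
           nuclei$y_um < 0 | nuclei$y_um >= h_um
    if (any(out))
      stop("nuclei outside mask bounds: ",
           paste(utils::head(nuclei$nucleus_id[out], 10), collapse = ", "))
  }
  structure(list(
    slide_id = as.character(slide_id), patient_id = as.character(patient_id),
    mpp = mpp, region_mask = region_mask, nuclei = nuclei,
    image = image, image_mpp = image_mpp,
    width_um = w_um, height_um = h_um, schema = schema
  ), class = "slide_panoptic")
}

# Validate/renormalize a nuclei table in place.
normalize_nuclei <- function(nuclei, schema = hips_schema()) {
  pc <- prob_cols(schema)
  nuclei <- as.data.frame(nuclei)
  if (nrow(nuclei) == 0) {
    need <- c("nucleus_id", "x_um", "y_um", pc)
    for (col in setdiff(need, names(nuclei))) nuclei[[col]] <- numeric(0)
    nuclei$superclass <- character(0)
    return(nuclei)
  }
  miss <- setdiff(c("nucleus_id", "x_um", "y_um", pc), names(nuclei))
  if (length(miss) > 0)
    stop("nuclei table missing columns: ", paste(miss, collapse = ", "))
  P <- as.matrix(nuclei[, pc])
  if (any(P < 0)) stop("negative nucleus class probabilities")
  s <- rowSums(P)
  if (any(s <= 0)) stop("nucleus probability vector sums to zero")
  P <- P / s
  nuclei[, pc] <- P
  nuclei$nucleus_id <- as.character(nuclei$nucleus_id)
  nuclei$superclass <- nucleus_superclass(P)
  nuclei$subclass <- schema$nucleus_subclasses[max.col(P, ties.method = "first")]
  nuclei
}

#' @export
print.slide_panoptic <- function(x, ...) {
  cat("slide_panoptic:", x$slide_id, sprintf("(patient %s)\n", x$patient_id))
  cat(sprintf("  field: %.0f x %.0f um at %g um/px%s\n", x$width_um, x$height_um,
              x$mpp, if (is.null(x$image)) "" else
                sprintf("; image at %g um/px", x$image_mpp)))
  cat(sprintf("  nuclei: %d (%s)\n", nrow(x$nuclei),
              paste(sprintf("%s=%d", names(table(x$nuclei$superclass)),
                            table(x$nuclei$superclass)), collapse = ", ")))
  invisible(x)
}

#' Load a slide's panoptic artifacts from disk
#'
#' @param region_mask_path single-channel TIFF or PNG label image; a sidecar
#'   JSON (same path plus \code{.json}) may carry \code{mpp}.
#' @param nuclei_path CSV (columns \code{nucleus_id, x_um, y_um, prob_*}) or
#'   GeoJSON FeatureCollection (Point/Polygon geometry, probs in properties).
#' @param image_path optional PNG/TIFF intensity image.
#' @param mpp microns per pixel; overrides the sidecar if given.
#' @param slide_id defaults to the mask file name.
#' @return A \code{\link{slide_panoptic}} object.
#' @export
load_panoptic <- function(region_mask_path, nuclei_path, image_path = NULL,
                          mpp = NULL, slide_id = NULL,
                          patient_id = NULL) {
  side <- paste0(region_mask_path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(mpp)) mpp <- meta$mpp
  if (is.null(mpp)) stop("mpp not given and no sidecar JSON found")
  mask <- read_label_image(region_mask_path)
  nuclei <- if (grepl("\\.(geojson|json)$", nuclei_path, ignore.case = TRUE)) {
    read_nuclei_geojson(nuclei_path)
  } else read_nuclei_csv(nuclei_path)
  img <- NULL
  image_mpp <- mpp
  if (!is.null(image_path)) {
    img <- read_intensity_image(image_path)
    iside <- paste0(image_path, ".json")
    if (file.exists(iside)) {
      im <- jsonlite::read_json(iside)
      if (!is.null(im$mpp)) image_mpp <- im$mpp
    }
  }
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]+$", "", basename(region_mask_path))
  if (is.null(patient_id)) patient_id <- slide_id
  slide_panoptic(slide_id, mpp, mask, nuclei, image = img,
                 image_mpp = image_mpp, patient_id = patient_id)
}

# -- raster IO ----------------------------------------------------------------

# Label images are stored with integer codes; PNG stores code/255 grayscale.
read_label_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- round(t(a) * 255)
  } else {
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- t(a)
  }
  matrix(as.integer(m), nrow = nrow(m))
}

write_label_image <- function(mask, path, mpp = NULL,
                              schema_version = hips_schema()$version) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(t(mask) / 255, path)
  } else {
    tiff::writeTIFF(t(mask) / 255, path, bits.per.sample = 8L)
  }
  if (!is.null(mpp))
    jsonlite::write_json(list(mpp = mpp, schema_version = schema_version),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_intensity_image <- function(path) {
  a <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else tiff::readTIFF(path)
  if (length(dim(a)) == 3) {
    aperm(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(2, 1, 3))
  } else t(a)
}

write_intensity_image <- function(img, path, mpp = NULL) {
  img <- pmin(pmax(img, 0), 1)
  a <- if (length(dim(img)) == 3) aperm(img, c(2, 1, 3)) else t(img)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(a, path)
  } else tiff::writeTIFF(a, path, bits.per.sample = 16L)
  if (!is.null(mpp))
    jsonlite::write_json(list(mpp = mpp), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

# -- nuclei IO ----------------------------------------------------------------

#' Read/write nuclei tables
#'
#' CSV dialect: columns \code{nucleus_id, x_um, y_um, prob_<subclass>...}, and
#' optionally \code{major_um, minor_um, orient_deg} or \code{wkt_polygon}.
#' GeoJSON dialect: FeatureCollection of Point or Polygon features with the
#' probabilities in \code{properties} (coordinates in microns).
#'
#' @rdname nuclei_io
#' @export
read_nuclei_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname nuclei_io
#' @export
write_nuclei_csv <- function(nuclei, path) {
  utils::write.csv(nuclei, path, row.names = FALSE)
  invisible(path)
}

#' @rdname nuclei_io
#' @export
read_nuclei_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  pc <- prob_cols()
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    props <- f$properties
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      xy <- unlist(geom$coordinates)
      wkt <- NA_character_
    } else if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
      xy <- colMeans(ring)
      wkt <- paste0("POLYGON((",
                    paste(sprintf("%g %g", ring[, 1], ring[, 2]),
                          collapse = ", "), "))")
    } else stop("unsupported geometry type: ", geom$type)
    out <- list(nucleus_id = props$nucleus_id %||% as.character(i),
                x_um = xy[1], y_um = xy[2], wkt_polygon = wkt)
    for (p in pc) out[[p]] <- props[[p]] %||% NA_real_
    out
  })
  do.call(rbind.data.frame, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse "POLYGON((x y, x y, ...))" into a 2-column matrix.
parse_wkt_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\)\\s*$", "", body)
  pts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[p != ""])))
  m[, 1:2, drop = FALSE]
}

# -- validation ---------------------------------------------------------------

#' Validate a slide-panoptic object
#'
#' Reporting-only: returns a class-composition summary, per-superclass nucleus
#' counts, and a list of invariant violations (empty iff the object conforms).
#' An empty nuclei table is reported as a warning entry, not a violation.
#'
#' @param slide a \code{\link{slide_panoptic}} (or a list with the same fields,
#'   allowing reports on not-yet-normalized inputs).
#' @return list of class \code{"hips_validation"} with \code{violations},
#'   \code{warnings}, \code{class_composition}, \code{nucleus_counts}.
#' @export
validate_panoptic <- function(slide) {
  schema <- hips_schema()
  viol <- character(0)
  warn <- character(0)
  mask <- slide$region_mask
  tab <- table(factor(as.vector(mask), levels = schema$region_classes,
                      labels = names(schema$region_classes)))
  comp <- as.numeric(tab) / length(mask)
  names(comp) <- names(tab)
  if (!is.numeric(slide$mpp) || slide$mpp <= 0)
    viol <- c(viol, "mpp must be a positive number")
  nuclei <- as.data.frame(slide$nuclei)
  counts <- integer(0)
  if (nrow(nuclei) == 0) {
    warn <- c(warn, "nuclei table is empty")
  } else {
    pc <- intersect(prob_cols(schema), names(nuclei))
    if (length(pc) < length(prob_cols(schema))) {
      viol <- c(viol, "missing probability columns")
    } else {
      P <- as.matrix(nuclei[, pc])
      s <- rowSums(P)
      off <- abs(s - 1) > 1e-6
      if (any(off))
        viol <- c(viol, sprintf(
          "%d nuclei with probability vectors not summing to 1 (max |sum-1| = %.3g)",
          sum(off), max(abs(s - 1))))
      if (any(P < 0)) viol <- c(viol, "negative probabilities present")
    }
    w_um <- nrow(mask) * slide$mpp
    h_um <- ncol(mask) * slide$mpp
    out <- nuclei$x_um < 0 | nuclei$x_um >= w_um |
           nuclei$y_um < 0 | nuclei$y_um >= h_um
    if (any(out))
      viol <- c(viol, sprintf("%d nuclei outside mask bounds: %s", sum(out),
                              paste(utils::head(nuclei$nucleus_id[out], 5),
                                    collapse = ", ")))
    sc <- if ("superclass" %in% names(nuclei)) nuclei$superclass
          else nucleus_superclass(nuclei[, prob_cols(schema)])
    counts <- table(sc)
  }
  structure(list(violations = viol, warnings = warn,
                 class_composition = comp, nucleus_counts = counts),
            class = "hips_validation")
}

#' @export
print.hips_validation <- function(x, ...) {
  cat("Panoptic validation report\n")
  cat("  tissue composition:",
      paste(sprintf("%s=%.1f%%", names(x$class_composition),
                    100 * x$class_composition), collapse = " "), "\n")
  if (length(x$nucleus_counts))
    cat("  nuclei:", paste(sprintf("%s=%d", names(x$nucleus_counts),
                                   as.integer(x$nucleus_counts)),
                           collapse = " "), "\n")
  if (length(x$warnings)) cat("  warnings:\n",
                              paste("   -", x$warnings, collapse = "\n"), "\n")
  if (length(x$violations)) {
    cat("  VIOLATIONS:\n", paste("   -", x$violations, collapse = "\n"), "\n")
  } else cat("  no violations\n")
  invisible(x)
}
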