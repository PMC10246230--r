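#' Extraction settings
#' @keywords internal
extract_params <- function(tile512_um = 512, tile256_um = 256,
                           min_tissue_frac = 0.5, band_um = 32,
                           top_k512 = 128, top_k256 = 256,
                           radii_um = c(16, 32, 64),
                           neighborhood_bands_um = c(128, 256),
                           rim_um = 4,
                           fiber_min_stroma = 0.30, fiber_min_tumor = 0.20) {
  as.list(environment())
}

# per-tile mean and population sd of values grouped by tile index
roi_stats <- function(values, tile_idx, n_tiles) {
  f <- factor(tile_idx, levels = seq_len(n_tiles))
  ok <- is.finite(values) & !is.na(tile_idx)
  n <- tabulate(f[ok], n_tiles)
  s <- vapply(split(values[ok], f[ok]), sum, numeric(1))
  s2 <- vapply(split(values[ok]^2, f[ok]), sum, numeric(1))
  m <- ifelse(n > 0, s / n, NA_real_)
  sd <- ifelse(n > 1, sqrt(pmax(s2 / n - m^2, 0)), NA_real_)
  list(mean = m, sd = sd, n = n)
}

#' Extract the full histomic feature vector of one slide
#'
#' Runs tiling, region morphometry, nuclear morphometry, spatial statistics
#' and stromal-matrix analysis on a \code{\link{slide_panoptic}} and
#' aggregates everything to a single per-WSI vector following the manifest
#' recipes (region mean/sd, WSI-direct, saliency-weighted top-k ROIs).
#' Image-dependent features are NA when the slide has no image (to be filled
#' by \code{\link{knn_impute}} downstream).
#'
#' @param slide a \code{\link{slide_panoptic}} with the region mask at
#'   1 um/px.
#' @param params an \code{extract_params()} list.
#' @return named numeric vector in \code{\link{hips_manifest}} order.
#' @export
extract_slide_features <- function(slide, params = extract_params()) {
  p <- params
  schema <- slide$schema %||% hips_schema()
  rc <- schema$region_classes
  manifest <- hips_manifest()
  out <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$name)

  mask1 <- slide$region_mask
  stopifnot(slide$mpp == 1)  # segmentation-resolution convention
  mask2 <- downsample_mask(mask1, 2L)        # region features at 2 um/px
  nuclei <- slide$nuclei
  tissue_um2 <- sum(mask1 != rc[["background"]]) * slide$mpp^2
  if (tissue_um2 <= 0) stop("slide has no tissue")
  tissue_mm2 <- tissue_um2 / 1e6

  # ---- WSI-direct spatial statistics --------------------------------------
  pts <- function(sel) as.matrix(nuclei[sel, c("x_um", "y_um"), drop = FALSE])
  ep <- pts(nuclei$superclass == "epithelial")
  ca <- pts(nuclei$superclass == "stromal")
  ti <- pts(nuclei$superclass == "tils")
  cancer <- pts(nuclei$subclass == "cancer_epith")

  out["GlobalCancerCellDensity"] <- nrow(cancer) / tissue_mm2
  out["GlobalEpithCellDensity"] <- nrow(ep) / tissue_mm2
  out["GlobalCAFDensity"] <- nrow(ca) / tissue_mm2
  out["GlobalTILsDensity"] <- nrow(ti) / tissue_mm2
  for (r in p$radii_um) {
    out[sprintf("LocalCAFDensity%duM", r)] <-
      local_density(ca, ca, r, same_class = TRUE)
    out[sprintf("LocalTILsDensity%duM", r)] <-
      local_density(ti, ti, r, same_class = TRUE)
    out[sprintf("EpithClustering%duM", r)] <-
      clustering_ratio(ep, ep, r, tissue_um2, same_class = TRUE)
    out[sprintf("CAFClustering%duM", r)] <-
      clustering_ratio(ca, ca, r, tissue_um2, same_class = TRUE)
    out[sprintf("TILsClustering%duM", r)] <-
      clustering_ratio(ti, ti, r, tissue_um2, same_class = TRUE)
    out[sprintf("TILsDensityWithin%duMOfEpithCell", r)] <-
      local_density(ep, ti, r)
    out[sprintf("CAFDensityWithin%duMOfEpithCell", r)] <-
      local_density(ep, ca, r)
  }
  for (r in c(32, 64)) {
    out[sprintf("TILsClusteringWithin%duMOfEpithCell", r)] <-
      clustering_ratio(ep, ti, r, tissue_um2)
    out[sprintf("CAFClusteringWithin%duMOfEpithCell", r)] <-
      clustering_ratio(ep, ca, r, tissue_um2)
  }
  cafs_geom <- nuclei[nuclei$superclass == "stromal", , drop = FALSE]
  for (r in c(32, 64))
    out[sprintf("CAFOrientationEntropy%duM", r)] <-
      fibroblast_orientation_entropy(cafs_geom, radius_um = r)

  # ---- region-level features ----------------------------------------------
  reg_agg <- function(vals, name_mean, name_sd = NULL) {
    a <- aggregate_regions_to_wsi(vals)
    out[name_mean] <<- a[["mean"]]
    if (!is.null(name_sd)) out[name_sd] <<- a[["sd"]]
  }
  ep_inst <- extract_region_instances(mask2, rc[["epithelium"]], mpp = 2)
  if (length(ep_inst) > 0) {
    shp <- t(vapply(ep_inst, region_shape_features, numeric(9)))
    reg_agg(shp[, "area_um2"], "EpithNestArea_Mean", "EpithNestArea_Std")
    reg_agg(shp[, "perimeter_um"], "EpithNestPerimeter_Mean",
            "EpithNestPerimeter_Std")
    reg_agg(shp[, "n_holes"], "NoOfHolesPerEpithNest_Mean",
            "NoOfHolesPerEpithNest_Std")
    reg_agg(shp[, "major_axis_um"], "EpithNestMajorAxis_Mean",
            "EpithNestMajorAxis_Std")
    reg_agg(shp[, "circularity"], "EpithNestCircularity_Mean",
            "EpithNestCircularity_Std")
    reg_agg(shp[, "convexity"], "EpithNestConvexity_Mean")
    reg_agg(shp[, "fractal_dim"], "EpithNestFractalDim_Mean")
    comp <- t(vapply(ep_inst, region_composition, numeric(10),
                     nuclei = nuclei))
    reg_agg(comp[, "nc_ratio"], "NucleusToCytoplasmRatioPerEpithNest_Mean",
            "NucleusToCytoplasmRatioPerEpithNest_Std")
    reg_agg(comp[, "cytoplasm_um2"], "CytoplasmAmountPerEpithNest_Mean")
    reg_agg(comp[, "n_low_grade"], "NoOfLowGradeNucleiPerEpithNest")
    reg_agg(comp[, "n_nuclei"], "NoOfNucleiPerEpithNest")
    nb <- t(vapply(ep_inst, neighborhood_composition, numeric(18),
                   region_mask = mask2, nuclei = nuclei))
    reg_agg(nb[, "band128_density_stromal_per_mm2"],
            "CAFDensityAtEpithNestMargin")
    reg_agg(nb[, "band256_density_stromal_per_mm2"],
            "CAFDensityAtEpithNestMargin256uM")
    reg_agg(nb[, "band128_frac_stroma"], "StromaFractionAtEpithNestMargin")
    reg_agg(nb[, "band256_frac_stroma"],
            "StromaFractionAtEpithNestMargin256uM")
    reg_agg(nb[, "band128_density_tils_per_mm2"],
            "TILsDensityAtEpithNestMargin")
  }
  st_inst <- extract_region_instances(mask2, rc[["stroma"]], mpp = 2)
  if (length(st_inst) > 0) {
    shp <- t(vapply(st_inst, region_shape_features, numeric(9)))
    reg_agg(shp[, "area_um2"], "StromaRegionArea_Mean", "StromaRegionArea_Std")
    reg_agg(shp[, "fractal_dim"], "StromaRegionFractalDim_Mean")
  }
  tl_inst <- extract_region_instances(mask2, rc[["tils_dense"]], mpp = 2)
  out["NoOfTILsRegions"] <- length(tl_inst)
  if (length(tl_inst) > 0) {
    shp <- t(vapply(tl_inst, region_shape_features, numeric(9)))
    reg_agg(shp[, "area_um2"], "TILsRegionArea_Mean", "TILsRegionArea_Std")
    reg_agg(shp[, "circularity"], "TILsRegionCircularity_Mean")
  }
  nc_inst <- extract_region_instances(mask2, rc[["necrosis"]], mpp = 2)
  out["NoOfNecrosisRegions"] <- length(nc_inst)
  out["GlobalNecrosisFraction"] <-
    sum(mask1 == rc[["necrosis"]]) * slide$mpp^2 / tissue_um2
  if (length(nc_inst) > 0) {
    shp <- t(vapply(nc_inst, region_shape_features, numeric(9)))
    reg_agg(shp[, "area_um2"], "NecrosisRegionArea_Mean",
            "NecrosisRegionArea_Std")
  }

  # ---- 512 um tiles and saliency ------------------------------------------
  t512 <- tile_slide(slide, side_um = p$tile512_um,
                     min_tissue_frac = p$min_tissue_frac,
                     band_um = p$band_um)
  if (nrow(t512) > 0) {
    out["SaliencyMean"] <- mean(t512$saliency)
    out["SaliencyStd"] <- if (nrow(t512) > 1)
      sqrt(mean((t512$saliency - mean(t512$saliency))^2)) else NA_real_
  }

  # ---- per-nucleus features, aggregated per 512 ROI -----------------------
  has_img <- !is.null(slide$image)
  img <- NULL; impp <- slide$image_mpp
  if (has_img) {
    img <- slide$image
    if (length(dim(img)) == 3) img <- hematoxylin_channel(img)
  } else impp <- 0.5
  if (nrow(nuclei) > 0 && nrow(t512) > 0) {
    dim_i <- if (has_img) dim(img) else
      c(ceiling(slide$width_um / impp), ceiling(slide$height_um / impp))
    lab <- rasterize_nuclei(nuclei, dim_i, impp)
    edge_map <- if (has_img) canny_edges(img, sigma_px = 1, mask = lab > 0)
                else NULL
    nsf <- nucleus_standard_features(nuclei, lab, image = img, mpp = impp,
                                     edge_map = edge_map)
    dr <- deep_ratios(nuclei[, prob_cols(schema)])
    # tile assignment by centroid (grid index matched to retained tiles)
    tk <- sprintf("t%d_%d", floor(nuclei$x_um / p$tile512_um) + 1L,
                  floor(nuclei$y_um / p$tile512_um) + 1L)
    tile_idx <- match(tk, t512$tile_id)
    sal <- t512$saliency
    nt <- nrow(t512)
    wagg <- function(per_nucleus, sel, name_mean, name_sd = NULL,
                     sd_source = c("within-roi", "none")) {
      v <- ifelse(sel, per_nucleus, NA_real_)
      st <- roi_stats(v, tile_idx, nt)
      out[name_mean] <<- saliency_weighted_aggregate(st$mean, sal,
                                                     p$top_k512)[["wmean"]]
      if (!is.null(name_sd))
        out[name_sd] <<- saliency_weighted_aggregate(st$sd, sal,
                                                     p$top_k512)[["wmean"]]
    }
    is_ep <- nuclei$superclass == "epithelial"
    is_ca <- nuclei$superclass == "stromal"
    is_ti <- nuclei$superclass == "tils"
    wagg(nsf$area_um2, is_ep, "EpithNucleusArea_Mean", "EpithNucleusArea_Std")
    wagg(nsf$major_um, is_ep, "EpithNucleusMajorAxis_Mean")
    wagg(nsf$eccentricity, is_ep, "EpithNucleusEccentricity_Mean")
    wagg(nsf$solidity, is_ep, "EpithNucleusSolidity_Mean")
    wagg(nsf$fractal_dim, is_ep, "EpithNucleusFractalDim_Mean")
    wagg(dr$epithelial_atypia, is_ep, "EpithelialAtypia_Mean",
         "EpithelialAtypia_Std")
    wagg(nsf$area_um2, is_ca, "CAFNucleusArea_Mean", "CAFNucleusArea_Std")
    wagg(nsf$eccentricity, is_ca, "CAFNucleusEccentricity_Mean")
    wagg(nsf$fractal_dim, is_ca, "CAFNucleusFractalDim_Mean")
    wagg(dr$caf_epithelialization, is_ca, "CAFEpithelialization_Mean",
         "CAFEpithelialization_Std")
    wagg(nsf$area_um2, is_ti, "TILsNucleusArea_Mean")
    wagg(nsf$eccentricity, is_ti, "TILsNucleusEccentricity_Mean")
    wagg(nsf$solidity, is_ti, "TILsNucleusSolidity_Mean")
    wagg(dr$tils_activation, is_ti, "TILsActivation_Mean", "TILsActivation_Std")
    if (has_img) {
      wagg(nsf$chromatin_clumping, is_ep, "ChromatinClumpingOfEpithNuclei",
           "ChromatinClumpingOfEpithNuclei_Std")
      wagg(nsf$intensity_mean, is_ep, "EpithNucleusIntensity_Mean",
           "EpithNucleusIntensity_Std")
      wagg(nsf$haralick_contrast, is_ep, "EpithNucleusHaralickContrast_Mean")
      wagg(nsf$haralick_entropy, is_ep, "EpithNucleusHaralickEntropy_Mean")
      wagg(nsf$chromatin_clumping, is_ca, "ChromatinClumpingOfCAFNuclei",
           "ChromatinClumpingOfCAFNuclei_Std")
      wagg(nsf$chromatin_clumping, is_ti, "ChromatinClumpingOfTILsNuclei",
           "ChromatinClumpingOfTILsNuclei_Std")
      # cytoplasmic rims (epithelial) and peri-CAF stromal rims share the
      # exclusive-rim ownership map
      rim_owner <- exclusive_rims(lab, impp, p$rim_um)
      rim <- cytoplasmic_rim_features(nuclei, lab, img, impp, p$rim_um,
                                      rim_owner = rim_owner)
      wagg(rim$rim_mean, is_ep, "EpithCytoplasmicIntensity_Mean",
           "EpithCytoplasmicIntensity_Std")
      wagg(rim$rim_haralick_contrast, is_ep,
           "EpithCytoplasmicHaralickContrast_Mean")
      wagg(rim$rim_haralick_homogeneity, is_ep,
           "EpithCytoplasmicHaralickHomogeneity_Mean")
      stroma_i <- upsample_mask_to(mask1, dim_i, slide$mpp, impp) ==
        rc[["stroma"]]
      rim_st <- cytoplasmic_rim_features(nuclei, lab, img, impp, p$rim_um,
                                         allowed = stroma_i & lab == 0,
                                         rim_owner = rim_owner,
                                         haralick = FALSE)
      caf_rm <- ifelse(is_ca, rim_st$rim_mean, NA_real_)
      hetero <- vapply(seq_len(nt), function(t)
        peri_caf_matrix_heterogeneity(caf_rm[which(tile_idx == t)]),
        numeric(1))
      hw <- saliency_weighted_aggregate(hetero, sal, p$top_k512)
      out["PeriCAFMatrixHeteroIn512uMROI"] <- hw[["wmean"]]
      out["PeriCAFMatrixHeteroIn512uMROI_Std"] <- hw[["wsd"]]
    }
  } else lab <- NULL

  # ---- 256 um ROIs: stromal matrix and collagen ---------------------------
  if (has_img) {
    t256 <- tile_slide(slide, side_um = p$tile256_um,
                       min_tissue_frac = p$min_tissue_frac,
                       band_um = p$band_um)
    if (nrow(t256) > 0) {
      if (is.null(lab)) {
        dim_i <- dim(img)
        lab <- rasterize_nuclei(nuclei, dim(img), impp)
      }
      stroma_i <- upsample_mask_to(mask1, dim(img), slide$mpp, impp) ==
        rc[["stroma"]]
      # fibers detected slide-wide (one edge pass), assigned to ROIs by
      # centroid; avoids splitting fibers at tile borders
      fib_all <- detect_collagen_fibers(img, stroma_i, lab > 0, mpp = impp)
      nvals <- list(sm_mean = rep(NA_real_, nrow(t256)),
                    sm_sd = rep(NA_real_, nrow(t256)),
                    sm_con = rep(NA_real_, nrow(t256)),
                    cfod = rep(NA_real_, nrow(t256)),
                    nstraight = rep(NA_real_, nrow(t256)),
                    flen = rep(NA_real_, nrow(t256)),
                    flen_sd = rep(NA_real_, nrow(t256)),
                    wav = rep(NA_real_, nrow(t256)))
      for (t in seq_len(nrow(t256))) {
        x0 <- floor(t256$x0_um[t] / impp) + 1L
        y0 <- floor(t256$y0_um[t] / impp) + 1L
        x1 <- min(dim(img)[1], floor((t256$x0_um[t] + t256$w_um[t]) / impp))
        y1 <- min(dim(img)[2], floor((t256$y0_um[t] + t256$h_um[t]) / impp))
        sub_i <- img[x0:x1, y0:y1]
        sub_s <- stroma_i[x0:x1, y0:y1]
        sub_l <- lab[x0:x1, y0:y1]
        matrix_px <- sub_s & sub_l == 0
        if (sum(matrix_px) > 20) {
          v <- sub_i[matrix_px]
          nvals$sm_mean[t] <- mean(v)
          nvals$sm_sd[t] <- stats::sd(v)
          hf <- try(EBImage::computeFeatures.haralick(
            matrix(as.integer(matrix_px), nrow(sub_i)), sub_i,
            haralick.nbins = 32, haralick.scales = 1), silent = TRUE)
          if (!inherits(hf, "try-error") && !is.null(hf))
            nvals$sm_con[t] <- hf[1, "h.con.s1"]
        }
        tile_area <- t256$w_um[t] * t256$h_um[t]
        stroma_fr <- t256$area_stroma_um2[t] / tile_area
        tumor_fr <- t256$area_epithelium_um2[t] / tile_area
        if (stroma_fr >= p$fiber_min_stroma && tumor_fr >= p$fiber_min_tumor) {
          fib <- fib_all[fib_all$x_um >= t256$x0_um[t] &
                           fib_all$x_um < t256$x0_um[t] + t256$w_um[t] &
                           fib_all$y_um >= t256$y0_um[t] &
                           fib_all$y_um < t256$y0_um[t] + t256$h_um[t], ,
                         drop = FALSE]
          nvals$cfod[t] <- cfod(fib)
          nvals$nstraight[t] <- sum(fib$straight)
          if (any(fib$straight)) {
            sl <- fib$length_um[fib$straight]
            nvals$flen[t] <- mean(sl)
            nvals$flen_sd[t] <- if (length(sl) > 1) stats::sd(sl) else NA_real_
          }
          if (nrow(fib) > 0) nvals$wav[t] <- mean(fib$waviness)
        }
      }
      w256 <- t256$saliency
      put <- function(v, name)
        out[name] <<- saliency_weighted_aggregate(v, w256,
                                                  p$top_k256)[["wmean"]]
      put(nvals$sm_mean, "StromalMatrixIntensity_Mean")
      put(nvals$sm_sd, "StromalMatrixIntensity_Std")
      put(nvals$sm_con, "StromalMatrixHaralickContrast_Mean")
      put(nvals$cfod, "CFOD")
      put(nvals$nstraight, "NoOfStraightFibers")
      put(nvals$flen, "StraightFiberMeanLength")
      put(nvals$flen_sd, "StraightFiberLengthStd")
      put(nvals$wav, "FiberWaviness_Mean")
    }
  }
  out
}

# nearest-neighbor upsample of a label mask onto an image grid
upsample_mask_to <- function(mask, dim_i, mask_mpp, img_mpp) {
  xi <- pmin(nrow(mask), floor((seq_len(dim_i[1]) - 0.5) * img_mpp / mask_mpp) + 1L)
  yi <- pmin(ncol(mask), floor((seq_len(dim_i[2]) - 0.5) * img_mpp / mask_mpp) + 1L)
  mask[xi, yi]
}

# hematoxylin concentration channel via standard H&E deconvolution
hematoxylin_channel <- function(rgb) {
  S <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  S <- S / sqrt(rowSums(S^2))
  od <- -log(pmax(matrix(rgb, ncol = 3), 1 / 256))
  C <- qr.solve(t(S), t(od))
  h <- matrix(pmax(C[1, ], 0), dim(rgb)[1], dim(rgb)[2])
  1 - h / max(h, 1e-9)   # dark = concentrated, matching grayscale convention
}

#' Extract a patient-level feature matrix from a set of slides
#'
#' Runs \code{\link{extract_slide_features}} on every slide, averages per-WSI
#' vectors across a patient's slides, and returns the patient-by-feature
#' matrix with the manifest attached. Per-slide failures are logged and
#' skipped; the run fails only if every slide fails.
#'
#' @param slides list of \code{\link{slide_panoptic}} objects.
#' @param params extraction settings.
#' @param verbose print a one-line log per slide.
#' @return data.frame: \code{patient_id} + 109 feature columns; attribute
#'   \code{"manifest"}; attribute \code{"slide_count"}.
#' @export
run_extract <- function(slides, params = extract_params(), verbose = FALSE) {
  if (length(slides) == 0) stop("no slides given")
  manifest <- hips_manifest()
  res <- list(); pid <- character(0); failed <- 0L
  for (s in slides) {
    fv <- tryCatch(extract_slide_features(s, params), error = function(e) {
      warning("slide ", s$slide_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(fv)) { failed <- failed + 1L; next }
    if (verbose)
      message(sprintf("slide %s: %d/%d features observed", s$slide_id,
                      sum(is.finite(fv)), length(fv)))
    res[[length(res) + 1L]] <- fv
    pid <- c(pid, s$patient_id)
  }
  if (length(res) == 0) stop("all slides failed feature extraction")
  M <- do.call(rbind, res)
  upat <- unique(pid)
  P <- t(vapply(upat, function(u)
    patient_level(M[pid == u, , drop = FALSE]), numeric(ncol(M))))
  df <- data.frame(patient_id = upat, P, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "manifest") <- manifest
  attr(df, "slide_count") <- as.integer(table(pid)[upat])
  df
}
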