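#' The histomic feature manifest
#'
#' The catalogue of 109 named patient-level histomic features organized into
#' 5 biological themes (epithelial, stromal, tils, necrosis, interactions)
#' and 26 subthemes, each with its aggregation recipe:
#' \itemize{
#'   \item \code{region-wsi}: per-region values to per-WSI mean/sd;
#'   \item \code{wsi-direct}: computed once over the whole WSI (global
#'     densities, clustering, interaction statistics) to avoid artificial ROI
#'     boundary artifacts;
#'   \item \code{roi512-saliency-top128}: per-nucleus values aggregated per
#'     512 um ROI then saliency-weighted over the top 128 most-salient ROIs;
#'   \item \code{roi256-saliency-top256}: per-ROI stromal-matrix/collagen
#'     values saliency-weighted over the top 256 most-salient 256 um ROIs.
#' }
#' \code{quoted} flags names used verbatim in the literature describing this
#' catalogue; the remaining entries are family expansions (mean/sd pairs,
#' the three radii, per-superclass variants).
#'
#' @return data.frame with columns \code{name, theme, subtheme, aggregation,
#'   quoted}.
#' @export
hips_manifest <- function() {
  E <- function(names, sub, agg, quoted = FALSE)
    data.frame(name = names, theme = NA_character_, subtheme = sub,
               aggregation = agg, quoted = quoted, stringsAsFactors = FALSE)
  m <- rbind(
    # --- epithelial ---------------------------------------------------------
    E(c("GlobalCancerCellDensity", "GlobalEpithCellDensity"),
      "EpithelialAbundance", "wsi-direct"),
    E(c("EpithNestArea_Mean", "EpithNestArea_Std",
        "EpithNestPerimeter_Mean", "EpithNestPerimeter_Std",
        "NoOfHolesPerEpithNest_Mean", "NoOfHolesPerEpithNest_Std",
        "EpithNestMajorAxis_Mean", "EpithNestMajorAxis_Std"),
      "EpithNestArchitecture", "region-wsi"),
    E(c("EpithNestCircularity_Mean", "EpithNestCircularity_Std",
        "EpithNestConvexity_Mean", "EpithNestFractalDim_Mean"),
      "EpithNestShape", "region-wsi"),
    E(paste0("EpithClustering", c(16, 32, 64), "uM"),
      "EpithClustering", "wsi-direct"),
    E(c("EpithNucleusArea_Mean", "EpithNucleusArea_Std",
        "EpithNucleusMajorAxis_Mean", "EpithNucleusEccentricity_Mean",
        "EpithNucleusSolidity_Mean", "EpithNucleusFractalDim_Mean"),
      "EpithNuclearMorphology", "roi512-saliency-top128"),
    E(c("ChromatinClumpingOfEpithNuclei", "ChromatinClumpingOfEpithNuclei_Std",
        "EpithNucleusIntensity_Mean", "EpithNucleusIntensity_Std",
        "EpithNucleusHaralickContrast_Mean",
        "EpithNucleusHaralickEntropy_Mean"),
      "EpithNuclearPleomorphism", "roi512-saliency-top128",
      quoted = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    E(c("EpithelialAtypia_Mean", "EpithelialAtypia_Std"),
      "EpithelialAtypia", "roi512-saliency-top128"),
    E(c("NucleusToCytoplasmRatioPerEpithNest_Mean",
        "NucleusToCytoplasmRatioPerEpithNest_Std",
        "CytoplasmAmountPerEpithNest_Mean",
        "NoOfLowGradeNucleiPerEpithNest", "NoOfNucleiPerEpithNest"),
      "EpithNestComposition", "region-wsi",
      quoted = c(FALSE, FALSE, FALSE, TRUE, FALSE)),
    E(c("EpithCytoplasmicIntensity_Mean", "EpithCytoplasmicIntensity_Std",
        "EpithCytoplasmicHaralickContrast_Mean",
        "EpithCytoplasmicHaralickHomogeneity_Mean"),
      "EpithCytoplasmTexture", "roi512-saliency-top128"),
    # --- stromal ------------------------------------------------------------
    E(c("GlobalCAFDensity", paste0("LocalCAFDensity", c(16, 32, 64), "uM")),
      "CAFAbundance", "wsi-direct"),
    E(paste0("CAFClustering", c(16, 32, 64), "uM"),
      "CAFClustering", "wsi-direct"),
    E(c("CAFNucleusArea_Mean", "CAFNucleusArea_Std",
        "CAFNucleusEccentricity_Mean", "CAFNucleusFractalDim_Mean",
        "ChromatinClumpingOfCAFNuclei", "ChromatinClumpingOfCAFNuclei_Std"),
      "CAFNuclearMorphology", "roi512-saliency-top128"),
    E(c("CAFEpithelialization_Mean", "CAFEpithelialization_Std"),
      "CAFEpithelialization", "roi512-saliency-top128"),
    E(paste0("CAFOrientationEntropy", c(32, 64), "uM"),
      "CAFOrientation", "wsi-direct"),
    E(c("PeriCAFMatrixHeteroIn512uMROI", "PeriCAFMatrixHeteroIn512uMROI_Std",
        "StromalMatrixIntensity_Mean", "StromalMatrixIntensity_Std",
        "StromalMatrixHaralickContrast_Mean"),
      "StromalMatrix",
      c("roi512-saliency-top128", "roi512-saliency-top128",
        "roi256-saliency-top256", "roi256-saliency-top256",
        "roi256-saliency-top256"),
      quoted = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    E(c("CFOD", "NoOfStraightFibers", "StraightFiberMeanLength",
        "StraightFiberLengthStd", "FiberWaviness_Mean"),
      "CollagenFibers", "roi256-saliency-top256",
      quoted = c(TRUE, FALSE, FALSE, FALSE, FALSE)),
    E(c("StromaRegionArea_Mean", "StromaRegionArea_Std",
        "StromaRegionFractalDim_Mean"),
      "StromaRegionMorphology", "region-wsi"),
    # --- tils ---------------------------------------------------------------
    E(c("GlobalTILsDensity", paste0("LocalTILsDensity", c(16, 32, 64), "uM")),
      "TILsAbundance", "wsi-direct",
      quoted = c(FALSE, FALSE, TRUE, FALSE)),
    E(paste0("TILsClustering", c(16, 32, 64), "uM"),
      "TILsClustering", "wsi-direct"),
    E(c("TILsNucleusArea_Mean", "TILsNucleusEccentricity_Mean",
        "TILsNucleusSolidity_Mean", "ChromatinClumpingOfTILsNuclei",
        "ChromatinClumpingOfTILsNuclei_Std"),
      "TILsNuclearMorphology", "roi512-saliency-top128"),
    E(c("TILsActivation_Mean", "TILsActivation_Std"),
      "TILsActivation", "roi512-saliency-top128"),
    E(c("TILsRegionArea_Mean", "TILsRegionArea_Std",
        "TILsRegionCircularity_Mean", "NoOfTILsRegions"),
      "TILsRegionMorphology",
      c("region-wsi", "region-wsi", "region-wsi", "wsi-direct")),
    # --- necrosis -----------------------------------------------------------
    E(c("GlobalNecrosisFraction", "NecrosisRegionArea_Mean",
        "NecrosisRegionArea_Std", "NoOfNecrosisRegions"),
      "NecrosisAbundance",
      c("wsi-direct", "region-wsi", "region-wsi", "wsi-direct")),
    # --- interactions -------------------------------------------------------
    E(c("CAFDensityAtEpithNestMargin", "CAFDensityAtEpithNestMargin256uM",
        "StromaFractionAtEpithNestMargin",
        "StromaFractionAtEpithNestMargin256uM",
        "SaliencyMean", "SaliencyStd"),
      "EpithStromalInterface",
      c(rep("region-wsi", 4), "wsi-direct", "wsi-direct"),
      quoted = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    E(c(paste0("TILsDensityWithin", c(16, 32, 64), "uMOfEpithCell"),
        "TILsClusteringWithin32uMOfEpithCell",
        "TILsClusteringWithin64uMOfEpithCell",
        "TILsDensityAtEpithNestMargin"),
      "EpithTILInteractions",
      c(rep("wsi-direct", 5), "region-wsi"),
      quoted = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    E(c(paste0("CAFDensityWithin", c(16, 32, 64), "uMOfEpithCell"),
        "CAFClusteringWithin32uMOfEpithCell",
        "CAFClusteringWithin64uMOfEpithCell"),
      "EpithCAFInteractions", "wsi-direct")
  )
  theme_of <- c(
    EpithelialAbundance = "epithelial", EpithNestArchitecture = "epithelial",
    EpithNestShape = "epithelial", EpithClustering = "epithelial",
    EpithNuclearMorphology = "epithelial",
    EpithNuclearPleomorphism = "epithelial", EpithelialAtypia = "epithelial",
    EpithNestComposition = "epithelial", EpithCytoplasmTexture = "epithelial",
    CAFAbundance = "stromal", CAFClustering = "stromal",
    CAFNuclearMorphology = "stromal", CAFEpithelialization = "stromal",
    CAFOrientation = "stromal", StromalMatrix = "stromal",
    CollagenFibers = "stromal", StromaRegionMorphology = "stromal",
    TILsAbundance = "tils", TILsClustering = "tils",
    TILsNuclearMorphology = "tils", TILsActivation = "tils",
    TILsRegionMorphology = "tils",
    NecrosisAbundance = "necrosis",
    EpithStromalInterface = "interactions",
    EpithTILInteractions = "interactions",
    EpithCAFInteractions = "interactions")
  m$theme <- unname(theme_of[m$subtheme])
  rownames(m) <- NULL
  m
}

#' Aggregate per-region values to the WSI level
#'
#' Unweighted mean and population standard deviation over region instances;
#' the sd is NA for a single region and both are NA with no regions.
#'
#' @param values numeric vector (NA entries dropped).
#' @return c(mean, sd).
#' @export
aggregate_regions_to_wsi <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(v),
    sd = if (length(v) > 1) sqrt(mean((v - mean(v))^2)) else NA_real_)
}

#' Saliency-weighted aggregation over the top-k ROIs
#'
#' Keeps the \code{top_k} ROIs by saliency (all if fewer) and returns the
#' weighted mean and weighted population sd of the values with the saliencies
#' as frequency weights. ROIs with a missing value are excluded together with
#' their weights. If all saliencies are zero the aggregation falls back to the
#' unweighted mean/sd with a warning. With equal weights the result equals the
#' unweighted aggregation exactly.
#'
#' @param x per-ROI values.
#' @param w per-ROI saliencies (nonnegative).
#' @param top_k ROI budget (128 for 512 um ROIs, 256 for 256 um ROIs).
#' @return c(wmean, wsd).
#' @export
saliency_weighted_aggregate <- function(x, w, top_k = 128) {
  stopifnot(length(x) == length(w), all(w >= 0, na.rm = TRUE))
  ord <- order(w, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  x <- x[keep]; w <- w[keep]
  ok <- is.finite(x) & is.finite(w)
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0) return(c(wmean = NA_real_, wsd = NA_real_))
  if (sum(w) == 0) {
    warning("all saliencies zero; falling back to unweighted aggregation")
    w <- rep(1, length(x))
  }
  wm <- sum(w * x) / sum(w)
  ws <- sqrt(sum(w * (x - wm)^2) / sum(w))
  c(wmean = wm, wsd = if (length(x) > 1) ws else NA_real_)
}

#' Average per-WSI feature vectors to the patient level
#'
#' @param wsi_matrix numeric matrix, one row per slide of the same patient
#'   (1-3 slides), columns = features; missing values are ignored per feature.
#' @return named numeric vector.
#' @export
patient_level <- function(wsi_matrix) {
  wsi_matrix <- rbind(wsi_matrix)
  out <- colMeans(wsi_matrix, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' z-score a feature matrix against reference statistics
#'
#' Each feature is centred and scaled by the reference (discovery-cohort)
#' mean and sd, omitting missing values. Fitting mode (\code{ref_stats =
#' NULL}) computes the statistics from the matrix itself and returns them for
#' later reuse. Features with zero reference sd are dropped with a warning.
#'
#' @param X data.frame/matrix of features (no id column).
#' @param ref_stats optional list with \code{mu}, \code{sigma} named vectors.
#' @return list(X = scaled data.frame, stats = list(mu, sigma)).
#' @export
zscore_features <- function(X, ref_stats = NULL) {
  X <- as.data.frame(X)
  if (is.null(ref_stats)) {
    mu <- vapply(X, function(v) mean(v, na.rm = TRUE), numeric(1))
    sigma <- vapply(X, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
    ref_stats <- list(mu = mu, sigma = sigma)
  } else {
    unknown <- setdiff(names(X), names(ref_stats$mu))
    if (length(unknown) > 0)
      stop("features missing from reference stats: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  bad <- names(X)[!is.finite(ref_stats$sigma[names(X)]) |
                    ref_stats$sigma[names(X)] <= 0]
  if (length(bad) > 0) {
    warning("dropping constant features: ", paste(bad, collapse = ", "))
    X <- X[, setdiff(names(X), bad), drop = FALSE]
  }
  for (j in names(X))
    X[[j]] <- (X[[j]] - ref_stats$mu[[j]]) / ref_stats$sigma[[j]]
  list(X = X, stats = ref_stats)
}

#' k-nearest-neighbor imputation against a reference cohort
#'
#' Each missing cell is replaced by the mean of that feature over the k
#' reference rows nearest in Euclidean distance computed on the mutually
#' observed features (distances are averaged per observed feature so rows
#' with different missingness are comparable). Observed cells are never
#' altered. Rows sharing fewer than \code{min_shared} observed features with
#' the reference fall back to reference column means.
#'
#' @param X data.frame to impute (typically z-scored).
#' @param reference complete-enough reference data.frame with the same
#'   columns (defaults to X itself, the fitting-cohort case).
#' @param k neighbor count (10 in the standard pipeline).
#' @param min_shared minimum mutually observed features for the distance.
#' @return imputed data.frame.
#' @export
knn_impute <- function(X, reference = X, k = 10, min_shared = 3) {
  X <- as.data.frame(X); reference <- as.data.frame(reference)
  stopifnot(identical(names(X), names(reference)))
  Rm <- as.matrix(reference)
  colmeans <- colMeans(Rm, na.rm = TRUE)
  Xm <- as.matrix(X)
  for (i in seq_len(nrow(Xm))) {
    miss <- which(is.na(Xm[i, ]))
    if (length(miss) == 0) next
    obs <- which(!is.na(Xm[i, ]))
    if (length(obs) == 0) stop("row ", i, " has all features missing")
    if (length(obs) < min_shared) {
      Xm[i, miss] <- colmeans[miss]
      next
    }
    d2 <- rowMeans((Rm[, obs, drop = FALSE] -
                      matrix(Xm[i, obs], nrow(Rm), length(obs),
                             byrow = TRUE))^2, na.rm = TRUE)
    d2[!is.finite(d2)] <- Inf
    for (j in miss) {
      ok <- which(!is.na(Rm[, j]) & is.finite(d2))
      if (length(ok) == 0) { Xm[i, j] <- colmeans[j]; next }
      nn <- ok[order(d2[ok])][seq_len(min(k, length(ok)))]
      Xm[i, j] <- mean(Rm[nn, j])
    }
  }
  out <- X
  out[, ] <- Xm
  out
}
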