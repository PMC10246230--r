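#' Write / read a patient-level feature table
#'
#' The table is a data.frame with a \code{patient_id} column followed by one
#' column per manifest feature. On disk it is a CSV with full precision plus a
#' JSON manifest sidecar (\code{<path>.manifest.json}) recording feature names,
#' themes, subthemes and aggregation recipes; reading checks the CSV columns
#' against the sidecar. Missing values are written as empty cells. Round trips
#' are lossless to at least 12 significant digits and preserve column order.
#'
#' @param features data.frame (\code{patient_id} + numeric feature columns).
#' @param path CSV path.
#' @param manifest feature manifest data.frame (see \code{\link{hips_manifest}});
#'   defaults to the attribute stored on \code{features}, else a minimal one.
#' @return \code{read_feature_table} returns the data.frame with the manifest
#'   attached as attribute \code{"manifest"}.
#' @export
write_feature_table <- function(features, path, manifest = NULL) {
  stopifnot("patient_id" %in% names(features))
  fn <- names(features)[names(features) != "patient_id"]
  if (anyDuplicated(fn)) stop("duplicate feature names")
  if (is.null(manifest)) manifest <- attr(features, "manifest")
  if (is.null(manifest))
    manifest <- data.frame(name = fn, theme = NA_character_,
                           subtheme = NA_character_,
                           aggregation = NA_character_,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$name)) stop("duplicate feature names in manifest")
  cols <- lapply(features, function(x)
    if (is.numeric(x)) sprintf("%.15g", x) else as.character(x))
  out <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(out)) out[[j]][is.na(features[[j]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  mpath <- paste0(path, ".manifest.json")
  manifest <- NULL
  if (file.exists(mpath)) {
    manifest <- jsonlite::fromJSON(mpath)
    fn <- setdiff(names(df), "patient_id")
    if (!setequal(manifest$name, fn) ||
        !identical(as.character(manifest$name), fn))
      stop("feature table columns do not match the manifest sidecar")
  }
  for (j in setdiff(names(df), "patient_id")) df[[j]] <- as.numeric(df[[j]])
  attr(df, "manifest") <- manifest
  df
}
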