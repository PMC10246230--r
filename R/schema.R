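#' Class schema for panoptic segmentation labels
#'
#' Defines the fixed vocabulary shared by every pipeline stage: the semantic
#' region classes of the tissue mask, the nucleus subclasses of the classifier
#' probability vector, and the mapping of subclasses onto the three nuclear
#' superclasses (epithelial, non-TIL stromal, TILs) used by the features.
#'
#' @return A list with elements \code{region_classes} (named integer codes),
#'   \code{nucleus_subclasses} (character), and \code{superclass_map}
#'   (named character, subclass -> superclass).
#' @export
hips_schema <- function() {
  list(
    version = "1.0",
    region_classes = c(
      background = 0L, epithelium = 1L, stroma = 2L,
      tils_dense = 3L, necrosis = 4L, other = 5L
    ),
    nucleus_subclasses = c(
      "cancer_epith", "normal_epith", "fibroblast",
      "lymphocyte", "plasma", "other"
    ),
    superclass_map = c(
      cancer_epith = "epithelial", normal_epith = "epithelial",
      fibroblast = "stromal", lymphocyte = "tils",
      plasma = "tils", other = "other"
    )
  )
}

#' Column names of the subclass probability block in a nuclei table
#' @keywords internal
prob_cols <- function(schema = hips_schema()) {
  paste0("prob_", schema$nucleus_subclasses)
}

#' Derive nucleus superclasses from a probability matrix
#'
#' The superclass is the argmax over subclass probabilities summed within each
#' superclass, e.g. \code{epithelial = cancer_epith + normal_epith}.
#'
#' @param probs numeric matrix, one row per nucleus, columns in the order of
#'   \code{hips_schema()$nucleus_subclasses}.
#' @return character vector of superclasses.
#' @export
nucleus_superclass <- function(probs) {
  schema <- hips_schema()
  probs <- as.matrix(probs)
  groups <- split(seq_along(schema$nucleus_subclasses),
                  schema$superclass_map[schema$nucleus_subclasses])
  agg <- vapply(groups, function(j) rowSums(probs[, j, drop = FALSE]),
                numeric(nrow(probs)))
  if (nrow(probs) == 1L) agg <- matrix(agg, nrow = 1L, dimnames = list(NULL, names(groups)))
  colnames(agg)[max.col(agg, ties.method = "first")]
}

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a bounded child seed from a base seed and a stream index, so each
# module/patient gets an independent reproducible stream.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
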