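#' Drop degenerate feature columns
#'
#' Removes all-zero columns, zero-variance columns, and columns whose
#' fraction of zero entries exceeds `max_zero_fraction`, mirroring the usual
#' radiomic preprocessing step (features that are entirely, or almost
#' entirely, zero carry no usable signal and break standardization).
#'
#' @param block Feature block: tibble with `sample_id` first column, or a
#'   matrix with sample rownames.
#' @param max_zero_fraction Columns with a strictly greater zero fraction are
#'   dropped (default 0.95).
#' @return The filtered block (same representation as the input tibble), with
#'   attribute `removed` holding the dropped feature names.
#' @examples
#' x <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                     f1 = c(1, 2, 3), f2 = c(0, 0, 0))
#' filter_degenerate_features(x)
#' @export
filter_degenerate_features <- function(block, max_zero_fraction = 0.95) {
  if (max_zero_fraction < 0 || max_zero_fraction > 1) {
    abort("`max_zero_fraction` must be in [0, 1]")
  }
  m <- as_feature_matrix(block)
  zero_frac <- colMeans(m == 0)
  sds <- apply(m, 2L, sd)
  drop <- zero_frac > max_zero_fraction | sds == 0 | !is.finite(sds)
  if (all(drop)) abort("all feature columns are degenerate")
  removed <- colnames(m)[drop]
  if (length(removed)) {
    inform(sprintf("removed %d degenerate feature(s): %s", length(removed),
                   paste(head(removed, 10L), collapse = ", ")))
  }
  out <- as_feature_tibble(m[, !drop, drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Standardize feature columns to z-scores
#'
#' Column-wise centering and scaling using the cohort mean and sample SD
#' (denominator `n - 1`). Cox feature weighting and the Z-score enrichment
#' thresholds both assume features on this scale.
#'
#' @inheritParams filter_degenerate_features
#' @return A tibble block flagged as standardized (attribute
#'   `standardized = TRUE`), with `center`/`scale` attributes recording the
#'   transformation.
#' @examples
#' x <- tibble::tibble(sample_id = c("a", "b", "c"), f1 = c(1, 2, 3))
#' standardize_features(x)
#' @export
standardize_features <- function(block) {
  m <- as_feature_matrix(block)
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "zero-variance column(s): %s; call filter_degenerate_features() first",
      paste(head(colnames(m)[sds == 0], 5L), collapse = ", ")
    ))
  }
  mus <- colMeans(m)
  z <- sweep(sweep(m, 2L, mus, "-"), 2L, sds, "/")
  out <- as_feature_tibble(z)
  attr(out, "standardized") <- TRUE
  attr(out, "center") <- mus
  attr(out, "scale") <- sds
  out
}
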