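#' Differential features across subtypes
#'
#' Screens every feature with a Kruskal-Wallis test across subtype labels
#' and applies a Benjamini-Hochberg adjustment within each modality;
#' features with adjusted p below `alpha` are flagged selected.
#'
#' @param blocks Named list of feature blocks (or a single block) sharing
#'   sample order.
#' @param labels Subtype label per sample, in block order.
#' @param alpha Selection threshold on the adjusted p-value (default 0.05).
#' @return A tibble with `modality`, `feature`, `statistic`, `p_value`,
#'   `p_adj`, `selected`.
#' @export
differential_features <- function(blocks, labels, alpha = 0.05) {
  if (is.data.frame(blocks) || is.matrix(blocks)) blocks <- list(block = blocks)
  mats <- check_blocks_aligned(blocks)
  if (is.null(names(mats)) || any(names(mats) == "")) {
    names(mats) <- sprintf("modality_%d", seq_along(mats))
  } else {
    names(mats) <- names(blocks)
  }
  labels <- factor(labels)
  if (length(labels) != nrow(mats[[1]])) abort("`labels` misaligned with the blocks")
  if (nlevels(labels) < 2) abort("need at least 2 subtypes")
  purrr::imap_dfr(mats, function(m, nm) {
    res <- apply(m, 2L, function(v) {
      kw <- kruskal_wallis(v, labels)
      c(kw$statistic, kw$p_value)
    })
    p_adj <- p.adjust(res[2L, ], method = "BH")
    tibble::tibble(
      modality = nm,
      feature = colnames(m),
      statistic = unname(res[1L, ]),
      p_value = unname(res[2L, ]),
      p_adj = unname(p_adj),
      selected = unname(p_adj < alpha)
    )
  })
}

#' Flag over- and under-expressed entries by Z-score thresholds
#'
#' Marks each sample x feature entry of a standardized block as
#' over-expressed (`Z >= threshold`), under-expressed
#' (`Z <= -threshold`) or neither. The boundary is inclusive; the
#' threshold is configurable (default 0.6).
#'
#' @param block Standardized feature block.
#' @param threshold Z-score cutoff (default 0.6).
#' @return An integer matrix (samples x features, dimnames preserved) with
#'   entries `1` (over), `-1` (under), `0` (none), carrying a `threshold`
#'   attribute.
#' @export
flag_expression <- function(block, threshold = 0.6) {
  m <- as_feature_matrix(block)
  if (is.data.frame(block) && !is_standardized(block)) {
    abort("`block` must be standardized (see standardize_features())")
  }
  flags <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  flags[m >= threshold] <- 1L
  flags[m <= -threshold] <- -1L
  attr(flags, "threshold") <- threshold
  flags
}

#' Hypergeometric enrichment of flagged features within subtypes
#'
#' For every subtype, feature, and direction (over/under), tests whether the
#' flagged samples concentrate in the subtype: with `N` cohort samples of
#' which `K` are flagged for the feature, and `k` of the subtype's `n_s`
#' samples flagged, the upper-tail hypergeometric probability `P(X >= k)` is
#' computed and BH-adjusted across features within each subtype x direction
#' family. A feature is `representative` of a subtype when its adjusted p is
#' below `alpha`, it is flagged in at least `within_threshold` of the
#' subtype's samples, and in less than `other_threshold` of the samples of
#' every other subtype.
#'
#' @param flags Flag matrix from [flag_expression()].
#' @param labels Subtype label per sample (row order of `flags`).
#' @param alpha FDR threshold (default 0.05).
#' @param within_threshold Minimum within-subtype flagged fraction
#'   (default 2/3).
#' @param other_threshold Strict upper bound on any other subtype's flagged
#'   fraction (default 1/3).
#' @return A tibble with `subtype`, `feature`, `direction`, `k`, `K`,
#'   `n_subtype`, `p_value`, `q_value`, `within_fraction`,
#'   `max_other_fraction`, `representative`.
#' @export
hypergeometric_enrichment <- function(flags, labels, alpha = 0.05,
                                      within_threshold = 2 / 3,
                                      other_threshold = 1 / 3) {
  labels <- factor(labels)
  if (length(labels) != nrow(flags)) abort("`labels` misaligned with `flags`")
  if (any(table(labels) == 0)) abort("empty subtype")
  if (nlevels(labels) < 2) abort("need at least 2 subtypes")
  N <- nrow(flags)
  out <- list()
  for (dir_ in c("over", "under")) {
    hit <- if (dir_ == "over") flags == 1L else flags == -1L
    K <- colSums(hit)
    frac_by_subtype <- rowsum(hit + 0, labels) / as.vector(table(labels))
    for (s in levels(labels)) {
      in_s <- labels == s
      n_s <- sum(in_s)
      k <- colSums(hit[in_s, , drop = FALSE])
      p <- phyper(k - 1, K, N - K, n_s, lower.tail = FALSE)
      q <- p.adjust(p, method = "BH")
      others <- frac_by_subtype[rownames(frac_by_subtype) != s, , drop = FALSE]
      max_other <- apply(others, 2L, max)
      within <- k / n_s
      out[[length(out) + 1L]] <- tibble::tibble(
        subtype = s,
        feature = colnames(flags),
        direction = dir_,
        k = unname(k),
        K = unname(K),
        n_subtype = n_s,
        p_value = unname(p),
        q_value = unname(q),
        within_fraction = unname(within),
        max_other_fraction = unname(max_other),
        representative = unname(q < alpha & within >= within_threshold &
                                  max_other < other_threshold)
      )
    }
  }
  dplyr::bind_rows(out)
}
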