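#' Preprocess a gene-expression matrix
#'
#' Averages duplicate genes and duplicate samples (one row/column kept per
#' name), removes genes and then samples with more than `max_zero_fraction`
#' zero entries, and applies `log2(x + 1)`. The result carries a
#' `transformed` flag so a second call is a no-op on the transform, making
#' the function idempotent.
#'
#' @param raw Expression input: tibble with a `gene` column plus one numeric
#'   column per sample, or a genes x samples matrix with dimnames.
#' @param max_zero_fraction Zero-fraction filter threshold (default 0.3,
#'   strictly-greater removal).
#' @return A tibble (`gene` column plus sample columns) flagged with
#'   attribute `transformed = TRUE`.
#' @export
preprocess_expression <- function(raw, max_zero_fraction = 0.3) {
  already <- isTRUE(attr(raw, "transformed"))
  m <- as_expression_matrix(raw)
  if (any(m < 0)) abort("expression values must be non-negative")
  # duplicates: average rows with the same gene, columns with the same sample
  if (anyDuplicated(rownames(m))) {
    m <- rowsum(m, rownames(m)) / as.vector(table(rownames(m))[unique(rownames(m))])
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  if (anyDuplicated(colnames(m))) {
    mt <- rowsum(t(m), colnames(m)) / as.vector(table(colnames(m))[unique(colnames(m))])
    m <- t(mt)
  }
  keep_genes <- rowMeans(m == 0) <= max_zero_fraction
  m <- m[keep_genes, , drop = FALSE]
  if (!nrow(m)) abort("all genes removed by the zero filter")
  keep_samples <- colMeans(m == 0) <= max_zero_fraction
  m <- m[, keep_samples, drop = FALSE]
  if (!ncol(m)) abort("all samples removed by the zero filter")
  if (!already) m <- log2(m + 1)
  out <- tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(gene = rownames(m), .before = 1L)
  attr(out, "transformed") <- TRUE
  out
}

as_expression_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("expression matrix needs gene rownames")
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x) || !"gene" %in% names(x)) {
    abort("expression input must be a matrix or a tibble with a `gene` column")
  }
  genes <- as.character(x$gene)
  m <- as.matrix(x[setdiff(names(x), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Pathway activity scores by multivariate linear model
#'
#' Regresses each sample's gene-expression profile on the pathway weight
#' columns jointly (ordinary least squares with intercept); the slope
#' t-value of each pathway coefficient is that sample's activity score —
#' positive t indicates activation, negative t inactivation. When the
#' weight input carries per-gene p-values, only the `top_n` most significant
#' genes per pathway keep their weight (others are zeroed), and the gene
#' universe is the union of retained genes intersected with the expression
#' rows. Because every sample shares the same design matrix, the normal
#' equations are solved once for all samples.
#'
#' @param expr Preprocessed expression ([preprocess_expression()] output,
#'   or a genes x samples matrix).
#' @param weights Pathway weights: genes x pathways matrix, or long tibble
#'   with `gene`, `pathway`, `weight` and optionally `p_value`.
#' @param top_n Genes retained per pathway when p-values are available
#'   (default 100).
#' @return Object of class `activity_scores`: tibble with `sample_id` and
#'   one t-value column per pathway; coefficient estimates are attached as
#'   attribute `coefficients`.
#' @export
mlm_activity <- function(expr, weights, top_n = 100) {
  e <- as_expression_matrix(expr)
  w_raw <- weights
  if (is.data.frame(w_raw) && "p_value" %in% names(w_raw)) {
    w_raw <- w_raw |>
      dplyr::group_by(.data$pathway) |>
      dplyr::slice_min(.data$p_value, n = top_n, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  w <- as_weight_matrix(w_raw)
  if (ncol(w) < 1) abort("need at least one pathway")
  genes <- intersect(rownames(e), rownames(w))
  if (length(genes) < ncol(w) + 2) {
    abort("too few shared genes between expression and weights")
  }
  X <- cbind(`(Intercept)` = 1, w[genes, , drop = FALSE])
  Y <- e[genes, , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    abort(sprintf("rank-deficient weight matrix; collinear pathway(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  df_resid <- length(genes) - ncol(X)
  if (df_resid < 1) abort("residual degrees of freedom < 1")
  coefs <- qr.coef(qx, Y)                      # (pathways + 1) x samples
  resid <- Y - X %*% coefs
  sigma2 <- colSums(resid^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(xtx_inv), sigma2))     # coef x samples
  tval <- coefs / se
  tmat <- t(tval[-1L, , drop = FALSE])         # samples x pathways
  colnames(tmat) <- colnames(w)
  out <- tibble::as_tibble(tmat, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = colnames(e), .before = 1L)
  attr(out, "coefficients") <- t(coefs[-1L, , drop = FALSE])
  attr(out, "df_resid") <- df_resid
  class(out) <- c("activity_scores", class(out))
  out
}

#' Contrast pathway activity between two subtypes
#'
#' Welch two-sample t-test of per-sample activity scores, non-reference
#' minus reference subtype, per pathway, with BH adjustment across
#' pathways. A negative t means the pathway is less active in the
#' non-reference subtype.
#'
#' @param scores An `activity_scores` tibble from [mlm_activity()].
#' @param labels Subtype label per sample (scores row order).
#' @param reference Label of the reference subtype.
#' @return A tibble with `pathway`, `t`, `p_value`, `p_adj`, `reference`.
#' @export
contrast_activity <- function(scores, labels, reference) {
  pathways <- setdiff(names(scores), "sample_id")
  labels <- as.character(labels)
  if (length(labels) != nrow(scores)) abort("`labels` misaligned with `scores`")
  if (!reference %in% labels) abort("`reference` is not a subtype label")
  lev <- unique(labels)
  if (length(lev) != 2) abort("activity contrast requires exactly two subtypes")
  if (min(table(labels)) < 2) abort("each subtype needs at least 2 samples")
  other <- setdiff(lev, reference)
  res <- purrr::map_dfr(pathways, function(p) {
    tt <- stats::t.test(scores[[p]][labels == other],
                        scores[[p]][labels == reference])
    tibble::tibble(pathway = p, t = unname(tt$statistic), p_value = tt$p.value)
  })
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res$reference <- reference
  res
}
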