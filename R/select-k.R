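#' Clustering prediction index over a grid of cluster counts
#'
#' Cross-validated choice-of-k criterion: the data are repeatedly split into
#' training and test halves, the full outcome-weighted pipeline (Cox weights,
#' integrated distance, MDS embedding, k-means) is fit on the training part,
#' test samples are assigned to the nearest training centroid, and the
#' criterion accumulates the squared distance of each test sample to its
#' assigned centroid. `CPI(k)` is the average of that sum over the `m_splits`
#' splits — a prediction error, so smaller is better.
#'
#' @inheritParams survclust_round
#' @param k_grid Candidate cluster counts (default 2:8).
#' @param m_splits Number of train/test splits (default 20).
#' @param split_fraction Training fraction per split (default 0.5).
#' @param n_starts k-means restarts per fit (default 25; the criterion needs
#'   stable, not exhaustive, optimization).
#' @param seed Integer seed.
#' @return Object of class `cpi_result`: list with `k_grid`, `cpi_raw`
#'   (mean over splits), `per_split` (m x length(k_grid) matrix), `m`.
#' @export
cpi_score <- function(blocks, survival, k_grid = 2:8, m_splits = 20,
                      split_fraction = 0.5, n_starts = 25, seed = 1) {
  mats <- check_blocks_aligned(blocks)
  ids <- rownames(mats[[1]])
  check_survival(survival, ids)
  n <- length(ids)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (min(k_grid) < 2 || max(k_grid) > floor(n / 3)) {
    abort("`k_grid` must lie within [2, N/3]")
  }
  n_test <- n - floor(n * split_fraction)
  if (max(k_grid) >= n_test) abort("largest k is not below the test-set size")
  per_split <- matrix(NA_real_, m_splits, length(k_grid),
                      dimnames = list(NULL, paste0("k", k_grid)))
  with_local_seed(seed, {
    for (i in seq_len(m_splits)) {
      train <- sort(sample.int(n, floor(n * split_fraction)))
      if (sum(survival$event[train]) < 2) {
        abort("a training split has < 2 events; increase split_fraction")
      }
      train_surv <- survival[train, , drop = FALSE]
      dist_m <- lapply(mats, function(m) {
        w <- cox_feature_weights(m[train, , drop = FALSE], train_surv)
        weighted_distance_matrix(m, w)
      })
      emb <- embed_distance_matrix(integrate_distances(dist_m))
      test <- setdiff(seq_len(n), train)
      for (j in seq_along(k_grid)) {
        km <- kmeans_pp(emb$coordinates[train, , drop = FALSE], k_grid[j],
                        n_starts = n_starts)
        asg <- assign_to_centroids(emb$coordinates[test, , drop = FALSE],
                                   km$centroids)
        per_split[i, j] <- sum(asg$sqdist)
      }
    }
  })
  structure(
    list(k_grid = k_grid, cpi_raw = colMeans(per_split),
         per_split = per_split, m = m_splits),
    class = "cpi_result"
  )
}

#' Gap statistic on an embedding
#'
#' Compares the log pooled within-cluster dispersion of the observed
#' embedding against its expectation under a null reference: `B` datasets
#' drawn uniformly over the per-coordinate range of the embedding
#' (Tibshirani's uniform-box null). Dispersion for cluster `r` is
#' `1/(2 n_r)` times the sum of pairwise squared Euclidean distances within
#' the cluster, which equals the cluster's within sum of squares.
#'
#' @param embedding An `mds_embedding` or coordinate matrix.
#' @param k_grid Candidate cluster counts (default 2:8).
#' @param B Number of reference datasets (default 50, must be >= 10).
#' @param n_starts k-means restarts per clustering (default 10).
#' @param seed Integer seed.
#' @return Object of class `gap_result`: list with `k_grid`, `gap`,
#'   `ref_log_wss_mean`, `obs_log_wss`, `se_gap`, `B`.
#' @export
gap_statistic <- function(embedding, k_grid = 2:8, B = 50, n_starts = 10,
                          seed = 1) {
  x <- if (inherits(embedding, "mds_embedding")) embedding$coordinates else
    as.matrix(embedding)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (B < 10) abort("`B` must be >= 10 for a stable null")
  if (min(k_grid) < 2 || max(k_grid) > nrow(x) - 1) abort("`k_grid` out of range")
  obs <- vapply(k_grid, function(k) {
    log(kmeans_pp(x, k, n_starts = n_starts)$wss)
  }, numeric(1))
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  ref <- matrix(NA_real_, B, length(k_grid))
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      xb <- sapply(seq_len(ncol(x)), function(j) runif(nrow(x), lo[j], hi[j]))
      for (j in seq_along(k_grid)) {
        ref[b, j] <- log(kmeans_pp(xb, k_grid[j], n_starts = n_starts)$wss)
      }
    }
  })
  structure(
    list(
      k_grid = k_grid,
      gap = colMeans(ref) - obs,
      ref_log_wss_mean = colMeans(ref),
      obs_log_wss = obs,
      se_gap = apply(ref, 2L, sd) * sqrt(1 + 1 / B),
      B = B
    ),
    class = "gap_result"
  )
}

#' Select the number of clusters from CPI and Gap
#'
#' The raw CPI is an error (smaller is better) while the gap statistic is a
#' benefit (larger is better), so both are brought to a common higher-is-
#' better `[0, 1]` scale — CPI negated, then each min–max rescaled over the
#' grid — and summed; `k_selected` is the argmax of the sum, with ties broken
#' toward the smaller k. Raw values are kept so the selection can be audited.
#'
#' @param cpi A `cpi_result`.
#' @param gap A `gap_result` on the same `k_grid`.
#' @return Object of class `kselect_result`: list with `scores` (tibble
#'   `k`, `cpi_raw`, `gap_raw`, `cpi_score`, `gap_score`, `combined`) and
#'   `k_selected`.
#' @export
select_k <- function(cpi, gap) {
  stopifnot(inherits(cpi, "cpi_result"), inherits(gap, "gap_result"))
  if (!identical(cpi$k_grid, gap$k_grid)) {
    abort("CPI and Gap were computed on different k grids")
  }
  rescale01 <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  cpi_score <- rescale01(-cpi$cpi_raw)
  gap_score <- rescale01(gap$gap)
  combined <- cpi_score + gap_score
  k_selected <- cpi$k_grid[which.max(combined)]  # which.max ties -> smaller k
  structure(
    list(
      scores = tibble::tibble(
        k = cpi$k_grid,
        cpi_raw = unname(cpi$cpi_raw),
        gap_raw = unname(gap$gap),
        cpi_score = unname(cpi_score),
        gap_score = unname(gap_score),
        combined = unname(combined)
      ),
      k_selected = k_selected
    ),
    class = "kselect_result"
  )
}

#' Estimate the optimal number of clusters for a cohort
#'
#' Convenience wrapper: computes the CPI over the grid via [cpi_score()],
#' the gap statistic on the full-data outcome-weighted embedding via
#' [gap_statistic()], and combines them with [select_k()].
#'
#' @inheritParams cpi_score
#' @param B Reference datasets for the gap statistic.
#' @return A `kselect_result` (with the `cpi_result` and `gap_result`
#'   attached as `$cpi` and `$gap`).
#' @export
choose_k <- function(blocks, survival, k_grid = 2:8, m_splits = 20, B = 50,
                     seed = 1) {
  mats <- check_blocks_aligned(blocks)
  check_survival(survival, rownames(mats[[1]]))
  cpi <- cpi_score(blocks, survival, k_grid = k_grid, m_splits = m_splits,
                   seed = seed)
  weights <- lapply(mats, function(m) cox_feature_weights(m, survival))
  dist_m <- Map(function(m, w) weighted_distance_matrix(m, w), mats, weights)
  emb <- embed_distance_matrix(integrate_distances(dist_m))
  gap <- gap_statistic(emb, k_grid = k_grid, B = B, seed = seed + 1L)
  out <- select_k(cpi, gap)
  out$cpi <- cpi
  out$gap <- gap
  out
}

#' @export
print.kselect_result <- function(x, ...) {
  cat(sprintf("<kselect_result> k selected = %d\n", x$k_selected))
  print(x$scores)
  invisible(x)
}

#' @rdname select_k
#' @param x,object A `kselect_result`.
#' @param ... Unused.
#' @export
tidy.kselect_result <- function(x, ...) x$scores

#' @rdname select_k
#' @export
glance.kselect_result <- function(x, ...) {
  tibble::tibble(k_selected = x$k_selected,
                 k_min = min(x$scores$k), k_max = max(x$scores$k))
}

#' @rdname select_k
#' @export
autoplot.kselect_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores,
                            c("cpi_score", "gap_score", "combined"),
                            names_to = "criterion", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$score,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = 2) +
    ggplot2::labs(title = "Cluster-number selection",
                  subtitle = sprintf("selected k = %d", object$k_selected)) +
    ggplot2::theme_minimal()
}
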