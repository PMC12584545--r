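#' One cross-validated round of outcome-weighted clustering
#'
#' Runs a single round of the weighting/clustering procedure: samples are
#' split into `n_folds` folds; for each fold, per-feature Cox weights are
#' estimated on the training folds only, weighted distances over all samples
#' are built with those weights, the integrated distance is embedded by
#' classical MDS, k-means centroids are fit on the training rows, and the
#' held-out samples are assigned to the nearest centroid. The round's
#' labeling is the union of held-out assignments across folds (fold labelings
#' are aligned to the first fold before the union, since k-means labels are
#' arbitrary per fold). Estimating the weights on training folds only keeps
#' the survival outcome from being used twice on the same samples.
#'
#' @param blocks List of standardized feature blocks sharing sample order.
#' @param survival Tibble `sample_id`, `time`, `event`, aligned.
#' @param k Number of clusters (>= 2).
#' @param n_folds Cross-validation folds (default 3).
#' @param n_starts k-means restarts (default 100).
#' @param seed Integer seed for the fold split and k-means.
#' @return List with `labels` (integer vector, one per sample, named by
#'   sample id) and `folds` (fold index per sample).
#' @export
survclust_round <- function(blocks, survival, k, n_folds = 3, n_starts = 100,
                            seed = NULL) {
  mats <- check_blocks_aligned(blocks)
  ids <- rownames(mats[[1]])
  check_survival(survival, ids)
  k <- assert_count(k, "k", min = 2L)
  n <- length(ids)
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  with_local_seed(seed, {
    folds <- sample(rep_len(seq_len(n_folds), n))
    full_labels <- matrix(0L, n_folds, n)
    for (f in seq_len(n_folds)) {
      train <- folds != f
      if (sum(survival$event[train]) < 2) {
        abort(sprintf(
          "training fold %d has < 2 events; use fewer folds or more samples", f
        ))
      }
      train_surv <- survival[train, , drop = FALSE]
      dist_m <- lapply(mats, function(m) {
        w <- cox_feature_weights(m[train, , drop = FALSE], train_surv)
        weighted_distance_matrix(m, w)
      })
      emb <- embed_distance_matrix(integrate_distances(dist_m))
      km <- kmeans_pp(emb$coordinates[train, , drop = FALSE], k,
                      n_starts = n_starts)
      full_labels[f, ] <- assign_to_centroids(emb$coordinates, km$centroids)$labels
    }
    for (f in seq_len(n_folds)[-1]) {
      full_labels[f, ] <- align_labels_to(full_labels[1, ], full_labels[f, ], k)
    }
    labels <- full_labels[cbind(folds, seq_len(n))]
    list(labels = setNames(labels, ids), folds = setNames(folds, ids))
  })
}

#' Outcome-weighted integrative clustering with consensus voting
#'
#' The package's core fit: repeats [survclust_round()] `n_rounds` times,
#' aligns each round's labeling to the first round by the label permutation
#' maximizing agreement, and takes a per-sample majority vote (ties broken
#' toward the smaller label index). The per-sample `agreement` is the
#' fraction of rounds voting the consensus label. Final centroids and
#' within-cluster sum of squares are computed on the full-data embedding
#' (weights estimated on all samples) for reporting.
#'
#' @inheritParams survclust_round
#' @param n_rounds Number of cross-validation rounds to vote over
#'   (default 50).
#' @param seed Integer seed; round `r` uses `seed + r`.
#' @return An object of class `survclust`: list with `k`, `labels`
#'   (tibble `sample_id`, `consensus_label`, `agreement`), `round_labels`
#'   (rounds x samples, aligned), `centroids`, `wss`, `embedding`,
#'   `weights` (full-data per-modality weight tibbles), `n_rounds`,
#'   `n_folds`.
#' @examples
#' \donttest{
#' ch <- simulate_cohort(n_samples = 90, seed = 3)
#' blocks <- lapply(ch$features, standardize_features)
#' fit <- survclust(blocks, ch$survival, k = 2, n_rounds = 5, n_starts = 10,
#'                  seed = 1)
#' glance(fit)
#' }
#' @export
survclust <- function(blocks, survival, k, n_rounds = 50, n_folds = 3,
                      n_starts = 100, seed = 1) {
  mats <- check_blocks_aligned(blocks)
  ids <- rownames(mats[[1]])
  check_survival(survival, ids)
  k <- assert_count(k, "k", min = 2L)
  n_rounds <- assert_count(n_rounds, "n_rounds", min = 1L)
  n <- length(ids)

  rounds <- matrix(0L, n_rounds, n, dimnames = list(NULL, ids))
  for (r in seq_len(n_rounds)) {
    rounds[r, ] <- survclust_round(blocks, survival, k, n_folds = n_folds,
                                   n_starts = n_starts, seed = seed + r)$labels
  }
  for (r in seq_len(n_rounds)[-1]) {
    rounds[r, ] <- align_labels_to(rounds[1, ], rounds[r, ], k)
  }
  votes <- apply(rounds, 2L, function(v) tabulate(v, nbins = k))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = k)
  consensus <- unname(apply(votes, 2L, which.max))  # ties toward smaller index
  agreement <- votes[cbind(consensus, seq_len(n))] / n_rounds

  # full-data geometry for reporting: weights on all samples
  weights <- lapply(mats, function(m) cox_feature_weights(m, survival))
  dist_m <- Map(function(m, w) weighted_distance_matrix(m, w), mats, weights)
  emb <- embed_distance_matrix(integrate_distances(dist_m))
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(emb$coordinates[consensus == j, , drop = FALSE])
  }))
  wss <- sum((emb$coordinates - centroids[consensus, , drop = FALSE])^2)

  structure(
    list(
      k = k,
      labels = tibble::tibble(sample_id = ids, consensus_label = consensus,
                              agreement = agreement),
      round_labels = rounds,
      centroids = centroids,
      wss = wss,
      embedding = emb,
      weights = weights,
      n_rounds = n_rounds,
      n_folds = n_folds,
      seed = seed
    ),
    class = "survclust"
  )
}

#' @export
print.survclust <- function(x, ...) {
  cat(sprintf("<survclust> k = %d, %d samples, %d rounds x %d folds\n",
              x$k, nrow(x$labels), x$n_rounds, x$n_folds))
  print(table(subtype = x$labels$consensus_label))
  cat(sprintf("mean agreement %.3f, WSS %.2f\n",
              mean(x$labels$agreement), x$wss))
  invisible(x)
}

#' @rdname survclust
#' @param x,object A `survclust` fit.
#' @param ... Unused.
#' @export
tidy.survclust <- function(x, ...) x$labels

#' @rdname survclust
#' @export
glance.survclust <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = nrow(x$labels), n_rounds = x$n_rounds, n_folds = x$n_folds,
    wss = x$wss, mean_agreement = mean(x$labels$agreement)
  )
}

#' @rdname survclust
#' @export
autoplot.survclust <- function(object, ...) {
  df <- tibble::tibble(
    dim1 = object$embedding$coordinates[, 1],
    dim2 = if (object$embedding$d >= 2) object$embedding$coordinates[, 2] else 0,
    subtype = factor(object$labels$consensus_label),
    agreement = object$labels$agreement
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = .data$subtype,
                                   alpha = .data$agreement)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha(range = c(0.35, 1)) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  title = "Outcome-weighted consensus subtypes") +
    ggplot2::theme_minimal()
}
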