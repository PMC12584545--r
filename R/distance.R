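#' Outcome-weighted pairwise distance matrix
#'
#' Computes `d(a, b) = sqrt(sum_j w_j (a_j - b_j)^2)` for all sample pairs:
#' a Euclidean metric in which every feature axis is scaled by its outcome
#' weight. With all weights equal to 1 this is the ordinary Euclidean
#' distance matrix.
#'
#' @param block Feature block (tibble with `sample_id`, or matrix).
#' @param weights Either the tibble returned by [cox_feature_weights()] or a
#'   numeric vector of non-negative weights, one per feature column.
#' @return A symmetric N x N matrix with zero diagonal and `sample_id`
#'   dimnames.
#' @examples
#' x <- tibble::tibble(sample_id = c("a", "b"), f1 = c(1, 0), f2 = c(0, 1))
#' weighted_distance_matrix(x, c(4, 1))  # sqrt(5) off-diagonal
#' @export
weighted_distance_matrix <- function(block, weights) {
  m <- as_feature_matrix(block)
  w <- if (is.data.frame(weights)) weights$weight else weights
  if (length(w) != ncol(m)) {
    abort(sprintf("got %d weights for %d features", length(w), ncol(m)))
  }
  if (any(w < 0)) abort("feature weights must be non-negative")
  scaled <- sweep(m, 2L, sqrt(w), "*")
  d <- as.matrix(dist(scaled))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Integrate per-modality distance matrices
#'
#' Averages the modality-wise weighted distance matrices with equal mixing
#' weights `gamma_m = 1/M`, producing the single integrated matrix that is
#' clustered.
#'
#' @param distances List of symmetric N x N matrices sharing sample order.
#' @return The integrated N x N matrix, with attributes `gammas` and
#'   `n_modalities`.
#' @export
integrate_distances <- function(distances) {
  if (!length(distances)) abort("need at least one distance matrix")
  ids <- rownames(distances[[1]])
  for (i in seq_along(distances)) {
    d <- distances[[i]]
    if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distances must be square matrices")
    if (!is.null(ids) && !identical(rownames(d), ids)) {
      abort("distance matrices do not share the same ordered sample ids")
    }
  }
  M <- length(distances)
  out <- Reduce(`+`, distances) / M
  attr(out, "gammas") <- rep(1 / M, M)
  attr(out, "n_modalities") <- M
  out
}

#' Embed a distance matrix by classical multidimensional scaling
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and keeps every component
#' with eigenvalue above `tol` (at most `d_max`). Pairwise Euclidean
#' distances between the returned coordinates reproduce the input exactly
#' when the matrix is Euclidean-embeddable; otherwise negative-eigenvalue
#' directions are dropped with a warning. k-means then operates on the
#' coordinates, which makes nearest-centroid assignment of held-out samples
#' well defined.
#'
#' @param distance Symmetric distance matrix (e.g. from
#'   [integrate_distances()]).
#' @param d_max Maximum number of retained dimensions (default: all
#'   above-tolerance components).
#' @param tol Eigenvalue retention threshold (default 1e-8).
#' @param neg_tol Warn when the discarded negative-eigenvalue energy
#'   exceeds this fraction of the positive energy (default 0.01; averaging
#'   Euclidean metrics routinely produces a numerically negligible negative
#'   tail, which is dropped silently).
#' @return An object of class `mds_embedding`: list with `coordinates`
#'   (N x d, sample rownames), `eigenvalues` (descending, full spectrum)
#'   and `d`; attribute `negative_energy` records the discarded fraction.
#' @export
embed_distance_matrix <- function(distance, d_max = NULL, tol = 1e-8,
                                  neg_tol = 0.01) {
  d <- distance
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`distance` must be square")
  n <- nrow(d)
  if (n < 3) abort("need at least 3 samples to embed")
  if (max(abs(d - t(d))) > 1e-10) abort("`distance` is not symmetric")
  d2 <- d * d
  # double centering without forming J explicitly
  rm_ <- rowMeans(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(d2))
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  keep <- which(e$values > tol)
  if (!length(keep)) {
    if (max(abs(d)) <= tol) {
      # degenerate but valid: all samples coincide
      coords <- matrix(0, n, 1L, dimnames = list(rownames(d), NULL))
      return(structure(
        list(coordinates = coords, eigenvalues = e$values, d = 1L),
        class = "mds_embedding", negative_energy = 0
      ))
    }
    abort("no positive-eigenvalue component to retain")
  }
  if (!is.null(d_max)) keep <- keep[seq_len(min(length(keep), d_max))]
  neg_energy <- sum(abs(e$values[e$values < 0])) / sum(e$values[e$values > 0])
  if (neg_energy > neg_tol) {
    warn(sprintf(
      "distance matrix is not Euclidean-embeddable: negative eigenvalues carry %.1f%% of the energy; dropped",
      100 * neg_energy
    ))
  }
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(d)
  structure(
    list(coordinates = coords, eigenvalues = e$values, d = length(keep)),
    class = "mds_embedding",
    negative_energy = neg_energy
  )
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d samples in %d dimensions\n",
              nrow(x$coordinates), x$d))
  invisible(x)
}
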