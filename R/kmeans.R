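#' k-means with k-means++ initialization on embedding coordinates
#'
#' Lloyd's algorithm started from k-means++ seeds, repeated `n_starts` times
#' with the best solution by within-cluster sum of squares retained.
#' Convergence is declared when every centroid moves less than `tol`
#' (Euclidean displacement) between consecutive iterations, or after
#' `max_iter` iterations.
#'
#' @param x An `mds_embedding` from [embed_distance_matrix()], or a numeric
#'   coordinate matrix (rows = samples).
#' @param k Number of clusters, `2 <= k <= N - 1`.
#' @param n_starts Number of random restarts (default 100).
#' @param max_iter Maximum Lloyd iterations per start (default 100).
#' @param tol Centroid-displacement convergence threshold (default 1e-5).
#' @param seed Integer seed; the same seed reproduces the solution exactly.
#' @return List with `labels` (1..k), `centroids` (k x d), `wss`, and
#'   `iterations` of the winning start.
#' @examples
#' pts <- rbind(matrix(rnorm(20, -5), 10), matrix(rnorm(20, 5), 10))
#' kmeans_pp(pts, k = 2, n_starts = 5, seed = 1)$labels
#' @export
kmeans_pp <- function(x, k, n_starts = 100, max_iter = 100, tol = 1e-5,
                      seed = NULL) {
  if (inherits(x, "mds_embedding")) x <- x$coordinates
  x <- as.matrix(x)
  n <- nrow(x)
  k <- assert_count(k, "k", min = 2L)
  if (k > n - 1) abort(sprintf("k = %d out of range for %d samples", k, n))
  xsq <- .rowSums(x * x, nrow(x), ncol(x))
  with_local_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- lloyd_once(x, xsq, k, max_iter, tol)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
    best$labels <- setNames(best$labels, rownames(x))
    best
  })
}

# one k-means++ initialized Lloyd run; xsq = precomputed row squared norms
lloyd_once <- function(x, xsq, k, max_iter, tol) {
  n <- nrow(x)
  d <- ncol(x)
  centers <- kmeanspp_init(x, xsq, k)
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cross <- x %*% t(centers)
    csq <- .rowSums(centers * centers, k, d)
    d2 <- xsq - 2 * cross + rep(csq, each = n)
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      idx <- labels == j
      nj <- sum(idx)
      if (nj > 0L) {
        new_centers[j, ] <- .colMeans(x[idx, , drop = FALSE], nj, d)
      } else {
        # re-seed an empty cluster at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), labels)])
        new_centers[j, ] <- x[far, ]
      }
    }
    moved <- sqrt(.rowSums((new_centers - centers)^2, k, d))
    centers <- new_centers
    if (max(moved) < tol || iter >= max_iter) break
  }
  csq <- .rowSums(centers * centers, k, d)
  d2 <- xsq - 2 * (x %*% t(centers)) + rep(csq, each = n)
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
  list(labels = labels, centroids = centers, wss = wss, iterations = iter)
}

kmeanspp_init <- function(x, xsq, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  pick <- sample.int(n, 1L)
  centers[1, ] <- x[pick, ]
  min_d2 <- pmax(xsq - 2 * drop(x %*% x[pick, ]) + xsq[pick], 0)
  for (j in seq_len(k)[-1]) {
    if (all(min_d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = min_d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmax(xsq - 2 * drop(x %*% x[pick, ]) + xsq[pick], 0)
    min_d2 <- pmin(min_d2, d2)
  }
  centers
}

# labels and squared distances of rows of x to their nearest centroid;
# ties go to the smaller cluster index
assign_to_centroids <- function(x, centroids) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x * x), rowSums(centroids * centroids), "+") -
    2 * x %*% t(centroids)
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels, sqdist = pmax(d2[cbind(seq_len(nrow(x)), labels)], 0))
}
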