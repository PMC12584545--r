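# Independent oracles used to verify package computations.

# Univariate Cox partial-likelihood maximizer by Newton-Raphson (Breslow
# risk sets; no ties expected in the continuous-time fixtures). Written from
# the partial-likelihood definition, independent of the survival package.
oracle_cox_univariate <- function(x, time, event, max_iter = 50, tol = 1e-10) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  n <- length(x)
  beta <- 0
  for (it in seq_len(max_iter)) {
    eta <- exp(beta * x)
    # risk set of subject i = subjects with time >= time_i (sorted: i..n)
    s0 <- rev(cumsum(rev(eta)))
    s1 <- rev(cumsum(rev(x * eta)))
    s2 <- rev(cumsum(rev(x^2 * eta)))
    u <- sum(event * (x - s1 / s0))
    i_info <- sum(event * (s2 / s0 - (s1 / s0)^2))
    step <- u / i_info
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Brute-force weighted distance by an explicit double loop over pairs.
oracle_weighted_dist <- function(m, w) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      d[a, b] <- sqrt(sum(w * (m[a, ] - m[b, ])^2))
    }
  }
  d
}

# Minimum within-cluster sum of squares over every assignment of n points
# to k labels (exhaustive enumeration; n <= 12).
oracle_min_wss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    lab <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      lab[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    if (length(unique(lab)) < k) next
    wss <- 0
    for (j in seq_len(k)) {
      pts <- x[lab == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2L, ctr, "-")^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# Pooled within-cluster dispersion from the pairwise squared-distance form.
oracle_gap_dispersion <- function(x, labels) {
  total <- 0
  for (j in unique(labels)) {
    pts <- x[labels == j, , drop = FALSE]
    d2 <- as.matrix(dist(pts))^2
    total <- total + sum(d2) / (2 * nrow(pts))
  }
  total
}

# AUC by explicit enumeration of positive-negative pairs.
oracle_auc <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  conc / (length(pos) * length(neg))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
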