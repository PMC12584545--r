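# Shared fixtures, built in code at test time.

# small strong two-subtype cohort for clustering tests
strong_cohort <- function(n = 120, seed = 1) {
  simulate_cohort(
    n_samples = n,
    modalities = list(c(p_features = 60, n_informative = 12),
                      c(p_features = 60, n_informative = 12)),
    effect_size = 2, subtype_log_hr = c(0, 1), seed = seed
  )
}

# cohort with no subtype structure at all
null_cohort <- function(n = 120, seed = 1, p = 60) {
  simulate_cohort(
    n_samples = n,
    modalities = list(c(p_features = p, n_informative = 0)),
    effect_size = 0, subtype_log_hr = c(0, 0), marker_features = 0,
    seed = seed
  )
}

std_blocks <- function(cohort) lapply(cohort$features, standardize_features)

# survival-signal block A plus an outcome-irrelevant confounder block B
# whose latent partition is stronger (effect 3) than the survival-linked one
confounded_cohort <- function(n = 200, seed = 1) {
  ch <- simulate_cohort(
    n_samples = n,
    modalities = list(c(p_features = 100, n_informative = 20)),
    marker_features = 0, seed = seed
  )
  set.seed(seed + 1000)
  conf <- sample(1:2, n, replace = TRUE)
  b <- matrix(rnorm(n * 100), n, 100)
  b[, 1:20] <- b[, 1:20] + 3 * (conf - 1)
  colnames(b) <- sprintf("conf_f%03d", seq_len(100))
  rownames(b) <- ch$survival$sample_id
  list(cohort = ch, confounder = b, conf_partition = conf)
}

joint_marker_matrix <- function(cohort) {
  m <- do.call(cbind, lapply(cohort$features, function(b) {
    x <- as.matrix(b[, -1])
    rownames(x) <- b$sample_id
    x
  }))
  m
}
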