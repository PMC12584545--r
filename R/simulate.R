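#' Simulate a multimodal cohort with survival-linked latent subtypes
#'
#' Generates the data structure the outcome-weighted clustering pipeline
#' assumes: several standardized-scale feature blocks in which only a subset
#' of features carries the subtype signal, right-censored survival times whose
#' hazard depends on the latent subtype, and a binary molecular marker
#' correlated with subtype and with a sparse set of additional features.
#' Every downstream stage of the package can be exercised on the result.
#'
#' Informative features are drawn `N(effect_size * (g - 1) * s_j, 1)` for
#' subtype `g` with a random per-feature sign `s_j`; the remaining features
#' are standard normal noise. Event times are exponential with per-sample
#' rate `exp(subtype_log_hr[g]) / baseline_scale` (proportional hazards by
#' construction); censoring times are independent exponentials whose rate is
#' found by bisection so the expected censored fraction equals `censor_rate`.
#' The marker is a subtype-linked Bernoulli flipped with probability
#' `1 - marker_assoc`, and `marker_features` noise columns of the first block
#' receive an additional mean shift of `marker_shift` for marker-positive
#' samples, so marker-prediction stages have a recoverable sparse target.
#'
#' @param n_samples Number of samples.
#' @param modalities List with one element per feature block, each a named
#'   vector `c(p_features = , n_informative = )`.
#' @param k_true Number of latent subtypes (>= 2).
#' @param mixing Subtype proportions (length `k_true`, sum 1). Default equal.
#' @param effect_size Mean shift, in SD units, of informative features
#'   between consecutive subtypes (>= 0).
#' @param subtype_log_hr Per-subtype log hazard relative to subtype 1
#'   (length `k_true`).
#' @param baseline_scale Scale (time units, months by convention) of the
#'   baseline exponential event-time distribution.
#' @param censor_rate Target censored fraction in `[0, 1)`.
#' @param marker_assoc Probability the binary marker agrees with its
#'   subtype-linked Bernoulli.
#' @param marker_features Number of first-block noise columns given a
#'   marker-linked shift.
#' @param marker_shift Size of that shift (SD units).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `synthetic_cohort`: a list with
#'   `features` (named list of tibbles, first column `sample_id`),
#'   `survival` (`sample_id`, `time`, `event`), `marker` (`sample_id`,
#'   `label` in `{"MGMTmet&IDHmut", "Others"}`), `truth` (`sample_id`,
#'   `true_label`), `informative` (per-modality integer index vectors),
#'   `marker_informative` (indices in block 1), and the call's `config`.
#' @examples
#' ch <- simulate_cohort(n_samples = 60, seed = 1)
#' table(ch$truth$true_label)
#' @export
simulate_cohort <- function(n_samples = 200,
                            modalities = list(
                              c(p_features = 100, n_informative = 20),
                              c(p_features = 100, n_informative = 20)
                            ),
                            k_true = 2,
                            mixing = NULL,
                            effect_size = 2,
                            subtype_log_hr = c(0, 1),
                            baseline_scale = 60,
                            censor_rate = 0.65,
                            marker_assoc = 0.8,
                            marker_features = 5,
                            marker_shift = 1.5,
                            seed = 1) {
  n_samples <- assert_count(n_samples, "n_samples", min = 4L)
  k_true <- assert_count(k_true, "k_true", min = 2L)
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (is.null(mixing)) mixing <- rep(1 / k_true, k_true)
  if (length(mixing) != k_true || abs(sum(mixing) - 1) > 1e-9 || any(mixing < 0)) {
    abort("`mixing` must have length k_true, be non-negative and sum to 1")
  }
  if (length(subtype_log_hr) != k_true) {
    abort("`subtype_log_hr` must have length k_true")
  }
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1)")
  for (m in modalities) {
    if (m[["n_informative"]] > m[["p_features"]]) {
      abort("n_informative cannot exceed p_features")
    }
  }

  config <- list(
    n_samples = n_samples, modalities = modalities, k_true = k_true,
    mixing = mixing, effect_size = effect_size, subtype_log_hr = subtype_log_hr,
    baseline_scale = baseline_scale, censor_rate = censor_rate,
    marker_assoc = marker_assoc, marker_features = marker_features,
    marker_shift = marker_shift, seed = seed
  )

  with_local_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n_samples))
    true_label <- sample.int(k_true, n_samples, replace = TRUE, prob = mixing)

    # subtype-linked Bernoulli, flipped with prob 1 - marker_assoc
    linked <- as.integer(true_label <= ceiling(k_true / 2))
    flip <- rbinom(n_samples, 1L, 1 - marker_assoc)
    marker <- ifelse(flip == 1L, 1L - linked, linked)

    informative <- vector("list", length(modalities))
    blocks <- vector("list", length(modalities))
    marker_idx <- integer(0)
    for (m in seq_along(modalities)) {
      p <- as.integer(modalities[[m]][["p_features"]])
      n_inf <- as.integer(modalities[[m]][["n_informative"]])
      x <- matrix(rnorm(n_samples * p), n_samples, p)
      inf_idx <- seq_len(n_inf)
      if (n_inf > 0 && effect_size > 0) {
        signs <- sample(c(-1, 1), n_inf, replace = TRUE)
        shift <- outer(effect_size * (true_label - 1), signs)
        x[, inf_idx] <- x[, inf_idx] + shift
      }
      if (m == 1L && marker_features > 0 && marker_shift > 0) {
        # marker signal lives in noise columns, disjoint from subtype signal
        marker_idx <- seq.int(p - marker_features + 1L, p)
        x[, marker_idx] <- x[, marker_idx] + marker_shift * marker
      }
      colnames(x) <- sprintf("mod%d_f%04d", m, seq_len(p))
      rownames(x) <- ids
      informative[[m]] <- inf_idx
      blocks[[m]] <- as_feature_tibble(x)
    }
    names(blocks) <- sprintf("modality_%d", seq_along(blocks))
    names(informative) <- names(blocks)

    rate <- exp(subtype_log_hr[true_label]) / baseline_scale
    t_event <- rexp(n_samples, rate)
    if (censor_rate > 0) {
      c_rate <- calibrate_censor_rate(rate, censor_rate)
      t_cens <- rexp(n_samples, c_rate)
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    structure(
      list(
        features = blocks,
        survival = tibble::tibble(sample_id = ids, time = time, event = event),
        marker = tibble::tibble(
          sample_id = ids,
          label = ifelse(marker == 1L, "MGMTmet&IDHmut", "Others")
        ),
        truth = tibble::tibble(sample_id = ids, true_label = true_label),
        informative = informative,
        marker_informative = marker_idx,
        config = config
      ),
      class = "synthetic_cohort"
    )
  })
}

# For exponential event times with per-sample rate lambda_i and a common
# exponential censoring rate c, E[censored fraction] = mean(c / (c + lambda)).
# Monotone in c, so bisection finds the rate hitting the target exactly.
calibrate_censor_rate <- function(event_rates, target) {
  f <- function(cr) mean(cr / (cr + event_rates)) - target
  lo <- 1e-12
  hi <- max(event_rates) * 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_cohort> %d samples, %d modalities (%s features), k_true = %d\n",
    cfg$n_samples, length(x$features),
    paste(vapply(x$features, function(b) ncol(b) - 1L, integer(1)), collapse = " + "),
    cfg$k_true
  ))
  cat(sprintf(
    "  events: %d (%.0f%% censored), marker positive: %d\n",
    sum(x$survival$event), 100 * mean(1 - x$survival$event),
    sum(x$marker$label == "MGMTmet&IDHmut")
  ))
  invisible(x)
}

#' Simulate a gene-expression matrix from pathway weights and activities
#'
#' Builds expression as `weights %*% t(activities)` plus Gaussian noise, the
#' generative model inverted by [mlm_activity()]. Used to test the pathway
#' scoring stage with known ground truth.
#'
#' @param weights Pathway weight input: either a genes x pathways numeric
#'   matrix with dimnames, or a long tibble with columns `gene`, `pathway`,
#'   `weight` (and optionally `p_value`).
#' @param activities Samples x pathways matrix (or data frame) of true
#'   activity levels; rownames (or a `sample_id` column) name the samples.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return A tibble with a `gene` column and one numeric column per sample.
#' @examples
#' w <- matrix(c(1, 2, 0, 0, 0, 0, 3, 1), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("A", "B")))
#' act <- matrix(c(1, -1, 0, 2), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("A", "B")))
#' simulate_pathway_expression(w, act, noise_sd = 0)
#' @export
simulate_pathway_expression <- function(weights, activities, noise_sd = 0.1,
                                        seed = 1) {
  w <- as_weight_matrix(weights)
  if (nrow(w) < 2 || ncol(w) < 1) abort("`weights` needs >= 1 pathway and >= 2 genes")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  a <- activities
  if (is.data.frame(a)) {
    if ("sample_id" %in% names(a)) {
      rn <- a$sample_id
      a <- as.matrix(a[setdiff(names(a), "sample_id")])
      rownames(a) <- rn
    } else {
      a <- as.matrix(a)
    }
  }
  if (ncol(a) != ncol(w)) {
    abort(sprintf("`activities` has %d pathways but `weights` has %d",
                  ncol(a), ncol(w)))
  }
  if (is.null(rownames(a))) rownames(a) <- sprintf("S%04d", seq_len(nrow(a)))
  with_local_seed(seed, {
    expr <- w %*% t(a)
    if (noise_sd > 0) {
      expr <- expr + matrix(rnorm(length(expr), sd = noise_sd),
                            nrow(expr), ncol(expr))
    }
    tibble::as_tibble(expr, .name_repair = "minimal") |>
      dplyr::mutate(gene = rownames(w), .before = 1L)
  })
}

# Accept a genes x pathways matrix or a long (gene, pathway, weight) tibble;
# return the matrix form with gene rownames. Missing pairs get weight 0.
as_weight_matrix <- function(weights) {
  if (is.matrix(weights)) {
    if (is.null(rownames(weights)) || is.null(colnames(weights))) {
      abort("weight matrix needs gene rownames and pathway colnames")
    }
    storage.mode(weights) <- "double"
    return(weights)
  }
  if (!is.data.frame(weights) ||
      !all(c("gene", "pathway", "weight") %in% names(weights))) {
    abort("`weights` must be a matrix or a tibble with gene, pathway, weight")
  }
  genes <- unique(weights$gene)
  paths <- unique(weights$pathway)
  m <- matrix(0, length(genes), length(paths), dimnames = list(genes, paths))
  m[cbind(match(weights$gene, genes), match(weights$pathway, paths))] <-
    weights$weight
  m
}

#' Write a synthetic cohort to delimited files
#'
#' Emits one TSV per feature block (`features_<name>.tsv`), plus
#' `survival.tsv`, `marker.tsv` and `truth.tsv`, all with a `sample_id`
#' first column, as read back by [read_feature_matrix()] and friends.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort$features)) {
    p <- file.path(dir, sprintf("features_%s.tsv", nm))
    readr::write_tsv(cohort$features[[nm]], p)
    paths <- c(paths, p)
  }
  for (nm in c("survival", "marker", "truth")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(cohort[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
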