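#' Per-feature Cox log-hazard weights
#'
#' Fits a univariable Cox proportional hazards model for every feature
#' column and returns `|beta|`, the absolute log hazard ratio, as the
#' feature's outcome weight. Features unrelated to survival get weights near
#' zero and are thereby down-weighted in the clustering metric; degenerate or
#' non-convergent fits get weight 0 with `converged = FALSE`. Estimates are
#' capped at `beta_cap` in absolute value so a single separating feature
#' cannot dominate the distance.
#'
#' @param block Standardized feature block ([standardize_features()]).
#' @param survival Tibble with `sample_id`, `time`, `event` aligned with the
#'   block's sample order.
#' @param beta_cap Cap on `|beta|` before use as a weight (default 10).
#' @param ties Tie handling passed to the Cox fitter (default `"efron"`).
#' @return A tibble with columns `feature`, `beta`, `weight`, `converged`.
#' @examples
#' ch <- simulate_cohort(n_samples = 80, seed = 2)
#' blk <- standardize_features(ch$features[[1]])
#' w <- cox_feature_weights(blk, ch$survival)
#' head(w)
#' @export
cox_feature_weights <- function(block, survival, beta_cap = 10,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  m <- as_feature_matrix(block)
  check_survival(survival, rownames(m))
  if (sum(survival$event) < 2) {
    abort("need at least 2 events to estimate feature weights")
  }
  y <- survival::Surv(survival$time, survival$event)
  ctrl <- survival::coxph.control()
  cox_fit <- survival::coxph.fit  # resolve once; the loop is hot
  p <- ncol(m)
  beta <- numeric(p)
  converged <- logical(p)
  suppressWarnings(
    for (j in seq_len(p)) {
      x <- m[, j, drop = FALSE]
      if (!all(is.finite(x)) || sd(x) == 0) next
      fit <- tryCatch(
        cox_fit(x, y, strata = NULL, offset = NULL, init = 0,
                control = ctrl, weights = NULL, method = ties,
                rownames = NULL),
        error = function(e) NULL
      )
      if (is.null(fit) || is.na(fit$coefficients) ||
          !is.finite(fit$coefficients) || fit$iter >= ctrl$iter.max) next
      beta[j] <- unname(fit$coefficients)
      converged[j] <- TRUE
    }
  )
  capped <- pmin(pmax(beta, -beta_cap), beta_cap)
  if (any(abs(beta) > beta_cap)) {
    inform(sprintf("%d feature weight(s) capped at |beta| = %g",
                   sum(abs(beta) > beta_cap), beta_cap))
  }
  tibble::tibble(
    feature = colnames(m),
    beta = capped,
    weight = abs(capped),
    converged = converged
  )
}
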