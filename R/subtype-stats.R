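#' Chi-square test for a subtype contingency table
#'
#' Pearson chi-square on an r x c table of counts. For 2 x 2 tables the
#' Yates continuity correction is applied when `continuity = "auto"`
#' (the convention used for the cohort baseline tables this reproduces);
#' larger tables are never corrected.
#'
#' @param counts Matrix (or data frame) of non-negative integer counts.
#' @param continuity `"auto"` (correct 2 x 2 only), `TRUE`, or `FALSE`.
#' @return A tibble with `statistic`, `df`, `p_value`,
#'   `correction_applied`.
#' @examples
#' # MGMT-IDH by subtype
#' chi_square_test(matrix(c(35, 16, 44, 67), 2))
#' @export
chi_square_test <- function(counts, continuity = "auto") {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != floor(m))) abort("`counts` must be non-negative integers")
  if (sum(m) == 0) abort("empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero marginal in the contingency table")
  }
  correct <- if (identical(continuity, "auto")) all(dim(m) == c(2L, 2L))
             else isTRUE(continuity)
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  if (any(ct$expected <= 0)) abort("expected count of zero in the table")
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    correction_applied = correct
  )
}

#' Kruskal-Wallis rank test across subtype groups
#'
#' Tie-corrected Kruskal-Wallis H with `df = groups - 1`. A fully tied
#' sample (zero rank variance) returns `H = 0`, `p = 1` rather than a
#' division by zero.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; >= 2 non-empty groups.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (length(values) != length(groups)) abort("`values` and `groups` differ in length")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Kaplan-Meier curves and log-rank test with an administrative cutoff
#'
#' Truncates follow-up at `cutoff_months` (times beyond the cutoff are set
#' to the cutoff and their events recoded as censored — the usual reading of
#' a "five-year cutoff"), then estimates product-limit curves per group and
#' runs the standard log-rank test.
#'
#' @param survival Tibble `sample_id`, `time`, `event`.
#' @param groups Group label per sample (same order).
#' @param cutoff_months Administrative censoring time (default 60; `Inf`
#'   disables truncation).
#' @return Object of class `km_logrank`: list with `km` (tidy per-group
#'   step-function tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `survival`), `logrank` (tibble `statistic`, `df`, `p_value`), and the
#'   truncated data.
#' @export
km_logrank <- function(survival, groups, cutoff_months = 60) {
  check_survival(survival)
  groups <- factor(groups)
  if (length(groups) != nrow(survival)) abort("`groups` misaligned with `survival`")
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  time <- pmin(survival$time, cutoff_months)
  event <- ifelse(survival$time > cutoff_months, 0L, survival$event)
  if (sum(event) < 1) abort("no events within the cutoff")
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_lab <- rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  km <- tibble::tibble(
    group = strata_lab,
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    survival = sf$surv
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd_$n) - 1L
  logrank <- tibble::tibble(
    statistic = sd_$chisq,
    df = df,
    p_value = pchisq(sd_$chisq, df, lower.tail = FALSE)
  )
  structure(
    list(km = km, logrank = logrank,
         data = tibble::tibble(sample_id = survival$sample_id, time = time,
                               event = event, group = groups),
         cutoff_months = cutoff_months),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> cutoff %.0f months; log-rank chi-square %.3f (df %d), p = %.3g\n",
              x$cutoff_months, x$logrank$statistic, x$logrank$df,
              x$logrank$p_value))
  invisible(x)
}

#' @rdname km_logrank
#' @param x,object A `km_logrank` result.
#' @param ... Unused.
#' @export
tidy.km_logrank <- function(x, ...) x$km

#' @rdname km_logrank
#' @export
glance.km_logrank <- function(x, ...) x$logrank

#' @rdname km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  km <- dplyr::group_by(object$km, .data$group)
  start <- dplyr::summarise(km, time = 0, survival = 1)
  df <- dplyr::bind_rows(start,
                         dplyr::select(object$km, "group", "time", "survival"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g",
                                     object$logrank$p_value)) +
    ggplot2::theme_minimal()
}

#' Multivariable Cox model with Schoenfeld diagnostics and EPV
#'
#' Fits a Cox proportional hazards model (Efron tie handling) of survival on
#' the supplied covariates, reports per-covariate log hazard ratios with
#' Wald tests and 95% confidence intervals (`HR = exp(B)`,
#' `CI = exp(B +/- 1.96 SE)`), tests proportional hazards via the Schoenfeld
#' residuals (Kaplan-Meier time transform by default), and reports events
#' per variable (events divided by the number of estimated coefficients).
#'
#' @param survival Tibble `sample_id`, `time`, `event`.
#' @param covariates Data frame of covariates; a `sample_id` column, if
#'   present, must match the survival order. Factors and numerics allowed.
#' @param zph_transform Time transform for the Schoenfeld test
#'   (default `"km"`).
#' @return Object of class `cox_result`: list with `coefficients` (tibble
#'   `term`, `B`, `SE`, `wald`, `p_value`, `HR`, `CI_lower`, `CI_upper`),
#'   `schoenfeld` (tibble `term`, `chisq`, `df`, `p_value`, including a
#'   `GLOBAL` row), `epv`, `n`, `events`, and the `survival::coxph` `fit`.
#' @export
fit_cox_multivariable <- function(survival, covariates, zph_transform = "km") {
  check_survival(survival)
  covs <- as.data.frame(covariates)
  if ("sample_id" %in% names(covs)) {
    if (!identical(as.character(covs$sample_id),
                   as.character(survival$sample_id))) {
      abort("`covariates` rows are not aligned with `survival`")
    }
    covs$sample_id <- NULL
  }
  if (nrow(covs) != nrow(survival)) abort("`covariates` misaligned with `survival`")
  const <- vapply(covs, function(v) length(unique(v)) == 1L, logical(1))
  if (any(const)) {
    abort(sprintf("constant covariate(s): %s",
                  paste(names(covs)[const], collapse = ", ")))
  }
  dat <- cbind(.time = survival$time, .event = survival$event, covs)
  fit <- tryCatch(
    survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = dat, ties = "efron", model = TRUE
    ),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w))) {
        abort(paste("Cox fit did not converge cleanly:", conditionMessage(w)))
      }
      suppressWarnings(survival::coxph(survival::Surv(.time, .event) ~ .,
                                       data = dat, ties = "efron", model = TRUE))
    }
  )
  b <- coef(fit)
  if (any(!is.finite(b))) abort("Cox fit produced non-finite coefficients (separation?)")
  se <- sqrt(diag(fit$var))
  n_cov <- length(b)
  events <- sum(survival$event)
  if (events < n_cov) abort("fewer events than covariates")
  zph <- survival::cox.zph(fit, transform = zph_transform)
  zt <- as.data.frame(zph$table)
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(b),
        B = unname(b),
        SE = unname(se),
        wald = unname((b / se)^2),
        p_value = unname(pchisq((b / se)^2, 1, lower.tail = FALSE)),
        HR = exp(unname(b)),
        CI_lower = exp(unname(b - 1.96 * se)),
        CI_upper = exp(unname(b + 1.96 * se))
      ),
      schoenfeld = tibble::tibble(
        term = rownames(zt),
        chisq = zt$chisq,
        df = zt$df,
        p_value = zt$p
      ),
      epv = events / n_cov,
      n = nrow(survival),
      events = events,
      fit = fit
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, EPV = %.1f\n",
              x$n, x$events, x$epv))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_cox_multivariable
#' @param x,object A `cox_result`.
#' @param ... Unused.
#' @export
tidy.cox_result <- function(x, ...) x$coefficients

#' @rdname fit_cox_multivariable
#' @export
glance.cox_result <- function(x, ...) {
  glob <- x$schoenfeld[x$schoenfeld$term == "GLOBAL", ]
  tibble::tibble(n = x$n, events = x$events, epv = x$epv,
                 schoenfeld_global_p = glob$p_value)
}

#' @rdname fit_cox_multivariable
#' @export
autoplot.cox_result <- function(object, ...) {
  df <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(.data$HR, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$CI_lower,
                                         xmax = .data$CI_upper),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
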