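#' Stability feature selection with L1-penalized logistic regression
#'
#' Repeats a stratified 80/20 split `n_splits` times; on each training part
#' an L1-penalized logistic regression is fit with its penalty chosen by
#' `cv_folds`-fold cross-validated binomial deviance (100 log-spaced lambda
#' values from the data-driven maximum down to `1e-4` of it), and the
#' features with nonzero coefficients at the chosen lambda are recorded.
#' Features whose selection frequency reaches `freq_threshold` form the
#' final selected set.
#'
#' @param block Feature block (tibble with `sample_id`, or matrix); normally
#'   the matrix of differential features.
#' @param labels Binary label per sample; the class named
#'   `"MGMTmet&IDHmut"`, when present, is treated as positive (otherwise
#'   set `positive`).
#' @param n_splits Number of random splits (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param cv_folds Cross-validation folds for the penalty (default 10).
#' @param freq_threshold Selection-frequency threshold (default 0.10).
#' @param seed Base seed; split `s` uses `seed + s - 1`, so the default
#'   reproduces seeds 1 to `n_splits`.
#' @param positive Positive class label (default auto-detected).
#' @return Object of class `stability_selection`: list with `frequencies`
#'   (tibble `feature`, `frequency`, `selected`), `selected` (character
#'   vector), `lambdas` (per split), `n_splits`.
#' @export
stability_select <- function(block, labels, n_splits = 100,
                             train_fraction = 0.8, cv_folds = 10,
                             freq_threshold = 0.10, seed = 1,
                             positive = NULL) {
  m <- as_feature_matrix(block)
  y <- binarize_labels(labels, positive, n = nrow(m))
  if (min(table(y)) < 20) abort("need at least 20 samples per class")
  counts <- setNames(numeric(ncol(m)), colnames(m))
  lambdas <- numeric(n_splits)
  n <- nrow(m)
  for (s in seq_len(n_splits)) {
    with_local_seed(seed + s - 1L, {
      train <- stratified_split(y, train_fraction)
      for (retry in 1:10) {
        if (length(unique(y[train])) == 2L) break
        inform("resampling a split with a missing class")
        train <- stratified_split(y, train_fraction)
        if (retry == 10) abort("could not draw a split containing both classes")
      }
      cv <- glmnet::cv.glmnet(m[train, , drop = FALSE], y[train],
                              family = "binomial", alpha = 1,
                              nfolds = cv_folds, nlambda = 100,
                              lambda.min.ratio = 1e-4,
                              type.measure = "deviance")
      lambdas[s] <- cv$lambda.min
      cf <- coef(cv, s = "lambda.min")
      nz <- rownames(cf)[as.vector(cf != 0)]
      nz <- setdiff(nz, "(Intercept)")
      counts[nz] <- counts[nz] + 1
    })
  }
  freq <- counts / n_splits
  structure(
    list(
      frequencies = tibble::tibble(
        feature = names(freq),
        frequency = unname(freq),
        selected = unname(freq >= freq_threshold)
      ),
      selected = names(freq)[freq >= freq_threshold],
      lambdas = lambdas,
      n_splits = n_splits,
      freq_threshold = freq_threshold
    ),
    class = "stability_selection"
  )
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("<stability_selection> %d/%d features at frequency >= %.0f%% over %d splits\n",
              length(x$selected), nrow(x$frequencies),
              100 * x$freq_threshold, x$n_splits))
  invisible(x)
}

#' @rdname stability_select
#' @param x,object A `stability_selection`.
#' @param ... Unused.
#' @export
tidy.stability_selection <- function(x, ...) x$frequencies

#' @rdname stability_select
#' @export
autoplot.stability_selection <- function(object, ...) {
  df <- dplyr::arrange(object$frequencies, dplyr::desc(.data$frequency))
  df <- head(df, 40L)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$feature,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$freq_threshold, linetype = 2) +
    ggplot2::labs(x = "Selection frequency", y = NULL) +
    ggplot2::theme_minimal()
}

binarize_labels <- function(labels, positive = NULL, n = NULL) {
  if (is.data.frame(labels)) labels <- labels$label
  if (!is.null(n) && length(labels) != n) {
    abort("labels are misaligned with the feature rows")
  }
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) abort("labels must have exactly 2 classes")
  pos <- positive %||%
    (if ("MGMTmet&IDHmut" %in% lev) "MGMTmet&IDHmut" else sort(lev)[1])
  as.integer(labels == pos)
}

stratified_split <- function(y, train_fraction) {
  sort(unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(length(idx) * train_fraction)))
  })))
}

#' Eight classification metrics from scores and binary truth
#'
#' AUC is computed from the Mann-Whitney rank statistic (ties as
#' mid-ranks); the remaining metrics come from the confusion matrix at
#' `threshold` on the score: sensitivity, specificity, accuracy, Youden
#' index (`Se + Sp - 1`), F-measure (harmonic mean of precision and
#' sensitivity), Matthews correlation coefficient, and G-means
#' (`sqrt(Se * Sp)`). Undefined ratios (zero denominators) are reported
#' as 0.
#'
#' @param y_true Binary truth (0/1), both classes present.
#' @param y_score Predicted probability of the positive class.
#' @param threshold Classification threshold (default 0.5).
#' @return A one-row tibble with `AUC`, `Se`, `Sp`, `ACC`, `Youden`,
#'   `F_measure`, `MCC`, `G_means`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))  # AUC 0.75
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y <- as.integer(y_true)
  if (length(unique(y)) < 2L) abort("both classes must be present")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(y_score)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  se <- tp / n1
  sp <- tn / n0
  acc <- (tp + tn) / (n1 + n0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + se == 0) 0 else 2 * prec * se / (prec + se)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  tibble::tibble(
    AUC = auc, Se = se, Sp = sp, ACC = acc,
    Youden = se + sp - 1,
    F_measure = f1,
    MCC = mcc,
    G_means = sqrt(se * sp)
  )
}

#' Repeated-split benchmark of binary-marker classifiers
#'
#' Repeats a stratified train/test split `n_splits` times and, on each
#' split, fits the requested classifiers on the training part and scores
#' the test part, computing the eight metrics of [compute_metrics()] at
#' probability threshold 0.5. Splits whose test part contains a single
#' class are recorded as missing and excluded from the per-model summary
#' means. Classifiers: logistic regression (`"LR"`), random forest
#' (`"RF"`, 500 trees), radial-kernel SVM with probability estimates
#' (`"SVM"`), and k-nearest neighbours (`"kNN"`, k = 5, neighbour-vote
#' fraction as the score). Additional classifiers can be plugged in via
#' `extra_models`, a named list of `function(x_train, y_train, x_test)`
#' returning positive-class scores.
#'
#' @inheritParams stability_select
#' @param models Subset of `c("LR", "RF", "SVM", "kNN")`.
#' @param n_splits Number of repeated splits (default 1000).
#' @param rf_trees Random-forest size (default 500).
#' @param knn_k Neighbour count for kNN (default 5).
#' @param extra_models Named list of additional classifier functions.
#' @return Object of class `model_benchmark`: list with `metrics`
#'   (tibble: `split`, `model`, eight metric columns), `summary`
#'   (per-model means over non-degenerate splits), `n_splits`,
#'   `n_excluded`.
#' @export
train_and_evaluate <- function(block, labels,
                               models = c("LR", "RF", "SVM", "kNN"),
                               n_splits = 1000, train_fraction = 0.8,
                               seed = 1, positive = NULL,
                               rf_trees = 500, knn_k = 5,
                               extra_models = NULL) {
  m <- as_feature_matrix(block)
  y <- binarize_labels(labels, positive, n = nrow(m))
  models <- match.arg(models, several.ok = TRUE)
  fitters <- classifier_fitters(models, rf_trees = rf_trees, knn_k = knn_k)
  if (length(extra_models)) fitters <- c(fitters, extra_models)
  rows <- vector("list", n_splits * length(fitters))
  ri <- 0L
  n_excluded <- 0L
  for (s in seq_len(n_splits)) {
    with_local_seed(seed + s - 1L, {
      train <- stratified_split(y, train_fraction)
      test <- setdiff(seq_len(nrow(m)), train)
      degenerate <- length(unique(y[test])) < 2L || length(unique(y[train])) < 2L
      if (degenerate) n_excluded <- n_excluded + 1L
      for (nm in names(fitters)) {
        ri <- ri + 1L
        if (degenerate) {
          rows[[ri]] <- dplyr::bind_cols(
            tibble::tibble(split = s, model = nm),
            tibble::as_tibble(as.list(setNames(rep(NA_real_, 8L),
              c("AUC", "Se", "Sp", "ACC", "Youden", "F_measure", "MCC",
                "G_means"))))
          )
        } else {
          score <- fitters[[nm]](m[train, , drop = FALSE], y[train],
                                 m[test, , drop = FALSE])
          rows[[ri]] <- dplyr::bind_cols(
            tibble::tibble(split = s, model = nm),
            compute_metrics(y[test], score)
          )
        }
      }
    })
  }
  metrics <- dplyr::bind_rows(rows)
  metric_cols <- c("AUC", "Se", "Sp", "ACC", "Youden", "F_measure", "MCC",
                   "G_means")
  summary <- metrics |>
    dplyr::filter(!is.na(.data$AUC)) |>
    dplyr::group_by(model = .data$model) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
  structure(
    list(metrics = metrics, summary = summary, n_splits = n_splits,
         n_excluded = n_excluded),
    class = "model_benchmark"
  )
}

classifier_fitters <- function(models, rf_trees, knn_k) {
  all <- list(
    LR = function(xtr, ytr, xte) {
      d <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = d, family = stats::binomial())
      )
      suppressWarnings(
        predict(fit, newdata = data.frame(xte, check.names = FALSE),
                type = "response")
      )
    },
    RF = function(xtr, ytr, xte) {
      fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                        ntree = rf_trees)
      predict(fit, xte, type = "prob")[, "1"]
    },
    SVM = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                        kernel = "radial", probability = TRUE)
      attr(predict(fit, xte, probability = TRUE), "probabilities")[, "1"]
    },
    kNN = function(xtr, ytr, xte) {
      pr <- class::knn(xtr, xte, factor(ytr, levels = c(0, 1)),
                       k = knn_k, prob = TRUE)
      frac <- attr(pr, "prob")
      ifelse(pr == "1", frac, 1 - frac)
    }
  )
  all[models]
}

#' @export
print.model_benchmark <- function(x, ...) {
  cat(sprintf("<model_benchmark> %d splits (%d degenerate, excluded)\n",
              x$n_splits, x$n_excluded))
  print(x$summary)
  invisible(x)
}

#' @rdname train_and_evaluate
#' @param x,object A `model_benchmark`.
#' @param ... Unused.
#' @export
tidy.model_benchmark <- function(x, ...) x$metrics

#' @rdname train_and_evaluate
#' @export
glance.model_benchmark <- function(x, ...) x$summary

#' @rdname train_and_evaluate
#' @export
autoplot.model_benchmark <- function(object, ...) {
  df <- dplyr::filter(object$metrics, !is.na(.data$AUC))
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$AUC,
                                   fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "AUC per split") +
    ggplot2::theme_minimal()
}

#' Compare classifiers against the best by ANOVA and Dunnett's test
#'
#' One-way analysis of variance of the per-split AUC values across models,
#' followed by Dunnett many-to-one comparisons of every model against the
#' model with the highest mean AUC. Splits with a missing AUC for any model
#' are dropped so all models are compared on the same splits.
#'
#' @param benchmark A `model_benchmark` from [train_and_evaluate()] with at
#'   least 2 models and 10 usable splits.
#' @return Object of class `model_comparison`: list with `reference` (best
#'   model), `anova` (tibble `F`, `df1`, `df2`, `p_value`), `comparisons`
#'   (tibble `model`, `estimate`, `p_adj` — Dunnett-adjusted).
#' @export
compare_models_dunnett <- function(benchmark) {
  stopifnot(inherits(benchmark, "model_benchmark"))
  wide <- benchmark$metrics |>
    dplyr::select("split", "model", "AUC") |>
    tidyr::pivot_wider(names_from = "model", values_from = "AUC") |>
    dplyr::filter(stats::complete.cases(dplyr::across(!dplyr::matches("^split$"))))
  model_names <- setdiff(names(wide), "split")
  if (length(model_names) < 2) abort("need at least 2 models")
  if (nrow(wide) < 10) abort("need at least 10 usable splits")
  long <- tidyr::pivot_longer(wide, -"split", names_to = "model",
                              values_to = "AUC")
  means <- tapply(long$AUC, long$model, mean)
  reference <- names(means)[which.max(means)]
  long$model <- stats::relevel(factor(long$model), ref = reference)
  fit <- aov(AUC ~ model, data = long)
  an <- summary(fit)[[1]]
  dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(model = "Dunnett")))
  structure(
    list(
      reference = reference,
      anova = tibble::tibble(
        F = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
        p_value = an[["Pr(>F)"]][1]
      ),
      comparisons = tibble::tibble(
        model = sub(" - .*$", "", names(dn$test$coefficients)),
        estimate = unname(dn$test$coefficients),
        p_adj = unname(as.vector(dn$test$pvalues))
      )
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> reference (best mean AUC): %s\n", x$reference))
  cat(sprintf("ANOVA F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  print(x$comparisons)
  invisible(x)
}

#' @rdname compare_models_dunnett
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) x$comparisons

#' Survival check of predicted versus true marker groups
#'
#' Runs the log-rank comparison of [km_logrank()] twice — once with groups
#' defined by the true binary labels and once with the predicted labels —
#' for side-by-side reporting of whether predicted groups reproduce the
#' survival separation of the true groups.
#'
#' @param survival Tibble `sample_id`, `time`, `event` for the scored
#'   samples.
#' @param y_true,y_pred Binary labels per sample.
#' @param cutoff_months Administrative cutoff (default 60).
#' @return List with elements `true` and `predicted`, each a `km_logrank`.
#' @export
km_check_of_predictions <- function(survival, y_true, y_pred,
                                    cutoff_months = 60) {
  list(
    true = km_logrank(survival, y_true, cutoff_months = cutoff_months),
    predicted = km_logrank(survival, y_pred, cutoff_months = cutoff_months)
  )
}
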