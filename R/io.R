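#' Read a delimited feature matrix
#'
#' Reads a delimited text file whose first column is `sample_id` and whose
#' header names the features. The delimiter (tab or comma) is sniffed from
#' the header line. Duplicate sample ids and non-numeric cells are errors.
#'
#' @param path File path.
#' @return A feature-block tibble.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(tb)[1] <- "sample_id"
  tb$sample_id <- as.character(tb$sample_id)
  feat <- setdiff(names(tb), "sample_id")
  bad <- feat[!vapply(tb[feat], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric feature column(s) in %s: %s", path,
                  paste(head(bad, 5L), collapse = ", ")))
  }
  as_feature_matrix(tb, arg = path)  # validates duplicates
  tb
}

#' Read a survival table
#'
#' @param path Delimited file with columns `sample_id`, `time`, `event`.
#' @return A tibble, validated.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_survival(tb)
  tb
}

#' Run the full subtyping pipeline on a cohort
#'
#' Executes the pipeline stages in order — cluster-number selection (unless
#' `k` is given), consensus clustering, survival evaluation of the
#' subtypes, differential-feature screening and enrichment, and (when a
#' binary marker is supplied) stability selection plus the classifier
#' benchmark — writing each stage's tables under `outdir` and returning the
#' fitted objects. A failing stage aborts with the stage name. Reruns with
#' the same inputs and seed are deterministic.
#'
#' @param blocks Named list of feature blocks (tibbles or file paths).
#' @param survival Survival tibble or file path.
#' @param marker Optional binary-marker tibble (`sample_id`, `label`) or
#'   path.
#' @param k Number of subtypes; `NULL` selects it via [choose_k()].
#' @param k_grid Candidate grid when selecting k.
#' @param n_rounds,n_folds Consensus parameters (defaults 50 and 3).
#' @param stability_splits,benchmark_splits Split counts for the marker
#'   stages (defaults 100 and 1000).
#' @param outdir Output directory (created).
#' @param seed Integer seed driving every stochastic stage.
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(blocks, survival, marker = NULL, k = NULL,
                         k_grid = 2:8, n_rounds = 50, n_folds = 3,
                         stability_splits = 100, benchmark_splits = 1000,
                         outdir = "owclust_out", seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (is.character(blocks)) blocks <- as.list(blocks)
  blocks <- lapply(blocks, function(b) {
    if (is.character(b)) read_feature_matrix(b) else b
  })
  if (is.null(names(blocks))) names(blocks) <- sprintf("modality_%d", seq_along(blocks))
  if (is.character(survival)) survival <- read_survival(survival)
  if (is.character(marker)) {
    marker <- readr::read_tsv(marker, show_col_types = FALSE, progress = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  blocks <- stage("preprocess", lapply(blocks, function(b) {
    standardize_features(filter_degenerate_features(b))
  }))

  kres <- NULL
  if (is.null(k)) {
    kres <- stage("select-k", choose_k(blocks, survival, k_grid = k_grid,
                                       seed = seed))
    k <- kres$k_selected
    readr::write_tsv(kres$scores, file.path(outdir, "kselect.tsv"))
  }

  fit <- stage("cluster", survclust(blocks, survival, k = k,
                                    n_rounds = n_rounds, n_folds = n_folds,
                                    seed = seed))
  readr::write_tsv(fit$labels, file.path(outdir, "labels.tsv"))

  km <- stage("evaluate", km_logrank(survival, fit$labels$consensus_label))
  cox <- stage("evaluate", fit_cox_multivariable(
    survival,
    data.frame(subtype = factor(fit$labels$consensus_label))
  ))
  jsonlite::write_json(
    list(logrank = km$logrank, cox = cox$coefficients,
         epv = cox$epv, schoenfeld = cox$schoenfeld),
    file.path(outdir, "evaluation.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )

  diff <- stage("enrich", differential_features(blocks,
                                                fit$labels$consensus_label))
  enr <- stage("enrich", {
    flags <- do.call(cbind, lapply(blocks, flag_expression))
    hypergeometric_enrichment(flags, fit$labels$consensus_label)
  })
  readr::write_tsv(diff, file.path(outdir, "differential_features.tsv"))
  readr::write_tsv(enr, file.path(outdir, "enrichment.tsv"))

  sel <- bench <- cmp <- NULL
  if (!is.null(marker)) {
    if (!identical(as.character(marker$sample_id), survival$sample_id)) {
      abort("marker rows are not aligned with the cohort sample order")
    }
    diff_feats <- diff$feature[diff$selected]
    joint <- do.call(cbind, lapply(blocks, as_feature_matrix))
    joint <- joint[, intersect(colnames(joint), diff_feats), drop = FALSE]
    if (ncol(joint) < 2) {
      inform("fewer than 2 differential features; skipping marker stages")
    } else {
      sel <- stage("stability-select",
                   stability_select(joint, marker$label,
                                    n_splits = stability_splits, seed = seed))
      readr::write_tsv(sel$frequencies, file.path(outdir, "stability.tsv"))
      feats <- if (length(sel$selected) >= 2) sel$selected else
        head(dplyr::arrange(sel$frequencies,
                            dplyr::desc(.data$frequency))$feature, 2L)
      bench <- stage("predict",
                     train_and_evaluate(joint[, feats, drop = FALSE],
                                        marker$label,
                                        n_splits = benchmark_splits,
                                        seed = seed))
      readr::write_tsv(bench$summary, file.path(outdir, "model_summary.tsv"))
      cmp <- stage("predict", compare_models_dunnett(bench))
      jsonlite::write_json(
        list(reference = cmp$reference, anova = cmp$anova,
             comparisons = cmp$comparisons),
        file.path(outdir, "model_comparison.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
  }

  invisible(list(k_selection = kres, fit = fit, km = km, cox = cox,
                 differential = diff, enrichment = enr,
                 stability = sel, benchmark = bench, comparison = cmp,
                 outdir = outdir))
}
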