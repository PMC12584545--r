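test_that("metrics hit their closed-form values on canonical cases", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(unlist(perfect)), rep(1, 8))

  all_pos <- compute_metrics(rep(c(1, 0), 25), rep(0.9, 50))
  expect_equal(all_pos$Sp, 0)
  expect_equal(all_pos$G_means, 0)
  expect_equal(all_pos$MCC, 0)

  auc75 <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(auc75$AUC, 0.75)

  expect_error(compute_metrics(c(1, 1), c(0.2, 0.4)), "classes")
})

test_that("AUC equals pair enumeration and pROC on random scores", {
  for (s in 1:5) {
    set.seed(s)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    score <- round(runif(40), 1)  # ties on purpose
    got <- compute_metrics(y, score)$AUC
    expect_equal(got, oracle_auc(y, score), tolerance = 1e-12)
    expect_equal(got,
                 as.numeric(suppressMessages(pROC::auc(y, score,
                                                       direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("Youden and G-means identities hold, MCC equals Pearson", {
  set.seed(1)
  for (i in 1:100) {
    y <- rbinom(30, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    score <- runif(30)
    mt <- compute_metrics(y, score)
    expect_equal(mt$Youden, mt$Se + mt$Sp - 1, tolerance = 1e-12)
    expect_equal(mt$G_means, sqrt(mt$Se * mt$Sp), tolerance = 1e-12)
    pred <- as.integer(score >= 0.5)
    if (length(unique(pred)) == 2) {
      expect_equal(mt$MCC, suppressWarnings(cor(pred, y)), tolerance = 1e-12)
    }
  }
})

test_that("stability selection keeps a duplicated signal feature", {
  set.seed(2)
  n <- 120
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rbinom(n, 1, plogis(2 * x[, 1]))
  x <- cbind(x, dup = x[, 1])
  colnames(x) <- c(sprintf("f%02d", 1:20), "dup")
  rownames(x) <- sprintf("s%03d", 1:n)
  labels <- ifelse(y == 1, "MGMTmet&IDHmut", "Others")
  sel <- stability_select(x, labels, n_splits = 10, seed = 1)
  expect_true(any(c("f01", "dup") %in% sel$selected))
  expect_true(all(sel$frequencies$frequency >= 0 &
                    sel$frequencies$frequency <= 1))
})

test_that("permuted labels keep the selected set small", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("f%03d", 1:100)))
  y <- sample(rep(c("MGMTmet&IDHmut", "Others"), each = n / 2))
  sel <- stability_select(x, y, n_splits = 20, seed = 1)
  expect_lte(length(sel$selected), 10)
})

test_that("the benchmark is perfect on separable data", {
  set.seed(4)
  n <- 100
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%03d", 1:n), c("a", "b", "c")))
  y <- rep(c("MGMTmet&IDHmut", "Others"), each = n / 2)
  x[y == "MGMTmet&IDHmut", 1] <- x[y == "MGMTmet&IDHmut", 1] + 20
  bench <- train_and_evaluate(x, y, n_splits = 5, rf_trees = 100, seed = 1)
  ok <- dplyr::filter(bench$metrics, !is.na(.data$AUC))
  expect_equal(ok$AUC, rep(1, nrow(ok)))
  # Platt-scaled SVM probabilities can graze the 0.5 operating point even
  # when the ranking is perfect; the hard-label models must be exact
  hard <- dplyr::filter(ok, .data$model != "SVM")
  expect_equal(hard$MCC, rep(1, nrow(hard)))
  expect_equal(hard$G_means, rep(1, nrow(hard)))
  expect_true(all(ok$MCC >= 0.9))
  expect_setequal(unique(ok$model), c("LR", "RF", "SVM", "kNN"))
})

test_that("uninformative features give chance-level AUC", {
  set.seed(5)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("f%d", 1:5)))
  y <- rep(c("MGMTmet&IDHmut", "Others"), each = n / 2)
  bench <- train_and_evaluate(x, y, models = "LR", n_splits = 200, seed = 1)
  expect_gt(bench$summary$AUC, 0.45)
  expect_lt(bench$summary$AUC, 0.55)
})

fake_benchmark <- function(aucs_by_model) {
  n <- length(aucs_by_model[[1]])
  metrics <- purrr::imap_dfr(aucs_by_model, function(a, nm) {
    tibble::tibble(split = seq_len(n), model = nm, AUC = a,
                   Se = a, Sp = a, ACC = a, Youden = a, F_measure = a,
                   MCC = a, G_means = a)
  })
  structure(list(metrics = metrics, summary = NULL, n_splits = n,
                 n_excluded = 0L),
            class = "model_benchmark")
}

test_that("model comparison follows ANOVA/Dunnett contracts", {
  set.seed(6)
  base <- rnorm(50, 0.7, 0.02)
  identical2 <- fake_benchmark(list(A = base, B = base))
  cmp <- compare_models_dunnett(identical2)
  expect_equal(cmp$anova$F, 0, tolerance = 1e-12)
  expect_gt(cmp$anova$p_value, 0.99)
  expect_equal(nrow(cmp$comparisons), 1)

  three <- fake_benchmark(list(
    A = rnorm(100, 0.70, 0.02),
    B = rnorm(100, 0.80, 0.02),
    C = rnorm(100, 0.71, 0.02)
  ))
  cmp3 <- compare_models_dunnett(three)
  expect_equal(cmp3$reference, "B")
  expect_equal(nrow(cmp3$comparisons), 2)
  expect_true(all(cmp3$comparisons$p_adj < 0.001))
})

test_that("survival check mirrors the truth for perfect predictions", {
  set.seed(7)
  n <- 80
  y <- rep(0:1, each = n / 2)
  time <- rexp(n, exp(1.2 * y) * 0.03)
  surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), time = time,
                         event = rep(1L, n))
  both <- km_check_of_predictions(surv, y, y)
  expect_equal(both$true$logrank$statistic, both$predicted$logrank$statistic)
  expect_error(km_check_of_predictions(surv, y, rep(1, n)), "groups")
})
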