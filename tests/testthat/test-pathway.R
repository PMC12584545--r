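make_expr <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(gene = rownames(m), .before = 1L)
}

test_that("expression preprocessing averages, filters, transforms", {
  m <- rbind(g1 = c(2, 4, 8), g2 = c(1, 1, 1), g1 = c(4, 6, 0))
  colnames(m) <- c("s1", "s2", "s3")
  out <- preprocess_expression(m, max_zero_fraction = 0.5)
  # duplicate g1 averaged before the transform: (2+4)/2, (4+6)/2, (8+0)/2
  expect_equal(out[out$gene == "g1", c("s1", "s2", "s3")],
               tibble::tibble(s1 = log2(4), s2 = log2(6), s3 = log2(5)),
               ignore_attr = TRUE)
  expect_equal(out[out$gene == "g2", ]$s1, 1)  # log2(1 + 1)

  # a gene with > 30% zeros is removed
  m2 <- rbind(keep = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
              drop = c(0, 0, 0, 0, 3, 4, 5, 6, 7, 8))
  colnames(m2) <- sprintf("s%02d", 1:10)
  out2 <- preprocess_expression(m2)
  expect_equal(out2$gene, "keep")

  m3 <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  out3 <- preprocess_expression(m3)
  expect_equal(as.matrix(out3[, -1]), log2(m3 + 1), ignore_attr = TRUE)
})

test_that("preprocessing is idempotent", {
  set.seed(1)
  m <- matrix(rexp(20 * 6), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  once <- preprocess_expression(m)
  twice <- preprocess_expression(once)
  expect_equal(twice, once)
})

test_that("negative expression is refused", {
  m <- matrix(c(-1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(preprocess_expression(m), "non-negative")
})

test_that("activity scoring matches the independent OLS oracle", {
  set.seed(2)
  w <- matrix(rnorm(12), 6, 2,
              dimnames = list(paste0("g", 1:6), c("P1", "P2")))
  e <- matrix(rexp(6 * 4), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  scores <- mlm_activity(e, w)
  for (j in 1:4) {
    fit <- lm(e[, j] ~ w[, "P1"] + w[, "P2"])
    tv <- summary(fit)$coefficients[-1, "t value"]
    expect_equal(unname(unlist(scores[j, c("P1", "P2")])), unname(tv),
                 tolerance = 1e-8)
  }
})

test_that("orthogonal designs isolate the active pathway", {
  # columns orthogonal to each other and to the intercept
  w <- cbind(P1 = c(1, 1, -1, -1, 0, 0, 0, 0), P2 = c(0, 0, 0, 0, 1, -1, 1, -1))
  rownames(w) <- paste0("g", 1:8)
  e <- matrix(w[, "P1"], ncol = 1, dimnames = list(paste0("g", 1:8), "s1"))
  scores <- mlm_activity(e, w)
  co <- attr(scores, "coefficients")
  expect_equal(unname(co[1, "P1"]), 1, tolerance = 1e-10)
  expect_equal(unname(co[1, "P2"]), 0, tolerance = 1e-10)
})

test_that("generated activities are recovered in sign", {
  set.seed(3)
  n_genes <- 120; n_paths <- 4; n_samples <- 40
  w <- matrix(rnorm(n_genes * n_paths), n_genes, n_paths,
              dimnames = list(sprintf("g%03d", 1:n_genes), paste0("P", 1:n_paths)))
  act <- matrix(sample(c(-2, 2), n_samples * n_paths, replace = TRUE),
                n_samples, n_paths,
                dimnames = list(sprintf("s%02d", 1:n_samples),
                                paste0("P", 1:n_paths)))
  expr <- simulate_pathway_expression(w, act, noise_sd = 0.1, seed = 4)
  scores <- mlm_activity(expr, w)
  tmat <- as.matrix(scores[, -1])
  expect_gt(mean(sign(tmat) == sign(act)), 0.95)
})

test_that("rank-deficient weights are refused by name", {
  w <- cbind(P1 = c(1, 2, 3, 4, 5, 6), P2 = 2 * c(1, 2, 3, 4, 5, 6))
  rownames(w) <- paste0("g", 1:6)
  e <- matrix(rexp(12), 6, 2, dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  expect_error(mlm_activity(e, w), "collinear")
})

test_that("per-pathway gene retention keeps the most significant genes", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:30)
  long <- tidyr::expand_grid(gene = genes, pathway = c("P1", "P2"))
  long$weight <- rnorm(nrow(long))
  long$p_value <- runif(nrow(long))
  e <- matrix(rexp(30 * 5), 30, 5,
              dimnames = list(genes, paste0("s", 1:5)))
  full <- mlm_activity(e, long, top_n = 10)
  manual <- long |>
    dplyr::group_by(pathway) |>
    dplyr::slice_min(p_value, n = 10, with_ties = FALSE) |>
    dplyr::ungroup()
  manual$p_value <- NULL
  expect_equal(as.matrix(full[, -1]),
               as.matrix(mlm_activity(e, manual)[, -1]),
               tolerance = 1e-10)
})

test_that("group contrasts are antisymmetric and calibrated", {
  set.seed(6)
  scores <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:40),
    P1 = rnorm(40), P2 = rnorm(40), P3 = rnorm(40)
  )
  labels <- rep(c(1, 2), each = 20)
  c12 <- contrast_activity(scores, labels, reference = 2)
  c21 <- contrast_activity(scores, labels, reference = 1)
  expect_equal(c12$t, -c21$t, tolerance = 1e-12)
  expect_true(all(c12$p_adj >= c12$p_value))

  # a shifted pathway is detected, the others are not
  scores$P2 <- scores$P2 + 3 * (labels == 1)
  res <- contrast_activity(scores, labels, reference = 2)
  expect_lt(res$p_adj[res$pathway == "P2"], 0.05)
  expect_error(contrast_activity(scores, rep(1, 40), reference = 1),
               "two subtypes")
})

test_that("null contrasts rarely reach significance", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    sc <- tibble::as_tibble(matrix(rnorm(60 * 5), 60, 5),
                            .name_repair = ~ paste0("P", 1:5))
    sc <- dplyr::mutate(sc, sample_id = sprintf("s%02d", 1:60), .before = 1L)
    res <- contrast_activity(sc, rep(1:2, 30), reference = 2)
    any(res$p_adj < 0.05)
  }, logical(1))
  expect_lte(sum(hits), 1)
})
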