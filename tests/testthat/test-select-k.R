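test_that("CPI is zero when all samples coincide", {
  n <- 30
  m <- matrix(1, n, 5, dimnames = list(sprintf("s%02d", 1:n),
                                       sprintf("f%d", 1:5)))
  surv <- tibble::tibble(sample_id = rownames(m),
                         time = seq_len(n) + 0.5,
                         event = rep(c(1L, 0L), n / 2))
  cpi <- cpi_score(list(m), surv, k_grid = 2:3, m_splits = 3, seed = 1)
  expect_equal(unname(cpi$cpi_raw), c(0, 0))
})

test_that("CPI aggregates per-split sums and is deterministic", {
  ch <- strong_cohort(n = 90, seed = 1)
  blocks <- std_blocks(ch)
  cpi <- cpi_score(blocks, ch$survival, k_grid = 2:4, m_splits = 4,
                   n_starts = 10, seed = 3)
  expect_equal(unname(cpi$cpi_raw), unname(colMeans(cpi$per_split)),
               tolerance = 1e-10)
  expect_true(all(cpi$per_split >= 0))
  cpi2 <- cpi_score(blocks, ch$survival, k_grid = 2:4, m_splits = 4,
                    n_starts = 10, seed = 3)
  expect_identical(cpi, cpi2)
  expect_error(cpi_score(blocks, ch$survival, k_grid = c(2, 40)), "k_grid")
})

test_that("CPI prefers the generating cluster count", {
  hits <- vapply(1:6, function(s) {
    ch <- strong_cohort(n = 120, seed = s + 20)
    cpi <- cpi_score(std_blocks(ch), ch$survival, k_grid = c(2, 4),
                     m_splits = 8, n_starts = 10, seed = s)
    cpi$cpi_raw[1] < cpi$cpi_raw[2]
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("gap statistic picks out two well-separated blobs", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(60, 0, 1), 30), matrix(rnorm(60, 20, 1), 30))
    gap <- gap_statistic(x, k_grid = 2:8, B = 20, seed = s)
    gap$k_grid[which.max(gap$gap)] == 2
  }, logical(1))
  expect_true(all(hits))
})

test_that("gap terms match the pairwise-dispersion oracle and identity", {
  set.seed(2)
  x <- rbind(matrix(rnorm(30, 0, 1), 15), matrix(rnorm(30, 8, 1), 15))
  gap <- gap_statistic(x, k_grid = 2:4, B = 15, n_starts = 20, seed = 7)
  # internal identity gap = ref - obs
  expect_equal(gap$gap, gap$ref_log_wss_mean - gap$obs_log_wss,
               tolerance = 1e-12)
  # observed term equals the pairwise squared-distance form of the formula
  for (j in seq_along(gap$k_grid)) {
    km <- kmeans_pp(x, gap$k_grid[j], n_starts = 20)
    expect_equal(gap$obs_log_wss[j], log(oracle_gap_dispersion(x, km$labels)),
                 tolerance = 1e-8)
  }
  expect_error(gap_statistic(x, B = 5), "B")
})

test_that("gap observed term is invariant to rigid rotation", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0, 0.5), 20), matrix(rnorm(40, 10, 0.5), 20))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  g1 <- gap_statistic(x, k_grid = 2:3, B = 12, n_starts = 20, seed = 1)
  g2 <- gap_statistic(x %*% rot, k_grid = 2:3, B = 12, n_starts = 20, seed = 1)
  expect_equal(g1$obs_log_wss, g2$obs_log_wss, tolerance = 1e-6)
})

fake_cpi <- function(k_grid, cpi_raw, m = 5) {
  structure(list(k_grid = as.integer(k_grid),
                 cpi_raw = setNames(cpi_raw, paste0("k", k_grid)),
                 per_split = NULL, m = m),
            class = "cpi_result")
}
fake_gap <- function(k_grid, gap) {
  structure(list(k_grid = as.integer(k_grid), gap = gap,
                 ref_log_wss_mean = gap, obs_log_wss = rep(0, length(gap)),
                 se_gap = rep(0.1, length(gap)), B = 20),
            class = "gap_result")
}

test_that("selection combines rescaled criteria with the documented rules", {
  cpi <- fake_cpi(2:6, c(10, 8, 8, 8, 8))        # decreasing then flat error
  gap <- fake_gap(2:6, c(1.0, 0.1, 0.1, 0.1, 0.1))  # peaked at 2, flat after
  sel <- select_k(cpi, gap)
  expect_equal(sel$k_selected, 2L)
  # both criteria favouring 2 give a strict (non-tie) winner
  sel_b <- select_k(fake_cpi(2:6, c(8, 9, 10, 10, 10)),
                    fake_gap(2:6, c(1.0, 0.2, 0.1, 0.05, 0.02)))
  expect_equal(sel_b$k_selected, 2L)

  flat <- select_k(fake_cpi(2:6, rep(3, 5)), fake_gap(2:6, rep(0.5, 5)))
  expect_equal(flat$k_selected, 2L)  # tie toward the smallest k

  # affine invariance of the min-max rescaling
  scaled <- select_k(fake_cpi(2:6, 10 * c(10, 8, 8, 8, 8)), gap)
  expect_equal(scaled$k_selected, sel$k_selected)
  expect_equal(scaled$scores$combined, sel$scores$combined)

  expect_error(select_k(fake_cpi(2:5, rep(1, 4)), gap), "grids")
})

test_that("end-to-end selection finds k = 2 on a strong cohort", {
  ch <- strong_cohort(n = 120, seed = 5)
  ks <- choose_k(std_blocks(ch), ch$survival, k_grid = 2:5, m_splits = 8,
                 B = 20, seed = 2)
  expect_equal(ks$k_selected, 2L)
  expect_equal(ks$scores$combined,
               ks$scores$cpi_score + ks$scores$gap_score)
})
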