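test_that("chi-square matches hand values and applies Yates only for 2x2", {
  flat <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_true(flat$correction_applied)

  r3 <- chi_square_test(matrix(c(10, 20, 30, 15, 25, 20), 3))
  expect_false(r3$correction_applied)
  expect_equal(r3$df, 2)

  # forcing the correction off reproduces the uncorrected Pearson statistic
  tab <- matrix(c(35, 16, 44, 67), 2)
  un <- chi_square_test(tab, continuity = FALSE)
  expect_equal(un$statistic,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)))
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)

  tied <- kruskal_wallis(rep(5, 10), rep(c("a", "b"), 5))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "groups")
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(1)
  pvals <- replicate(200, {
    kruskal_wallis(rnorm(60), sample(rep(1:2, 30)))$p_value
  })
  expect_gte(mean(pvals < 0.05), 0.02)
  expect_lte(mean(pvals < 0.05), 0.09)
})

test_that("log-rank is zero for identical groups and matches a hand oracle", {
  surv <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                         time = rep(c(3, 5, 8, 12, 20), 2),
                         event = rep(c(1L, 0L, 1L, 1L, 0L), 2))
  same <- km_logrank(surv, rep(c("g1", "g2"), each = 5), cutoff_months = 60)
  expect_equal(same$logrank$statistic, 0, tolerance = 1e-10)

  # 4-sample worked example: O - E accumulated at each event time
  surv4 <- tibble::tibble(sample_id = letters[1:4], time = 1:4,
                          event = rep(1L, 4))
  groups <- c("A", "A", "B", "B")
  res <- km_logrank(surv4, groups, cutoff_months = Inf)
  o_minus_e <- 0; v <- 0
  for (t in 1:4) {
    at_risk <- surv4$time >= t
    nA <- sum(at_risk & groups == "A"); n <- sum(at_risk)
    d <- sum(surv4$time == t)
    o_minus_e <- o_minus_e + (groups[surv4$time == t] == "A") - d * nA / n
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  expect_equal(res$logrank$statistic, o_minus_e^2 / v, tolerance = 1e-8)
})

test_that("the cutoff censors administratively without adding events", {
  surv <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         time = c(10, 50, 70, 90, 30, 100),
                         event = c(1L, 1L, 1L, 0L, 0L, 1L))
  res <- km_logrank(surv, rep(c("a", "b"), 3), cutoff_months = 60)
  expect_true(all(res$data$time <= 60))
  expect_equal(sum(res$data$event), 2)  # the two events before 60 months
  km <- tidy(res)
  for (g in unique(km$group)) {
    expect_true(all(diff(km$survival[km$group == g]) <= 1e-12))
  }
})

test_that("log-rank detects a strong hazard difference", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    g <- rep(1:2, each = n / 2)
    time <- rexp(n, ifelse(g == 2, 3, 1) * 0.02)
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           time = time, event = rep(1L, n))
    km_logrank(surv, g)$logrank$p_value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("multivariable Cox recovers coefficients with exact identities", {
  set.seed(2)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  time <- rexp(n, exp(0.9 * x1))
  surv <- tibble::tibble(sample_id = sprintf("s%04d", 1:n),
                         time = time, event = rbinom(n, 1, 0.8))
  fit <- fit_cox_multivariable(surv, data.frame(x1 = x1, x2 = x2))
  co <- tidy(fit)
  b1 <- co[co$term == "x1", ]
  expect_gt(b1$B, 0.8); expect_lt(b1$B, 1.0)
  b2 <- co[co$term == "x2", ]
  expect_gt(b2$HR, 0.9); expect_lt(b2$HR, 1.1)
  expect_equal(co$HR, exp(co$B))
  expect_equal(co$CI_lower, exp(co$B - 1.96 * co$SE))
  expect_equal(co$CI_upper, exp(co$B + 1.96 * co$SE))
  expect_equal(fit$epv, sum(surv$event) / 2)
  expect_true("GLOBAL" %in% fit$schoenfeld$term)
  expect_true(all(fit$schoenfeld$p_value >= 0 & fit$schoenfeld$p_value <= 1))
})

test_that("degenerate Cox inputs are refused", {
  surv <- tibble::tibble(sample_id = letters[1:6], time = 1:6 + 0.5,
                         event = c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_error(fit_cox_multivariable(surv, data.frame(flat = rep(1, 6))),
               "constant")
  expect_error(
    fit_cox_multivariable(surv, data.frame(a = rnorm(6), b = rnorm(6),
                                           c = rnorm(6), d = rnorm(6))),
    "fewer events|converge|coefficients"
  )
})
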