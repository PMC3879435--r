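long_profile <- function(values, parameter = "TiAL") {
  tibble::tibble(specimen = seq_along(values), parameter = parameter,
                 value = values)
}

test_that("identical 2D and 3D cohorts compare as a perfect identity", {
  set.seed(8)
  v <- rnorm(12, 30, 2)
  cmp <- compare_2d_3d(long_profile(v), long_profile(v))
  expect_equal(cmp$pct_error, 0)
  expect_equal(cmp$a, 1, tolerance = 1e-9)
  expect_equal(cmp$b, 0, tolerance = 1e-7)
  expect_equal(cmp$r, 1, tolerance = 1e-12)
  expect_true(is.na(cmp$t_p))  # paired test degenerate on zero differences
})

test_that("percent error of the means follows the printed convention", {
  # cohort means 29.35 (2D) vs 28.41 (3D): 100 * (29.35 - 28.41) / 28.41
  v3 <- c(28.41, 28.41); v2 <- c(29.35, 29.35)
  cmp <- compare_2d_3d(long_profile(v3), long_profile(v2))
  expect_equal(cmp$pct_error, 100 * (29.35 - 28.41) / 28.41,
               tolerance = 1e-12)
  expect_equal(round(cmp$pct_error, 2), 3.31)
})

test_that("the calibration regression predicts 3D from 2D", {
  set.seed(5)
  x2 <- rnorm(58, 63.73, 3.83)
  x3 <- 0.97 * x2 + 0.95 + rnorm(58, sd = 0.1)
  fit <- fit_2d3d_regression(x2, x3)
  ci <- confint(fit$fit)
  expect_gt(0.97, ci[2, 1]); expect_lt(0.97, ci[2, 2])
  expect_gt(0.95, ci[1, 1]); expect_lt(0.95, ci[1, 2])
  # applying published-scale coefficients maps the 2D mean near the 3D mean
  expect_equal(correct_2d(63.73, list(a = 0.97, b = 0.95)), 62.77,
               tolerance = 0.005)
  expect_lt(abs(correct_2d(63.73, list(a = 0.97, b = 0.95)) - 62.60), 0.5)
  expect_equal(correct_2d(29.35, list(a = 0.95, b = 0.39)), 28.27,
               tolerance = 0.005)
  expect_equal(correct_2d(5, list(a = 1, b = 0)), 5)
})

test_that("regression recovery is within its confidence interval at n = 58", {
  set.seed(31)
  ok <- 0
  for (rep in 1:5) {
    x2 <- rnorm(58, 30, 3)
    x3 <- 0.95 * x2 + 0.39 + rnorm(58, sd = 0.3)
    ci <- confint(fit_2d3d_regression(x2, x3)$fit)
    ok <- ok + (ci[2, 1] < 0.95 && 0.95 < ci[2, 2] &&
                  ci[1, 1] < 0.39 && 0.39 < ci[1, 2])
  }
  expect_gte(ok, 4)  # 95% CIs: occasional misses allowed
})

test_that("ICC(3,k) matches the ANOVA oracle on fixed matrices", {
  m <- matrix(c(9, 10, 11,
                5, 6, 4,
                8, 8, 9), nrow = 3, byrow = TRUE)
  res <- icc_3k(m)
  # independent oracle: two-way ANOVA mean squares via stats::aov
  long <- data.frame(y = as.vector(m),
                     specimen = factor(rep(1:3, 3)),
                     pose = factor(rep(1:3, each = 3)))
  av <- summary(stats::aov(y ~ specimen + pose, data = long))[[1]]
  bms <- av["specimen", "Mean Sq"]; ems <- av["Residuals", "Mean Sq"]
  expect_equal(res$icc, (bms - ems) / bms, tolerance = 1e-12)
  expect_equal(res$bms, bms, tolerance = 1e-12)
  expect_equal(res$ems, ems, tolerance = 1e-12)

  # invariance to adding a constant
  expect_equal(icc_3k(m + 100)$icc, res$icc, tolerance = 1e-9)
})

test_that("ICC limits: duplicated columns give 1, constant matrices error", {
  v <- c(4, 9, 7, 12)
  expect_equal(icc_3k(cbind(v, v, v))$icc, 1)
  expect_error(icc_3k(matrix(5, 4, 3)), "constant")
  expect_error(icc_3k(matrix(1:3, 1, 3)), "at least 2")
})

test_that("ICC is high when specimen variance dominates pose noise", {
  set.seed(14)
  mu <- rnorm(58, 30, 3)
  m <- matrix(mu, 58, 10) + matrix(rnorm(580, sd = 0.3), 58, 10)
  res <- icc_3k(m)
  expect_gt(res$icc, 0.95)
  expect_equal(res$band, "very good")
  # incomplete rows are dropped and counted
  m[3, 5] <- NA
  expect_equal(icc_3k(m)$n_dropped, 1)
  expect_equal(icc_3k(m)$n, 57)
})

test_that("tidiers return the expected shapes", {
  set.seed(6)
  fit <- fit_2d3d_regression(rnorm(20, 30, 2), rnorm(20, 30, 2))
  expect_named(glance(fit), c("a", "b", "r.squared", "nobs"))
  expect_equal(nrow(tidy(fit)), 2)
  res <- icc_3k(matrix(rnorm(12, rep(c(5, 9, 14, 20), 3)), 4, 3))
  expect_named(glance(res), c("icc", "band", "n", "k", "n_dropped"))
})

test_that("correction reduces error under an exact affine 2D-3D relation", {
  set.seed(7)
  x2 <- rnorm(30, 33, 3)
  x3 <- 0.9 * x2 + 2
  model <- fit_2d3d_regression(x2, x3)
  corrected <- correct_2d(x2, model)
  expect_lt(max(abs(corrected - x3)), 1e-9)
})
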