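test_that("error statistics satisfy their closed forms and edge cases", {
  y <- c(0.2, 0.5, 0.9, 1.2)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y + 0.07), 0.07)      # constant offset
  expect_equal(nse(y, y), 1)
  expect_equal(nse(y, rep(mean(y), 4)), 0)  # mean predictor
  expect_equal(willmott_d(y, y), 1)
  expect_error(nse(rep(1, 3), c(1, 2, 3)),
               class = "spermophagy_domain_error")
  expect_error(willmott_d(rep(1, 3), rep(1, 3)),
               class = "spermophagy_domain_error")
  expect_error(rmse(y, y[-1]), class = "spermophagy_dimension_error")
})

test_that("rmse dominates mae and both are jointly reorder-invariant", {
  for (s in 1:50) {
    pair <- withr::with_seed(s, list(y = rnorm(20), p = rnorm(20)))
    expect_gte(rmse(pair$y, pair$p), mae(pair$y, pair$p))
  }
  y <- withr::with_seed(3, runif(15)); p <- withr::with_seed(4, runif(15))
  o <- withr::with_seed(5, sample(15))
  expect_equal(nse(y, p), nse(y[o], p[o]))
  expect_equal(willmott_d(y, p), willmott_d(y[o], p[o]))
})

test_that("AIC is -2 M + 2C and prefers the larger objective", {
  expect_equal(quasi_aic(0, 8), 16)
  expect_equal(quasi_aic(15 * log(0.5), 8), 36.794, tolerance = 1e-3)
  expect_lt(quasi_aic(-5, 8), quasi_aic(-10, 8))
})

test_that("fit_statistics assembles totals with the population SD", {
  p <- c(0.8, 1.0, 1.2)
  st <- fit_statistics(c(0.9, 1.0, 1.2), p)
  expect_equal(st$tot_pred, 3.0)
  expect_equal(st$mean_pred, 1.0)
  expect_equal(st$sd_pred, sqrt(mean((p - 1)^2)))   # divisor n, not n-1
  expect_true(is.na(st$aic))
  # a single pair still yields totals; agreement statistics are undefined
  st1 <- fit_statistics(1, 1.3)
  expect_equal(st1$sd_pred, 0)
  expect_true(is.na(st1$nse) && is.na(st1$d))
})

test_that("penalty scan selects by EF with AIC tie-break and handles lambda 0", {
  obs <- simulate_observations(default_table2_config(seed = 3))
  sc <- penalty_scan(obs, standardize = TRUE)
  expect_equal(nrow(sc), 8)
  expect_equal(sc$lambda, seq(0.25, 2, by = 0.25))
  expect_equal(sum(sc$selected), 1)
  expect_true(all(sc$ef[sc$selected] >= sc$ef))
  # a {0} grid reduces to the plain LR fit
  sc0 <- penalty_scan(obs, lambdas = 0, standardize = TRUE)
  lr <- alr_fit(obs, lambda = 0, standardize = TRUE)
  expect_equal(nrow(sc0), 1)
  expect_true(sc0$selected)
  expect_equal(coef(sc0$fits[[1]]), coef(lr))
})

test_that("Murtaugh threshold matches the chi-square closed form", {
  expect_equal(murtaugh_threshold(1, 0.05), 1.84, tolerance = 5e-3)
  expect_equal(murtaugh_threshold(2, 0.05), 1.99, tolerance = 5e-3)
  expect_equal(murtaugh_threshold(1, 1 - 1e-12), -2, tolerance = 1e-6)
  # strictly increasing in 1 - P for fixed k
  ps <- seq(0.9, 0.01, by = -0.05)
  expect_true(all(diff(sapply(ps, murtaugh_threshold, k = 1)) > 0))
  expect_error(murtaugh_threshold(0, 0.05),
               class = "spermophagy_domain_error")
  expect_error(murtaugh_threshold(1, 1.2),
               class = "spermophagy_domain_error")
})

test_that("variable removal decides by strict comparison with the threshold", {
  expect_equal(variable_removal_test(-130.457, -129.792)$decision, "remove")
  expect_equal(variable_removal_test(0, 5)$decision, "retain")
  thr <- murtaugh_threshold(1, 0.05)
  expect_equal(variable_removal_test(0, thr)$decision, "retain")  # boundary
  expect_equal(variable_removal_test(0, thr - 1e-9)$decision, "remove")
})
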