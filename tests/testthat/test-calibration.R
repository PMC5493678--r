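test_that("penalized objective matches its closed form", {
  d15 <- as_observations(tibble::tibble(rp = rep(0.3, 15)))
  b0 <- rep(0, 8)
  # p = 0.5 everywhere and a zero penalty at beta = 0
  expect_equal(penalized_loglik(b0, d15, lambda = 5), 15 * log(0.5))
  d1 <- as_observations(tibble::tibble(rp = 0.3))
  expect_equal(penalized_loglik(b0, d1, lambda = 0), log(0.5))
  # penalty separability: objectives differ by exactly lambda * ||beta||^2
  d <- random_problem(n = 12, seed = 5)
  b <- withr::with_seed(6, rnorm(8, 0, 0.4))
  expect_equal(penalized_loglik(b, d, 0) - penalized_loglik(b, d, 1.75),
               1.75 * sum(b^2))
})

test_that("analytic gradient agrees with closed forms and finite differences", {
  d <- random_problem(n = 15, seed = 7)
  X <- cbind(1, as.matrix(d[, bofc_factors()]))
  # at beta = 0 every p is 0.5
  expect_equal(alr_gradient(rep(0, 8), d, 0),
               setNames(drop(crossprod(X, d$rp - 0.5)),
                        c("(Intercept)", bofc_factors())))
  # stationarity: responses generated exactly from beta
  b <- withr::with_seed(8, rnorm(8, 0, 0.3))
  d2 <- d
  d2$rp <- plogis(drop(X %*% b))
  d2$sp <- map_rp_to_sp(d2$rp)
  expect_lt(max(abs(alr_gradient(b, d2, 0))), 1e-12)
  # finite-difference oracle at random (beta, data, lambda)
  for (s in 1:20) {
    dd <- random_problem(n = 10, seed = 100 + s)
    bb <- withr::with_seed(200 + s, rnorm(8, 0, 0.5))
    lam <- c(0, 0.25, 1.75)[1 + s %% 3]
    g <- alr_gradient(bb, dd, lam)
    expect_lt(max(abs(g - fd_gradient(bb, dd, lam)) / pmax(1, abs(g))), 1e-6)
  }
})

test_that("adaptive coefficient implements the floor and the clamp", {
  b <- rep(0, 8)
  # consecutive displacements of equal norm: ratio 1
  expect_equal(adaptive_coefficient(b, b + 1, b + 2), 1.0)
  # displacement ratio 0.5 hits the 0.95 floor
  expect_equal(adaptive_coefficient(b, b + 1, b + 3), 0.95)
  # ratio 1.3: clamped to 1, literal otherwise
  prev <- b; curr <- b + 1.3; nxt <- curr + 1
  expect_equal(adaptive_coefficient(prev, curr, nxt, clamp = TRUE), 1.0)
  expect_equal(adaptive_coefficient(prev, curr, nxt, clamp = FALSE), 1.3)
  expect_error(adaptive_coefficient(b, b + 1, b + 1),
               class = "spermophagy_degenerate_step_error")
})

test_that("an intercept-only fit to a single y = 0.5 row recovers logit(0.5) = 0", {
  d <- as_observations(tibble::tibble(rp = 0.5))
  fit <- alr_fit(d, lambda = 0, covariates = character(0))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-4)
})

test_that("calibration matches an independent optimizer and recovers truth", {
  cfg <- default_table2_config(seed = 2, noise_sd = 0)
  cfg$replicates <- 3L
  obs <- simulate_observations(cfg)     # 168 noise-free rows
  fit <- alr_fit(obs, lambda = 0, standardize = TRUE)
  expect_true(fit$converged)
  # predictions agree with a BFGS maximizer of the same objective
  oracle <- optim_oracle(obs, lambda = 0)
  p_fit <- predict(fit, obs)$p
  p_oracle <- plogis(drop(cbind(1, as.matrix(obs[, bofc_factors()])) %*% oracle))
  expect_lt(max(abs(p_fit - p_oracle)), 1e-4)
  # noise-free parameter recovery on the standardized fitting scale
  truth <- cfg$true_beta
  truth_std <- c(truth[1] + sum(truth[-1] * fit$scaling$center),
                 truth[-1] * fit$scaling$scale)
  expect_lt(max(abs(fit$coefficients_fit - truth_std)), 1e-2)
  # the raw-scale back-transform reproduces the raw linear predictor
  expect_equal(predict(fit, obs)$f,
               linear_predictor(obs, coef(fit)), tolerance = 1e-10)
})

test_that("fits from different starts agree and the step size never grows", {
  obs <- simulate_observations(default_table2_config(seed = 4))
  f1 <- alr_fit(obs, lambda = 0.5, standardize = TRUE,
                control = alr_control(beta_init = 1))
  f2 <- alr_fit(obs, lambda = 0.5, standardize = TRUE,
                control = alr_control(beta_init = 0))
  expect_lt(max(abs(predict(f1, obs)$p - predict(f2, obs)$p)), 1e-4)
  expect_true(all(diff(f1$trace$alpha) <= 0))
  expect_true(all(f1$trace$delta >= 0.95 & f1$trace$delta <= 1,
                  na.rm = TRUE))
})

test_that("hitting the iteration cap reports non-convergence without error", {
  obs <- simulate_observations(default_table2_config(seed = 4))
  expect_warning(
    fit <- alr_fit(obs, lambda = 0.5, standardize = TRUE,
                   control = alr_control(max_iter = 5)),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 5)
  expect_true(all(is.finite(coef(fit))))
})

test_that("responses on the boundary of (0,1) are rejected", {
  obs <- suppressWarnings(as_observations(tibble::tibble(rp = c(0.5, 1))))
  suppressWarnings(   # revalidation re-raises the mapping warning
    expect_error(alr_fit(obs), class = "spermophagy_domain_error"))
})
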