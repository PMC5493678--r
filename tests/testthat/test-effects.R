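test_that("marginal effect is the analytic derivative of predicted spermophagy", {
  expect_equal(marginal_effect(rep(0, 8), "agp"), 0)
  # p = 0.5 at an all-zero profile with zero intercept: effect = -beta/2
  b <- coefficient_vector(agp = 0.01)
  expect_equal(marginal_effect(b, "agp"), -0.005)
  expect_error(marginal_effect(b, "caffeine"),
               class = "spermophagy_unknown_factor_error")
  # central finite-difference oracle at random points and coefficients
  for (s in 1:25) {
    bb <- withr::with_seed(s, coefficient_vector(
      rnorm(1, 0, 0.3), rnorm(1, 0, 0.01), rnorm(1, 0, 0.05),
      rnorm(1, 0, 0.2), rnorm(1, 0, 0.05), rnorm(1, 0, 0.005),
      rnorm(1, 0, 0.01), rnorm(1, 0, 0.001)))
    fac <- bofc_factors()[1 + s %% 7]
    x0 <- withr::with_seed(1000 + s,
                           setNames(runif(7, 0, 50), bofc_factors()))
    h <- 1e-4 * max(1, x0[[fac]])
    xp <- xm <- x0; xp[fac] <- x0[fac] + h; xm[fac] <- x0[fac] - h
    fd <- (predict_spermophagy(tibble::as_tibble(as.list(xp)), bb)$sp_hat -
             predict_spermophagy(tibble::as_tibble(as.list(xm)), bb)$sp_hat) /
      (2 * h)
    me <- marginal_effect(bb, fac, profile = x0)
    expect_equal(me, fd, tolerance = 1e-6)
  }
  # positive slope implies reduction of spermophagy everywhere
  for (dose in c(0, 10, 100, 1000)) {
    expect_lt(marginal_effect(coefficient_vector(agp = 0.01), "agp",
                              profile = c(agp = dose)), 0)
  }
})

test_that("marginal grid spans 25 tenth-fold steps and labels the shape", {
  g0 <- marginal_grid(rep(0, 8), "agp", dose_max = 100)
  expect_equal(nrow(g0), 25)
  expect_equal(g0$scale, seq(0.1, 2.5, by = 0.1))
  expect_equal(g0$effect, rep(0, 25))
  expect_equal(unique(g0$slope_shape), "straight")
  # a strong slope pushes p past 0.5 inside the grid: |effect| peaks and
  # then declines ("curved"); a weak slope keeps |effect| growing through
  # the last dose ("straight")
  gc <- marginal_grid(coefficient_vector(intercept = -0.3, agp = 0.01),
                      "agp", dose_max = 100)
  expect_equal(unique(gc$slope_shape), "curved")
  peak <- which.max(abs(gc$effect))
  expect_gt(peak, 1)
  expect_lt(peak, 25)
  gs <- marginal_grid(coefficient_vector(intercept = -0.3, agp = 0.001),
                      "agp", dose_max = 100)
  expect_equal(unique(gs$slope_shape), "straight")
  expect_true(all(diff(abs(gs$effect)) > 0))
  expect_equal(gs$dose, gs$scale * 100)
})

test_that("combination effects are control-relative and order-invariant", {
  ctrl <- combination_effect(coefficient_vector(agp = 0.01), NULL)
  expect_equal(ctrl$percent_change, 0)
  # closed form: beta_AG = logit(0.6)/100 at dose 100 moves sp 0.8 -> 0.6
  b <- coefficient_vector(agp = qlogis(0.6) / 100)
  eff <- combination_effect(b, c(agp = 100))
  expect_equal(eff$sp_control, 0.8)
  expect_equal(eff$sp_combo, 0.6)
  expect_equal(eff$percent_change, -25)
  # listing order of the factors does not matter
  b2 <- coefficient_vector(agp = 0.004, pge2 = 0.001)
  e12 <- combination_effect(b2, c(agp = 100, pge2 = 300))
  e21 <- combination_effect(b2, c(pge2 = 300, agp = 100))
  expect_equal(e12, e21)
  # opposing slopes partially cancel in the additive linear predictor
  bop <- coefficient_vector(agp = 0.004, angii = -0.04)
  e_both <- combination_effect(bop, c(agp = 100, angii = 10))
  e_agp <- combination_effect(bop, c(agp = 100))
  expect_lt(abs(e_both$percent_change), abs(e_agp$percent_change))
  expect_warning(combination_effect(b2, c(agp = 500)), "beyond")
  expect_error(combination_effect(b2, c(unknown = 1)),
               class = "spermophagy_unknown_factor_error")
})

test_that("all-positive slopes only ever reduce predicted spermophagy", {
  b <- coefficient_vector(0, 1e-4, 0.03, 0.3, 0.04, 1.5e-3, 6e-3, 2e-4)
  rep1 <- combination_report(b, max_order = 2)
  singles <- rep1[rep1$n_factors == 1, ]
  expect_true(all(singles$percent_change <= 0))
  # adding a positive-slope factor never increases predicted spermophagy
  pairs <- rep1[rep1$n_factors == 2, ]
  for (i in seq_len(nrow(pairs))) {
    fs <- strsplit(pairs$combination[i], "+", fixed = TRUE)[[1]]
    expect_lte(pairs$sp_combo[i],
               min(singles$sp_combo[singles$combination %in% fs]) + 1e-12)
  }
})

test_that("factor classification partitions ranked reductions at the largest gaps", {
  # the narrative grouping: {52.5, 48.5 | 36.6 | 26.8, 26.6}
  reports <- tibble::tibble(
    combination = c("agp", "bsa", "pge2", "lh", "edn1"),
    percent_change = -c(52.5, 48.5, 36.6, 26.8, 26.6))
  cl <- classify_factors(reports)
  expect_equal(cl$class, c(1L, 1L, 2L, 3L, 3L))
  expect_equal(cl$factor[1:2], c("agp", "bsa"))
  # permutation invariance
  cl2 <- classify_factors(reports[c(3, 5, 1, 4, 2), ])
  expect_equal(cl, cl2)
  # single factor collapses to one class
  one <- classify_factors(tibble::tibble(combination = "agp",
                                         percent_change = -10))
  expect_equal(one$class, 1L)
  expect_error(classify_factors(tibble::tibble()),
               class = "spermophagy_input_error")
})

test_that("abrogation ranking orders factors by suppression of the ANGII rise", {
  b <- coefficient_vector(-0.3, 1e-4, 3e-2, 0.3, -4e-2, 1.5e-3, 6e-3, 2e-4)
  rk <- abrogation_ranking(b)
  expect_equal(nrow(rk), 6)
  expect_true(all(diff(rk$percent_change_vs_angii) >= 0))
  expect_true(all(rk$percent_change_vs_angii < 0))
})
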