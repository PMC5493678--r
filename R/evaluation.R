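check_pair <- function(y, p) {
  if (!is.numeric(y) || !is.numeric(p) || length(y) != length(p) ||
      length(y) == 0) {
    abort("`y` and `p` must be numeric vectors of equal nonzero length.",
          class = "spermophagy_dimension_error")
  }
}

#' Error statistics for prediction-observation pairs
#'
#' Root mean square error, mean absolute error, Nash-Sutcliffe efficiency
#' (EF) and Willmott's index of agreement between observed values `y` and
#' predictions `p`.  `willmott_d()` uses the variant with both the observed
#' and the predicted mean in the denominator,
#' d = 1 - sum((y - p)^2) / sum((|y - ybar| + |p - pbar|)^2),
#' which is the form under which the bundled validation table's agreement
#' statistics reproduce.
#'
#' @param y Observed values.
#' @param p Predicted values.
#' @return A scalar.
#' @export
#' @examples
#' fx <- validation_fixture()
#' rmse(fx$phagocytosis, fx$alr_ref)
rmse <- function(y, p) {
  check_pair(y, p)
  sqrt(mean((y - p)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, p) {
  check_pair(y, p)
  mean(abs(y - p))
}

#' @rdname rmse
#' @export
nse <- function(y, p) {
  check_pair(y, p)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    abort("Observed values have zero variance; Nash-Sutcliffe efficiency is undefined.",
          class = "spermophagy_domain_error")
  }
  1 - sum((y - p)^2) / sstot
}

#' @rdname rmse
#' @export
willmott_d <- function(y, p) {
  check_pair(y, p)
  den <- sum((abs(y - mean(y)) + abs(p - mean(p)))^2)
  if (den == 0) {
    abort("Denominator of Willmott's d is zero (no spread in y or p).",
          class = "spermophagy_domain_error")
  }
  1 - sum((y - p)^2) / den
}

#' Akaike information criterion from a maximized objective
#'
#' AIC = -2 M(beta*) + 2 C, with M the maximized (quasi-)log-likelihood
#' objective and C the number of coefficients (8 for the full model).
#'
#' @param m_star Maximized objective value.
#' @param n_coef Number of coefficients C >= 1.
#' @return The scalar AIC.
#' @export
quasi_aic <- function(m_star, n_coef) {
  stopifnot(is.numeric(m_star), length(m_star) == 1,
            is.numeric(n_coef), n_coef >= 1)
  -2 * m_star + 2 * n_coef
}

#' Assemble the full statistics row for a prediction-observation pairing
#'
#' Combines the error statistics with prediction totals in the layout of
#' the model-comparison tables: total predicted phagocytosis (`tot_pred`),
#' its mean and its population standard deviation (divisor n).
#'
#' @inheritParams rmse
#' @param m_star Maximized objective for the AIC column (`NA` if the
#'   predictions did not come from an optimized fit).
#' @param n_coef Number of coefficients for the AIC column.
#' @return One-row tibble: `rmse`, `mae`, `nse`, `d`, `aic`, `tot_pred`,
#'   `mean_pred`, `sd_pred`, `n`.
#' @export
#' @examples
#' fx <- validation_fixture()
#' fit_statistics(fx$phagocytosis, fx$alr_ref)
fit_statistics <- function(y, p, m_star = NA_real_, n_coef = 8) {
  check_pair(y, p)
  n <- length(p)
  # agreement statistics are undefined without spread (e.g. a single pair);
  # report NA there rather than refusing the whole row
  na_if_degenerate <- function(expr) {
    tryCatch(expr, spermophagy_domain_error = function(e) NA_real_)
  }
  tibble(
    rmse = rmse(y, p), mae = mae(y, p),
    nse = na_if_degenerate(nse(y, p)),
    d = na_if_degenerate(willmott_d(y, p)),
    aic = if (is.na(m_star)) NA_real_ else quasi_aic(m_star, n_coef),
    tot_pred = sum(p), mean_pred = mean(p),
    sd_pred = sqrt(mean((p - mean(p))^2)),
    n = n)
}

#' Scan the penalty coefficient over a grid
#'
#' Calibrates the model once per penalty value and reports training-set
#' statistics for each, marking the selected row: highest Nash-Sutcliffe
#' efficiency, ties broken by lowest AIC.  A calibration failure at one
#' lambda yields an NA row (with a warning) without aborting the scan.
#'
#' @param data Observation data frame.
#' @param lambdas Penalty grid; default 0.25, 0.5, ..., 2.
#' @param covariates Covariate subset for the model.
#' @param control An [alr_control()] list.
#' @param standardize Passed to [alr_fit()].
#' @return Tibble with one row per lambda: `lambda`, `ef`, `d`, `rmse`,
#'   `mae`, `aic`, `converged`, `selected`, plus a `fits` list-column of
#'   the underlying `alr_fit` objects.
#' @export
penalty_scan <- function(data, lambdas = seq(0.25, 2, by = 0.25),
                         covariates = bofc_factors(),
                         control = alr_control(), standardize = FALSE) {
  stopifnot(length(lambdas) >= 1, all(lambdas >= 0))
  data <- as_observations(data)
  rows <- purrr::map(lambdas, function(lam) {
    fit <- tryCatch(
      alr_fit(data, lambda = lam, covariates = covariates,
              control = control, standardize = standardize),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("Calibration failed at lambda = %g: %s",
                   lam, conditionMessage(fit)))
      return(list(stats = tibble(lambda = lam, ef = NA_real_, d = NA_real_,
                                 rmse = NA_real_, mae = NA_real_,
                                 aic = NA_real_, converged = NA),
                  fit = NULL))
    }
    pred <- predict(fit, data)
    st <- fit_statistics(data$rp, pred$p, m_star = fit$objective,
                         n_coef = length(fit$coefficients))
    list(stats = tibble(lambda = lam, ef = st$nse, d = st$d, rmse = st$rmse,
                        mae = st$mae, aic = st$aic,
                        converged = fit$converged),
         fit = fit)
  })
  out <- dplyr::bind_rows(purrr::map(rows, "stats"))
  out$fits <- purrr::map(rows, "fit")
  out$selected <- FALSE
  ok <- which(!is.na(out$ef))
  if (length(ok) > 0) {
    best <- ok[order(-out$ef[ok], out$aic[ok])][1]
    out$selected[best] <- TRUE
  }
  out
}

#' Murtaugh delta-AIC removal threshold
#'
#' The AIC-difference cutoff equivalent to a chi-square test of dropping
#' `k` coefficients at significance level `P`:
#' threshold = qchisq(1 - P, k) - 2 k.  For k = 1 and P = 0.05 this is
#' 1.84.
#'
#' @param k Number of coefficients tested, >= 1.
#' @param p_value Significance level in (0, 1).
#' @return The scalar threshold.
#' @export
#' @examples
#' murtaugh_threshold(1, 0.05)
murtaugh_threshold <- function(k, p_value = 0.05) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer.", class = "spermophagy_domain_error")
  }
  if (!is.numeric(p_value) || length(p_value) != 1 || p_value <= 0 ||
      p_value >= 1) {
    abort("`p_value` must lie in (0, 1).", class = "spermophagy_domain_error")
  }
  qchisq(1 - p_value, df = k) - 2 * k
}

#' AIC-based variable removal decision
#'
#' Compares |AIC_full - AIC_reduced| with the [murtaugh_threshold()]; a
#' difference strictly below the threshold accepts the null hypothesis that
#' the dropped coefficients are zero, i.e. the variable can be removed.
#'
#' @param aic_full AIC of the model containing the variable.
#' @param aic_reduced AIC of the model without it.
#' @param k Number of coefficients dropped.
#' @param p_value Significance level.
#' @return One-row tibble: `delta_aic`, `threshold`, `decision`
#'   ("remove" or "retain").
#' @export
#' @examples
#' variable_removal_test(-130.457, -129.792)  # delta = 0.97 -> remove
variable_removal_test <- function(aic_full, aic_reduced, k = 1,
                                  p_value = 0.05) {
  stopifnot(is.finite(aic_full), is.finite(aic_reduced))
  delta <- abs(aic_full - aic_reduced)
  thr <- murtaugh_threshold(k, p_value)
  tibble(delta_aic = delta, threshold = thr,
         decision = if (delta < thr) "remove" else "retain")
}
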