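#' Numerically stable logistic map
#'
#' `logistic(f)` returns exp(f) / (1 + exp(f)) evaluated without overflow
#' for any finite `f` (delegates to [stats::plogis()]).  Dose covariates in
#' this model span 0--4000, so linear predictors can be very large during
#' calibration; the value is always strictly inside (0, 1) in floating
#' point terms up to saturation.
#'
#' @param f Numeric vector of linear-predictor values.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' logistic(c(-0.338, 0, 50))
logistic <- function(f) {
  stopifnot(is.numeric(f))
  plogis(f)
}

#' Linear predictor of the spermophagy logit model
#'
#' Computes f = beta0 + sum_j beta_j x_j row-wise, with the slopes applied
#' to the raw dose values in the fixed covariate order of
#' [bofc_factors()].
#'
#' @param data Data frame with the seven dose columns (missing columns are
#'   treated as dose 0 via [as_observations()] semantics).
#' @param beta Coefficient vector of length 8 (intercept first).
#' @return Numeric vector of linear-predictor values, one per row.
#' @export
linear_predictor <- function(data, beta) {
  beta <- check_beta(beta)
  data <- as_tibble(data)
  covs <- bofc_factors()
  for (nm in setdiff(covs, names(data))) data[[nm]] <- 0
  X <- design_matrix(data)
  drop(X %*% beta)
}

#' Predict spermophagy for a set of dose profiles
#'
#' Applies the logistic model on both scales: the linear predictor `f`, the
#' response-scale probability `p = logistic(f)` and the predicted
#' spermophagy `sp_hat = 1.8 - 2 p` (inverse of the response mapping).
#'
#' @param data Data frame of dose profiles (one row per condition).
#' @param beta Coefficient vector of length 8, or an [alr_fit] object.
#' @return The input tibble with columns `f`, `p` and `sp_hat` appended.
#' @export
#' @examples
#' predict_spermophagy(tibble::tibble(agp = c(0, 50, 100)),
#'                     coefficient_vector(agp = 0.01))
predict_spermophagy <- function(data, beta) {
  if (inherits(beta, "alr_fit")) beta <- beta$coefficients
  data <- as_tibble(data)
  if (nrow(data) < 1) {
    abort("`data` must contain at least one row.",
          class = "spermophagy_input_error")
  }
  f <- linear_predictor(data, beta)
  p <- logistic(f)
  dplyr::bind_cols(data, tibble(f = f, p = p, sp_hat = map_rp_to_sp(p)))
}
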