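#' Calibration settings for the iterative fit
#'
#' @param epsilon Convergence tolerance on the Euclidean norm of the
#'   coefficient update (default 1e-5).
#' @param alpha0 Initial step size; the first two step sizes are both
#'   `alpha0` (default 1).
#' @param beta_init Initial coefficient value(s): a scalar recycled over all
#'   coefficients (default 1, the all-ones start) or a full-length vector.
#' @param max_iter Iteration cap (default 100000); hitting it yields
#'   `converged = FALSE`, not an error.
#' @param delta_clamp If `TRUE` (default) the damped step control is used:
#'   the adaptive coefficient is 1 while the update norms are shrinking and
#'   0.95 otherwise, so the step-size sequence is non-increasing and decays
#'   whenever the iteration is not contracting.  `FALSE` gives the literal
#'   max(0.95, ratio) rule, which can grow the step and can stall in a
#'   period-2 orbit at the stability boundary (see the methods vignette).
#' @param keep_trace If `TRUE` (default) the per-iteration trace (step size,
#'   adaptive coefficient, update norm, objective, coefficients) is stored
#'   on the fit.
#' @return A list of class `alr_control`.
#' @export
alr_control <- function(epsilon = 1e-5, alpha0 = 1, beta_init = 1,
                        max_iter = 100000L, delta_clamp = TRUE,
                        keep_trace = TRUE) {
  stopifnot(is.numeric(epsilon), epsilon > 0,
            is.numeric(alpha0), alpha0 > 0,
            is.numeric(beta_init), all(is.finite(beta_init)),
            max_iter >= 1)
  structure(list(epsilon = epsilon, alpha0 = alpha0, beta_init = beta_init,
                 max_iter = as.integer(max_iter), delta_clamp = delta_clamp,
                 keep_trace = keep_trace),
            class = "alr_control")
}

# light validation for possibly sub-model coefficient vectors
check_beta_for <- function(beta, covariates) {
  len <- 1L + length(covariates)
  if (!is.numeric(beta) || length(beta) != len) {
    abort(sprintf("`beta` must have length %d (intercept + %d covariates), got %d.",
                  len, length(covariates), length(beta)),
          class = "spermophagy_dimension_error")
  }
  if (!all(is.finite(beta))) {
    abort("`beta` must be finite.", class = "spermophagy_domain_error")
  }
  names(beta) <- c("(Intercept)", covariates)
  beta
}

# log-likelihood terms via plogis(log.p = TRUE): stable for |f| >> 700
loglik_terms <- function(f, y) {
  y * plogis(f, log.p = TRUE) + (1 - y) * plogis(-f, log.p = TRUE)
}

#' Penalized quasi-log-likelihood of the logit model
#'
#' The objective maximized by the calibration:
#' M(beta) = sum_i \[ y_i log p_i + (1 - y_i) log(1 - p_i) \] - lambda ||beta||^2,
#' where the responses y_i are the mapped values on the (0, 1) scale
#' (continuous fractions, not binary outcomes — a Bernoulli-style
#' quasi-likelihood) and p_i comes from the logistic model.  `lambda = 0`
#' gives the plain (LR) objective; the squared-norm penalty covers the
#' whole coefficient vector, intercept included.
#'
#' @param beta Coefficient vector (intercept + one slope per covariate).
#' @param data Observation data frame with an `rp` (or `sp`) column.
#' @param lambda Penalty coefficient, >= 0.
#' @param covariates Covariate subset defining the model (default: all
#'   seven, in fixed order).
#' @return The scalar objective value.
#' @export
penalized_loglik <- function(beta, data, lambda = 0,
                             covariates = bofc_factors()) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  beta <- check_beta_for(beta, covariates)
  data <- as_observations(data)
  X <- design_matrix(data, covariates)
  f <- drop(X %*% beta)
  sum(loglik_terms(f, data$rp)) - lambda * sum(beta^2)
}

#' Gradient of the penalized quasi-log-likelihood
#'
#' Closed form of the score: sum_i (y_i - p_i) X_i - 2 lambda beta, with
#' X_i the intercept-augmented covariate row.
#'
#' @inheritParams penalized_loglik
#' @return Numeric vector shaped like `beta`.
#' @export
alr_gradient <- function(beta, data, lambda = 0,
                         covariates = bofc_factors()) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  beta <- check_beta_for(beta, covariates)
  data <- as_observations(data)
  X <- design_matrix(data, covariates)
  p <- plogis(drop(X %*% beta))
  drop(crossprod(X, data$rp - p)) - 2 * lambda * beta
}

#' Adaptive step-size coefficient
#'
#' delta_k = max(0.95, ||beta_k - beta_(k-1)|| / ||beta_k - beta_(k+1)||),
#' optionally capped at 1 (`clamp = TRUE`, the default) so that the
#' step-size sequence alpha_(k+1) = delta_k alpha_k never increases.
#'
#' @param beta_prev,beta_curr,beta_next Coefficient vectors at iterations
#'   k-1, k, k+1.
#' @param clamp Cap the ratio at 1.
#' @return The scalar adaptive coefficient.
#' @export
adaptive_coefficient <- function(beta_prev, beta_curr, beta_next,
                                 clamp = TRUE) {
  den <- sqrt(sum((beta_curr - beta_next)^2))
  if (den == 0) {
    abort("Degenerate step: beta_k equals beta_(k+1); calibration has already converged.",
          class = "spermophagy_degenerate_step_error")
  }
  num <- sqrt(sum((beta_curr - beta_prev)^2))
  d <- max(0.95, num / den)
  if (clamp) d <- min(d, 1)
  d
}

# core iteration on a prepared design matrix; returns the raw loop result
calibrate_core <- function(X, y, lambda, control) {
  np <- ncol(X)
  beta <- control$beta_init
  if (length(beta) == 1) beta <- rep(beta, np)
  if (length(beta) != np) {
    abort(sprintf("`beta_init` must have length 1 or %d.", np),
          class = "spermophagy_dimension_error")
  }
  grad_fn <- function(b) drop(crossprod(X, y - plogis(drop(X %*% b)))) - 2 * lambda * b
  obj_fn <- function(b) sum(loglik_terms(drop(X %*% b), y)) - lambda * sum(b^2)

  max_iter <- control$max_iter
  keep <- control$keep_trace
  if (keep) {
    tr_alpha <- tr_delta <- tr_step <- tr_obj <- numeric(max_iter)
    tr_beta <- matrix(NA_real_, max_iter, np)
  }
  alpha <- control$alpha0          # alpha_0 = alpha_1 = alpha0
  beta_prev <- NULL
  converged <- FALSE
  k <- 0L
  n_rec <- 0L
  repeat {
    g <- grad_fn(beta)
    beta_next <- beta + alpha * g
    if (!all(is.finite(beta_next))) {
      abort("Calibration diverged: coefficients became non-finite.",
            class = "spermophagy_divergence_error")
    }
    step_norm <- sqrt(sum((beta_next - beta)^2))
    obj <- obj_fn(beta_next)
    if (!is.finite(obj)) {
      abort("Calibration diverged: objective became non-finite.",
            class = "spermophagy_divergence_error")
    }
    delta <- NA_real_
    if (k >= 1L && step_norm > 0) {
      ratio <- sqrt(sum((beta - beta_prev)^2)) / step_norm
      if (control$delta_clamp) {
        # damped mode: keep the step size while the update norms shrink
        # (ratio > 1), damp by the 0.95 floor while they do not.  The raw
        # rule freezes alpha at the stability boundary (a period-2 orbit
        # has ratio exactly 1), which contradicts the intended limit
        # alpha_k -> 0; this branch restores it while keeping delta in
        # [0.95, 1] and alpha non-increasing.
        delta <- if (ratio > 1) 1 else 0.95
      } else {
        delta <- max(0.95, ratio)   # literal rule; the step can grow
      }
    }
    n_rec <- n_rec + 1L
    if (keep) {
      tr_alpha[n_rec] <- alpha; tr_delta[n_rec] <- delta
      tr_step[n_rec] <- step_norm; tr_obj[n_rec] <- obj
      tr_beta[n_rec, ] <- beta_next
    }
    if (step_norm < control$epsilon) {
      beta_prev <- beta; beta <- beta_next
      converged <- TRUE
      break
    }
    if (!is.na(delta)) alpha <- delta * alpha   # alpha_(k+1); alpha_1 stays alpha0
    beta_prev <- beta; beta <- beta_next
    k <- k + 1L
    if (n_rec >= max_iter) break
  }
  trace <- NULL
  if (keep) {
    trace <- tibble(iter = seq_len(n_rec), alpha = tr_alpha[seq_len(n_rec)],
                    delta = tr_delta[seq_len(n_rec)],
                    step_norm = tr_step[seq_len(n_rec)],
                    objective = tr_obj[seq_len(n_rec)])
    tr_beta <- tr_beta[seq_len(n_rec), , drop = FALSE]
    colnames(tr_beta) <- colnames(X)
  } else tr_beta <- NULL
  list(beta = beta, converged = converged, n_iter = n_rec,
       objective = obj_fn(beta), trace = trace, beta_trace = tr_beta)
}

#' Fit the penalized (ALR) or plain (LR) logistic model
#'
#' Maximizes [penalized_loglik()] by the iterative gradient-ascent scheme
#' beta_(k+1) = beta_k + alpha_k grad M(beta_k) with the dynamically
#' adapted step size alpha_(k+1) = delta_k alpha_k, where delta_k is the
#' [adaptive_coefficient()] computed once beta_(k+1) is known.  Iteration
#' starts from the all-ones coefficient vector with alpha_0 = alpha_1 = 1
#' and stops when ||beta_(k+1) - beta_k|| < epsilon.  `lambda = 0` is the
#' unpenalized logistic (LR) fit; `lambda > 0` the ridge-penalized (ALR)
#' fit.
#'
#' With `standardize = TRUE` the dose columns are centred and scaled to
#' unit variance before fitting and the coefficients are mapped back to the
#' raw dose scale afterwards (exact algebra).  Standardizing is strongly
#' recommended whenever doses span several orders of magnitude: the raw
#' design is then extremely ill-conditioned for a first-order fixed-step
#' scheme.  The penalty applies on the fitting scale.
#'
#' @param data Observation data frame (see [as_observations()]); responses
#'   are taken from the mapped `rp` column.
#' @param lambda Penalty coefficient lambda >= 0.
#' @param covariates Covariate subset to include (default all seven).
#' @param control An [alr_control()] list.
#' @param standardize Centre/scale covariates before fitting.
#' @return An object of class `alr_fit` with elements `coefficients` (raw
#'   dose scale), `coefficients_fit` (fitting scale), `scaling`,
#'   `converged`, `n_iter`, `objective` (final penalized objective on the
#'   fitting scale), `aic`, `trace` and `beta_trace`.
#' @export
#' @examples
#' obs <- simulate_observations(default_table2_config(seed = 1))
#' fit <- alr_fit(obs, lambda = 1.75, standardize = TRUE)
#' coef(fit)
alr_fit <- function(data, lambda = 0, covariates = bofc_factors(),
                    control = alr_control(), standardize = FALSE) {
  stopifnot(inherits(control, "alr_control"),
            is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  data <- as_observations(data)
  X <- design_matrix(data, covariates)
  y <- data$rp
  if (any(y <= 0 | y >= 1)) {
    abort("Responses `rp` must lie strictly inside (0, 1).",
          class = "spermophagy_domain_error")
  }

  scaling <- NULL
  Xfit <- X
  if (standardize && length(covariates) > 0) {
    cols <- seq_len(length(covariates)) + 1L
    sds <- apply(X[, cols, drop = FALSE], 2, sd)
    const <- !is.finite(sds) | sds == 0   # constant columns stay untouched
    ctr <- ifelse(const, 0, colMeans(X[, cols, drop = FALSE]))
    scl <- ifelse(const, 1, sds)
    Xfit[, cols] <- sweep(sweep(X[, cols, drop = FALSE], 2, ctr), 2, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }

  res <- calibrate_core(Xfit, y, lambda, control)
  if (!res$converged) {
    warn(sprintf(
      "Calibration did not converge within %d iterations (last update norm above epsilon = %g).",
      control$max_iter, control$epsilon))
  }
  beta_fit <- setNames(res$beta, colnames(X))
  beta_raw <- beta_fit
  if (!is.null(scaling)) {
    slopes <- beta_fit[-1] / scaling$scale
    beta_raw <- c(beta_fit[1] - sum(beta_fit[-1] * scaling$center / scaling$scale),
                  slopes)
    names(beta_raw) <- colnames(X)
  }
  structure(list(coefficients = beta_raw, coefficients_fit = beta_fit,
                 scaling = scaling, lambda = lambda,
                 covariates = covariates, converged = res$converged,
                 n_iter = res$n_iter, objective = res$objective,
                 aic = quasi_aic(res$objective, length(beta_fit)),
                 control = control, n = nrow(data),
                 trace = res$trace, beta_trace = res$beta_trace,
                 standardize = standardize),
            class = "alr_fit")
}

#' @export
print.alr_fit <- function(x, ...) {
  cat(sprintf("Penalized logistic spermophagy model (lambda = %g)\n", x$lambda))
  cat(sprintf("  %s after %d iterations (n = %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$n))
  cat(sprintf("  penalized objective M(beta*) = %.5f, AIC = %.4f\n",
              x$objective, x$aic))
  cat("  coefficients (raw dose scale):\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.alr_fit <- function(object, ...) object$coefficients

#' Predict from a fitted model
#'
#' @param object An `alr_fit`.
#' @param newdata Data frame of dose profiles; defaults to an error (the
#'   fit does not store its training data).
#' @param ... Unused.
#' @return See [predict_spermophagy()].
#' @export
predict.alr_fit <- function(object, newdata, ...) {
  if (missing(newdata)) {
    abort("`newdata` is required: the fit object does not retain training data.",
          class = "spermophagy_input_error")
  }
  beta <- coefficient_vector()
  beta[names(object$coefficients)] <- object$coefficients
  predict_spermophagy(newdata, beta)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted model
#'
#' @param x An `alr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate` (raw dose
#'   scale) and `estimate_fit` (fitting scale, identical unless the fit
#'   standardized its covariates).
#' @export
tidy.alr_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         estimate_fit = unname(x$coefficients_fit))
}

#' One-row summary of a fitted model
#'
#' @param x An `alr_fit`.
#' @param ... Unused.
#' @return Tibble with `lambda`, `objective`, `aic`, `converged`, `n_iter`,
#'   `n`.
#' @export
glance.alr_fit <- function(x, ...) {
  tibble(lambda = x$lambda, objective = x$objective, aic = x$aic,
         converged = x$converged, n_iter = x$n_iter, n = x$n)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the calibration trace of a fit
#'
#' Shows the penalized objective and the step size over iterations.
#'
#' @param object An `alr_fit` fitted with `keep_trace = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alr_fit <- function(object, ...) {
  if (is.null(object$trace)) {
    abort("No trace stored; refit with `keep_trace = TRUE`.",
          class = "spermophagy_input_error")
  }
  long <- tidyr::pivot_longer(
    object$trace[, c("iter", "objective", "alpha")],
    c("objective", "alpha"), names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = sprintf("Calibration trace (lambda = %g)", object$lambda)) +
    ggplot2::theme_minimal()
}
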