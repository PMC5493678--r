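# small random fitting problems on well-scaled covariates, used by the
# gradient / optimizer checks
random_problem <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    data <- tibble::tibble(
      bsa = abs(rnorm(n)), lh = abs(rnorm(n)),
      boec = sample(0:1, n, replace = TRUE),
      angii = abs(rnorm(n)), pge2 = abs(rnorm(n)), agp = abs(rnorm(n)),
      edn1 = abs(rnorm(n)),
      rp = runif(n, 0.05, 0.95))
    data$sp <- map_rp_to_sp(data$rp)
    data
  })
}

# independent maximizer of the same penalized objective (never the
# package's iterative path)
optim_oracle <- function(data, lambda = 0, start = rep(1, 8)) {
  X <- cbind(1, as.matrix(data[, bofc_factors()]))
  y <- data$rp
  nll <- function(b) {
    f <- drop(X %*% b)
    -(sum(y * plogis(f, log.p = TRUE) + (1 - y) * plogis(-f, log.p = TRUE)) -
        lambda * sum(b^2))
  }
  gr <- function(b) -(drop(crossprod(X, y - plogis(drop(X %*% b)))) - 2 * lambda * b)
  optim(start, nll, gr, method = "BFGS",
        control = list(maxit = 5000, reltol = 1e-14))$par
}

# central finite differences of the penalized objective
fd_gradient <- function(beta, data, lambda, h = 1e-5) {
  vapply(seq_along(beta), function(j) {
    hp <- hm <- beta
    hj <- h * max(1, abs(beta[j]))
    hp[j] <- beta[j] + hj
    hm[j] <- beta[j] - hj
    (penalized_loglik(hp, data, lambda) -
       penalized_loglik(hm, data, lambda)) / (2 * hj)
  }, numeric(1))
}
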