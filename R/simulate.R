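#' Construct a simulation configuration
#'
#' A configuration holds the true coefficient vector, the multi-study
#' design (one dose-profile tibble per study), the response noise level
#' and the seed.  Responses are generated on the mapped (0, 1) scale:
#' rp = clip(p + N(0, noise_sd), 0.001, 0.999) with
#' p = logistic(f(true_beta, x)), then sp = 1.8 - 2 rp.
#'
#' @param true_beta Coefficient vector of length 8.
#' @param studies Named list of data frames; each holds the dose columns of
#'   one study's design points (missing dose columns are 0).
#' @param replicates Replicate rows generated per design point.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   rp scale, >= 0.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(true_beta, studies, replicates = 1,
                              noise_sd = 0.05, seed = 1L) {
  true_beta <- check_beta(true_beta)
  if (!is.list(studies) || length(studies) == 0 ||
      is.null(names(studies)) || any(names(studies) == "")) {
    abort("`studies` must be a nonempty named list of design data frames.",
          class = "spermophagy_config_error")
  }
  for (nm in names(studies)) {
    d <- studies[[nm]]
    if (!is.data.frame(d) || nrow(d) == 0) {
      abort(sprintf("Study `%s` must be a nonempty data frame.", nm),
            class = "spermophagy_config_error")
    }
    num <- d[, intersect(names(d), bofc_factors()), drop = FALSE]
    if (ncol(num) == 0 ||
        any(purrr::map_lgl(num, ~ any(.x < 0, na.rm = TRUE)))) {
      abort(sprintf("Study `%s` needs non-negative dose columns.", nm),
            class = "spermophagy_config_error")
    }
  }
  stopifnot(is.numeric(noise_sd), noise_sd >= 0, replicates >= 1)
  structure(list(true_beta = true_beta, studies = studies,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# 10-fold dose series from `top` downwards, with a zero control:
# 0, top/10^(k-1), ..., top/10, top
tenfold_series <- function(top, n_doses = 4) {
  c(0, top / 10^rev(seq_len(n_doses) - 1))
}

#' Default five-study simulation design
#'
#' Emulates the structure of the multi-study training material: five
#' in vitro studies contributing 4 + 17 + 12 + 15 + 8 = 56 conditions,
#' with 10-fold dose series spanning each component's experimental range
#' (BSA fixed at 4000 µg/ml in the first study; LH 0--10 ng/ml with and
#' without BOEC co-culture; PGE2 0--352 (or 0--35.2) ng/ml; AGP
#' 0--100 ng/ml; ANGII 0--10 ng/ml; EDN-1 0--2490 pg/ml).  The default
#' true coefficients are chosen so that predicted spermophagy spans
#' roughly 0.5--1.1 over the design — the band observed experimentally —
#' with ANGII the single spermophagy-*increasing* component.
#'
#' @param seed Integer seed.
#' @param noise_sd Noise level on the rp scale (default 0.05, emulating
#'   between-replicate spread of assay means).
#' @param true_beta Optional override of the true coefficient vector.
#' @return A `simulation_config`.
#' @export
#' @examples
#' obs <- simulate_observations(default_table2_config(seed = 7))
#' dplyr::count(obs, source)
default_table2_config <- function(seed = 1L, noise_sd = 0.05,
                                  true_beta = NULL) {
  if (is.null(true_beta)) {
    true_beta <- coefficient_vector(
      intercept = -0.30,
      bsa   = 1.0e-4,   # 4000 µg/ml -> +0.40 on the logit
      lh    = 3.0e-2,   # 10 ng/ml  -> +0.30
      boec  = 3.0e-1,   # indicator -> +0.30
      angii = -4.0e-2,  # 10 ng/ml  -> -0.40 (increases spermophagy)
      pge2  = 1.5e-3,   # 352 ng/ml -> +0.53
      agp   = 6.0e-3,   # 100 ng/ml -> +0.60
      edn1  = 2.0e-4)   # 2490 pg/ml -> +0.50
  }
  studies <- list(
    # single-dose BSA study, 4 replicate conditions
    `Li(2010)` = tibble(bsa = rep(4000, 4)),
    # LH dose series crossed with BOEC co-culture, plus a PGE2 arm: 17
    `Marey(2014)` = dplyr::bind_rows(
      tidyr::expand_grid(lh = tenfold_series(10, 3), boec = c(0, 1)),
      tibble(pge2 = tenfold_series(35.2, 4)[-1],
             lh = 0, boec = 0),
      tibble(lh = 10, boec = 1, pge2 = c(3.52, 35.2, 0.352, 35.2, 3.52))),
    # EDN-1 series plus PGE2 series and their joint points: 12
    `Marey(2016a)` = dplyr::bind_rows(
      tibble(edn1 = tenfold_series(2490, 4)),
      tibble(pge2 = tenfold_series(352, 4)),
      tibble(edn1 = c(249, 2490), pge2 = c(35.2, 35.2))),
    # ANGII series with PGE2 challenge: 15
    `Marey(2016b)` = dplyr::bind_rows(
      tibble(angii = tenfold_series(10, 4)),
      tibble(angii = tenfold_series(10, 4), pge2 = 3.52),
      tibble(angii = c(0, 0.1, 1, 10, 10), pge2 = c(0.352, 0.352, 0.352, 0.352, 3.52))),
    # AGP dose series: 8
    `LIU(2014)` = tibble(agp = c(tenfold_series(100, 4), 100 / 3, 10 / 3, 100 / 30)))
  simulation_config(true_beta, studies, replicates = 1,
                    noise_sd = noise_sd, seed = seed)
}

#' Generate a synthetic multi-study observation set
#'
#' Expands the configured designs, computes the model probability per row,
#' adds clipped Gaussian noise on the rp scale and converts back to the
#' spermophagy scale.  Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A validated observation tibble with a `source` study column.
#' @export
simulate_observations <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a `simulation_config`.",
          class = "spermophagy_config_error")
  }
  design <- purrr::imap_dfr(config$studies, function(d, nm) {
    d <- as_tibble(d)
    for (cv in setdiff(bofc_factors(), names(d))) d[[cv]] <- 0
    # a dose column absent from one arm of a study design means dose 0
    d <- mutate(d, across(all_of(bofc_factors()),
                          ~ tidyr::replace_na(.x, 0)))
    d <- d[rep(seq_len(nrow(d)), each = config$replicates),
           bofc_factors()]
    d$source <- nm
    d
  })
  p <- logistic(linear_predictor(design, config$true_beta))
  rp <- withr::with_seed(config$seed, {
    pmin(pmax(p + rnorm(length(p), 0, config$noise_sd), 0.001), 0.999)
  })
  design$rp <- rp
  design$sp <- map_rp_to_sp(rp)
  as_observations(design)
}

#' Parameter-recovery experiment
#'
#' Repeated generate-and-calibrate cycles: for each replicate and each
#' penalty value the model is refitted to freshly generated data and the
#' recovered coefficients are compared with the truth.  Fits are run on
#' standardized covariates (exact back-transform) because the default
#' multi-study design spans four orders of dose magnitude.
#'
#' @param config A [simulation_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param lambdas Penalty values to fit (default 0, the plain fit).
#' @param n_reps Number of generate/fit replicates, >= 1.
#' @param control Calibration settings.
#' @param standardize Fit on standardized covariates (default `TRUE`).
#' @return A list with `estimates` (tibble: `rep`, `lambda`, `term`,
#'   `true`, `estimate`, `error`, raw dose scale; `estimate_fit`/`true_fit`
#'   on the fitting scale) and `summary` (per lambda and term: `bias`,
#'   `rmse`, `n_fail`).
#' @export
recovery_experiment <- function(config, lambdas = 0, n_reps = 1,
                                control = alr_control(),
                                standardize = TRUE) {
  stopifnot(n_reps >= 1)
  est <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    obs <- simulate_observations(cfg)
    purrr::map_dfr(lambdas, function(lam) {
      fit <- tryCatch(
        alr_fit(obs, lambda = lam, control = control,
                standardize = standardize),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble(rep = r, lambda = lam, term = NA_character_,
                      true = NA_real_, estimate = NA_real_,
                      error = NA_real_, estimate_fit = NA_real_,
                      true_fit = NA_real_, failed = TRUE))
      }
      truth <- config$true_beta
      truth_fit <- truth
      if (!is.null(fit$scaling)) {
        truth_fit <- c(truth[1] + sum(truth[-1] * fit$scaling$center),
                       truth[-1] * fit$scaling$scale)
      }
      tibble(rep = r, lambda = lam, term = names(fit$coefficients),
             true = unname(truth), estimate = unname(fit$coefficients),
             error = unname(fit$coefficients - truth),
             estimate_fit = unname(fit$coefficients_fit),
             true_fit = unname(truth_fit), failed = FALSE)
    })
  })
  summary <- est %>%
    filter(!.data$failed) %>%
    group_by(.data$lambda, .data$term) %>%
    summarise(true = .data$true[1], bias = mean(.data$error),
              rmse = sqrt(mean(.data$error^2)), .groups = "drop")
  n_fail <- est %>%
    group_by(.data$lambda) %>%
    summarise(n_fail = sum(.data$failed & is.na(.data$term)),
              .groups = "drop")
  list(estimates = est, summary = dplyr::left_join(summary, n_fail,
                                                   by = "lambda"))
}
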