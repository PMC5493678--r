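profile_from_doses <- function(doses = NULL) {
  prof <- as.list(setNames(rep(0, length(bofc_factors())), bofc_factors()))
  if (!is.null(doses) && length(doses) > 0) {
    unknown <- setdiff(names(doses), bofc_factors())
    if (length(unknown) > 0) {
      abort(paste0("Unknown factor(s): ", paste(unknown, collapse = ", ")),
            class = "spermophagy_unknown_factor_error")
    }
    prof[names(doses)] <- as.list(unname(unlist(doses)))
  }
  as_tibble(prof)
}

#' Marginal effect of one component on predicted spermophagy
#'
#' The instantaneous rate of change of predicted spermophagy with respect
#' to the dose of one component, at a given dose profile:
#' d sp_hat / d x_j = -2 beta_j p (1 - p) — the standard logit marginal
#' effect propagated through the spermophagy inverse map sp = 1.8 - 2 p.
#' A component that raises the response-scale probability (positive slope)
#' therefore always *reduces* predicted spermophagy.
#'
#' @param beta Coefficient vector of length 8, or an [alr_fit].
#' @param factor One of [bofc_factors()].
#' @param profile Named doses of the evaluation point (unnamed components
#'   are 0); may be a named vector/list or a one-row data frame.
#' @return The scalar marginal effect on the spermophagy scale.
#' @export
#' @examples
#' marginal_effect(coefficient_vector(agp = 0.01), "agp",
#'                 profile = c(agp = 50))
marginal_effect <- function(beta, factor, profile = NULL) {
  if (inherits(beta, "alr_fit")) beta <- coef(predict_beta_full(beta))
  beta <- check_beta(beta)
  if (!is.character(factor) || length(factor) != 1 ||
      !factor %in% bofc_factors()) {
    abort(sprintf("`factor` must be one of: %s.",
                  paste(bofc_factors(), collapse = ", ")),
          class = "spermophagy_unknown_factor_error")
  }
  if (is.data.frame(profile)) profile <- as.list(profile[1, , drop = FALSE])
  x <- profile_from_doses(profile)
  p <- predict_spermophagy(x, beta)$p
  -2 * beta[[factor]] * p * (1 - p)
}

# promote a (possibly sub-model) fit's coefficients to a full-length vector
predict_beta_full <- function(fit) {
  beta <- coefficient_vector()
  beta[names(fit$coefficients)] <- fit$coefficients
  structure(list(coefficients = beta), class = "alr_fit")
}

#' Marginal-effect grid over scaled doses
#'
#' Evaluates [marginal_effect()] along a dose grid expressed as multiples
#' of the factor's maximum experimental dose: 0.1, 0.2, ..., 2.5 times
#' `dose_max` (one-tenth-fold intervals, extending past the experimental
#' maximum at 1 up to 2.5).  The curve shape is summarized as `"curved"`
#' when the effect magnitude peaks strictly before the end of the grid —
#' the signature of the dose range pushing the probability past 0.5, where
#' p(1 - p) is maximal — and `"straight"` otherwise.
#'
#' @inheritParams marginal_effect
#' @param dose_max Dose corresponding to scale 1 (defaults to the factor's
#'   entry in [default_dose_maxima()]).
#' @param base_profile Doses of the other components (default all 0).
#' @return Tibble with 25 rows: `factor`, `scale`, `dose`, `effect`,
#'   `slope_shape`.
#' @export
marginal_grid <- function(beta, factor, dose_max = NULL,
                          base_profile = NULL) {
  if (inherits(beta, "alr_fit")) beta <- coef(predict_beta_full(beta))
  beta <- check_beta(beta)
  if (is.null(dose_max)) dose_max <- default_dose_maxima()[[factor]]
  stopifnot(is.numeric(dose_max), dose_max > 0)
  scales <- seq(0.1, 2.5, by = 0.1)
  base <- profile_from_doses(base_profile)
  grid <- base[rep(1, length(scales)), ]
  grid[[factor]] <- scales * dose_max
  pred <- predict_spermophagy(grid, beta)
  effect <- -2 * beta[[factor]] * pred$p * (1 - pred$p)
  aeff <- abs(effect)
  flat <- diff(range(aeff)) < 1e-12
  shape <- if (!flat && which.max(aeff) < length(aeff)) "curved" else "straight"
  doses <- grid[[factor]]
  tibble(factor = factor, scale = scales, dose = doses,
         effect = effect, slope_shape = shape)
}

#' Predicted effect of a dose combination relative to control
#'
#' Predicts spermophagy for a profile holding the listed components at the
#' given doses (all other components at the control profile's doses) and
#' expresses the change relative to the control prediction as a
#' percentage: negative values mean a reduction of spermophagy.
#'
#' @inheritParams marginal_effect
#' @param doses Named numeric vector of component doses forming the
#'   combination; empty means the control itself (0% change).
#' @param control Named doses of the control profile (default all 0).
#' @param ranges Optional named vector of maximum permitted doses; doses
#'   beyond their range raise a warning unless `allow_out_of_range = TRUE`.
#' @param allow_out_of_range Suppress the out-of-range warning.
#' @return One-row tibble: `combination` (factors joined by "+"),
#'   `n_factors`, `sp_control`, `sp_combo`, `percent_change`.
#' @export
#' @examples
#' combination_effect(coefficient_vector(agp = qlogis(0.6) / 100),
#'                    c(agp = 100))
combination_effect <- function(beta, doses = NULL, control = NULL,
                               ranges = default_dose_maxima(),
                               allow_out_of_range = FALSE) {
  if (inherits(beta, "alr_fit")) beta <- coef(predict_beta_full(beta))
  beta <- check_beta(beta)
  ctrl <- profile_from_doses(control)
  if (is.null(doses) || length(doses) == 0) {
    sp0 <- predict_spermophagy(ctrl, beta)$sp_hat
    return(tibble(combination = "(control)", n_factors = 0L,
                  sp_control = sp0, sp_combo = sp0, percent_change = 0))
  }
  doses <- unlist(doses)
  unknown <- setdiff(names(doses), bofc_factors())
  if (length(unknown) > 0) {
    abort(paste0("Unknown factor(s): ", paste(unknown, collapse = ", ")),
          class = "spermophagy_unknown_factor_error")
  }
  if (!allow_out_of_range && !is.null(ranges)) {
    over <- names(doses)[doses > ranges[names(doses)]]
    if (length(over) > 0) {
      warn(paste0("Dose(s) beyond the experimental range: ",
                  paste(over, collapse = ", ")))
    }
  }
  combo <- ctrl
  combo[names(doses)] <- as.list(unname(doses))
  sp0 <- predict_spermophagy(ctrl, beta)$sp_hat
  sp1 <- predict_spermophagy(combo, beta)$sp_hat
  ord <- names(doses)[order(match(names(doses), bofc_factors()))]
  tibble(combination = paste(ord, collapse = "+"),
         n_factors = length(doses), sp_control = sp0, sp_combo = sp1,
         percent_change = 100 * (sp1 - sp0) / sp0)
}

#' All single and pairwise combination effects at reference doses
#'
#' Builds the full set of individual and order-`max_order` combination
#' predictions at each factor's reference dose (default: its maximum
#' experimental dose), the input expected by [classify_factors()].
#'
#' @inheritParams combination_effect
#' @param factors Factors to combine (default all seven).
#' @param doses Named reference dose per factor.
#' @param max_order Largest combination size (default 2 = pairwise).
#' @return Tibble of [combination_effect()] rows.
#' @export
combination_report <- function(beta, factors = bofc_factors(),
                               doses = default_dose_maxima(),
                               control = NULL, max_order = 2) {
  stopifnot(length(factors) >= 1, max_order >= 1)
  combos <- purrr::map(seq_len(min(max_order, length(factors))),
                       function(k) utils::combn(factors, k, simplify = FALSE))
  combos <- purrr::flatten(combos)
  purrr::map_dfr(combos, function(fs) {
    combination_effect(beta, doses[fs], control = control,
                       ranges = NULL)
  })
}

#' Rank and classify factors by their mean combination effect
#'
#' Each factor is scored by the mean percent *reduction* of spermophagy
#' (the negated percent change) across every combination containing it.
#' Factors are ranked by that score and partitioned into `n_classes`
#' contiguous classes at the largest gaps of the ranked scores, class 1
#' holding the strongest reducers.
#'
#' @param reports Tibble of combination rows ([combination_report()]
#'   output or equivalent, with `combination` and `percent_change`).
#' @param n_classes Number of classes (default 3).
#' @return Tibble with one row per factor: `factor`, `mean_reduction`,
#'   `rank`, `class`.
#' @export
classify_factors <- function(reports, n_classes = 3) {
  if (!is.data.frame(reports) || nrow(reports) == 0 ||
      !all(c("combination", "percent_change") %in% names(reports))) {
    abort("`reports` must be a nonempty tibble with `combination` and `percent_change`.",
          class = "spermophagy_input_error")
  }
  members <- strsplit(reports$combination, "+", fixed = TRUE)
  factors <- sort(unique(unlist(members)))
  factors <- setdiff(factors, "(control)")
  if (length(factors) == 0) {
    abort("No factors found in `reports`.",
          class = "spermophagy_input_error")
  }
  score <- purrr::map_dbl(factors, function(f) {
    hit <- purrr::map_lgl(members, ~ f %in% .x)
    mean(-reports$percent_change[hit])
  })
  out <- tibble(factor = factors, mean_reduction = score) %>%
    arrange(desc(.data$mean_reduction)) %>%
    mutate(rank = row_number())
  k <- min(n_classes, nrow(out))
  cls <- rep(1L, nrow(out))
  if (k > 1 && nrow(out) > 1) {
    gaps <- -diff(out$mean_reduction)            # drop between consecutive ranks
    cut_after <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1)])
    cls <- cumsum(c(1L, as.integer(seq_along(gaps) %in% cut_after)))
  }
  out$class <- cls
  out
}

#' Rank factors by their ability to abrogate the ANGII effect
#'
#' ANGII is the one component that *increases* predicted spermophagy.  Each
#' candidate factor is scored by the percent change of predicted
#' spermophagy when it is added (at its reference dose) to an ANGII-only
#' profile, relative to ANGII alone — an interpretation of "abrogation" as
#' the suppression achieved on top of the ANGII background.
#'
#' @inheritParams combination_report
#' @param angii_dose ANGII background dose (default its experimental
#'   maximum).
#' @return Tibble ranked by strongest suppression: `factor`,
#'   `percent_change_vs_angii`, `rank`.
#' @export
abrogation_ranking <- function(beta, factors = setdiff(bofc_factors(), "angii"),
                               doses = default_dose_maxima(),
                               angii_dose = default_dose_maxima()[["angii"]]) {
  if (inherits(beta, "alr_fit")) beta <- coef(predict_beta_full(beta))
  beta <- check_beta(beta)
  base <- c(angii = angii_dose)
  rows <- purrr::map_dfr(factors, function(f) {
    d <- c(base, setNames(doses[[f]], f))
    eff <- combination_effect(beta, d, control = base, ranges = NULL)
    tibble(factor = f, percent_change_vs_angii = eff$percent_change)
  })
  rows %>%
    arrange(.data$percent_change_vs_angii) %>%
    mutate(rank = row_number())
}

#' Plot marginal-effect curves for several factors
#'
#' @param beta Coefficient vector or `alr_fit`.
#' @param factors Factors to plot.
#' @param dose_maxima Named dose anchors (scale 1) per factor.
#' @return A ggplot object of effect vs scaled dose, one line per factor.
#' @export
plot_marginal_effects <- function(beta, factors = bofc_factors(),
                                  dose_maxima = default_dose_maxima()) {
  grids <- purrr::map_dfr(factors, function(f) {
    marginal_grid(beta, f, dose_max = dose_maxima[[f]])
  })
  ggplot2::ggplot(grids, ggplot2::aes(x = .data$scale, y = .data$effect,
                                      colour = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dose (multiple of experimental maximum)",
                  y = "marginal effect on predicted spermophagy",
                  colour = "component") +
    ggplot2::theme_minimal()
}
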