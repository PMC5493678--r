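#' Map observed spermophagy onto the (0, 1) response scale
#'
#' The phagocytosis ratio SP (observed spermophagy relative to control,
#' roughly 0.2--1.4 in the source experiments) is placed on the open unit
#' interval by the affine map RP = 0.2 + (1.4 - SP) / 2 so that a logistic
#' model can be fitted to it.  Larger RP corresponds to a stronger
#' *reduction* of spermophagy.
#'
#' @param sp Numeric vector of spermophagy values.
#' @return Numeric vector of mapped responses.  A warning is raised when a
#'   mapped value falls outside the open interval (0, 1), since the logistic
#'   quasi-likelihood is undefined at the endpoints.
#' @seealso [map_rp_to_sp()] for the inverse.
#' @export
#' @examples
#' map_sp_to_rp(c(1.4, 1.0, 0.23))
map_sp_to_rp <- function(sp) {
  stopifnot(is.numeric(sp))
  if (any(!is.finite(sp))) {
    abort("`sp` must be finite.", class = "spermophagy_domain_error")
  }
  rp <- 0.2 + (1.4 - sp) / 2
  out <- rp <= 0 | rp >= 1
  if (any(out)) {
    warn(sprintf(
      "%d mapped response value(s) fall outside (0, 1); the quasi-likelihood is undefined there.",
      sum(out)))
  }
  rp
}

#' Invert the response mapping back to the spermophagy scale
#'
#' Algebraic inverse of [map_sp_to_rp()]: SP = 1.8 - 2 RP.  Applied to a
#' logistic probability it converts a model prediction back to the
#' phagocytosis-ratio scale on which the experiments are reported.
#'
#' @param rp Numeric vector of responses (typically in (0, 1)).
#' @return Numeric vector of spermophagy values.
#' @export
#' @examples
#' map_rp_to_sp(map_sp_to_rp(0.85))
map_rp_to_sp <- function(rp) {
  stopifnot(is.numeric(rp))
  if (any(!is.finite(rp))) {
    abort("`rp` must be finite.", class = "spermophagy_domain_error")
  }
  1.8 - 2 * rp
}

#' Convert endothelin-1 concentrations between pg/ml and ng/ml
#'
#' EDN-1 doses are stored in pg/ml throughout the package (the unit of the
#' experimental dose tables, 0--2490 pg/ml).  Some summaries of the same
#' experiments quote ng/ml (0--24.9).  Conversion is never done silently;
#' use these helpers where a different unit is required.
#'
#' @param x Numeric vector of concentrations.
#' @return Converted numeric vector.
#' @export
#' @examples
#' edn1_pg_to_ng(2490)  # 2.49 ng/ml
edn1_pg_to_ng <- function(x) x / 1000

#' @rdname edn1_pg_to_ng
#' @export
edn1_ng_to_pg <- function(x) x * 1000
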