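#' Validate a tibble of dose-response observations
#'
#' An observation set is a plain tibble with one row per assay condition:
#' the seven component doses (`bsa`, `lh`, `boec`, `angii`, `pge2`, `agp`,
#' `edn1`), the observed spermophagy `sp`, the mapped response `rp`, and
#' optionally `superoxide` and a `source` study label.  `as_observations()`
#' fills in missing dose columns with 0, derives `rp` from `sp` (or `sp`
#' from `rp`) where absent, and enforces the domain invariants: doses are
#' non-negative, `boec` is a 0/1 indicator, and `sp`/`rp` are consistent
#' under the response mapping.
#'
#' @param data A data frame.
#' @param fill_missing_doses If `TRUE` (default) absent dose columns are
#'   added as 0; otherwise their absence is an error.
#' @return A tibble with the dose columns in fixed order, then `sp`, `rp`
#'   and any extra columns.
#' @export
#' @examples
#' as_observations(tibble::tibble(agp = c(0, 100), sp = c(1.0, 0.6)))
as_observations <- function(data, fill_missing_doses = TRUE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "spermophagy_input_error")
  }
  data <- as_tibble(data)
  covs <- bofc_factors()
  missing_doses <- setdiff(covs, names(data))
  if (length(missing_doses) > 0) {
    if (!fill_missing_doses) {
      abort(paste0("Missing dose column(s): ",
                   paste(missing_doses, collapse = ", ")),
            class = "spermophagy_missing_column_error")
    }
    for (nm in missing_doses) data[[nm]] <- 0
  }
  if (!"sp" %in% names(data) && !"rp" %in% names(data)) {
    abort("`data` must contain an `sp` (spermophagy) or `rp` (mapped response) column.",
          class = "spermophagy_missing_column_error")
  }

  for (nm in c(covs, intersect(c("sp", "rp", "superoxide"), names(data)))) {
    col <- data[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(sprintf("Column `%s` is not numeric (first offending row: %s).",
                    nm, ifelse(is.na(bad), "?", bad)),
            class = "spermophagy_nonnumeric_error")
    }
    if (anyNA(col)) {
      abort(sprintf("Column `%s` contains missing values.", nm),
            class = "spermophagy_nonnumeric_error")
    }
  }
  for (nm in setdiff(covs, "boec")) {
    if (any(data[[nm]] < 0)) {
      abort(sprintf("Column `%s` contains negative concentrations.", nm),
            class = "spermophagy_negative_concentration_error")
    }
  }
  if (!all(data$boec %in% c(0, 1))) {
    abort("`boec` must be a 0/1 co-culture indicator.",
          class = "spermophagy_invariant_error")
  }

  if (!"rp" %in% names(data)) {
    data$rp <- map_sp_to_rp(data$sp)
  } else if (!"sp" %in% names(data)) {
    data$sp <- map_rp_to_sp(data$rp)
  } else if (max(abs(data$rp - map_sp_to_rp(data$sp))) > 1e-8) {
    abort("`sp` and `rp` columns are inconsistent with rp = 0.2 + (1.4 - sp)/2.",
          class = "spermophagy_invariant_error")
  }
  if (nrow(data) < 1) {
    abort("Observation set must contain at least one row.",
          class = "spermophagy_input_error")
  }
  rest <- setdiff(names(data), c(covs, "sp", "rp"))
  data[, c(covs, "sp", "rp", rest)]
}

#' Read dose-response observations from CSV
#'
#' Reads a UTF-8 comma-separated file with a header row and the column
#' names of [as_observations()] (a `column_map` can rename non-standard
#' headers), then validates it.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping standard names
#'   to the file's header names, e.g. `c(sp = "phagocytosis")`.
#' @return A validated observation tibble.
#' @export
read_observations <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "spermophagy_input_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) {
        abort(sprintf("Mapped column `%s` (for `%s`) not found in %s.",
                      src, std, path),
              class = "spermophagy_missing_column_error")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  as_observations(raw, fill_missing_doses = FALSE)
}

#' Write an observation tibble to CSV
#'
#' Companion writer to [read_observations()]; full numeric precision is
#' preserved on a read/write round trip.
#'
#' @param data An observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  data <- as_observations(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# intercept-augmented design matrix in the fixed covariate order
design_matrix <- function(data, covariates = bofc_factors()) {
  stopifnot(all(covariates %in% names(data)))
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             as.matrix(data[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}
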