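# md5 of the packaged validation table; guards against silent corruption
.fixture_md5 <- "f071af8f7b68e2b0dfda8a3c06a749f3"

#' The bundled 15-row literature validation table
#'
#' Fifteen in vitro conditions compiled from the published dose-response
#' experiments (Marey 2016a/b, Liu 2014) that report both sperm
#' phagocytosis and superoxide production, together with the reference
#' predictions of the penalized (ALR) and plain (LR) logistic models for
#' each condition.  Doses not reported for a condition are encoded as 0;
#' EDN-1 is in pg/ml as printed in the source tables.
#'
#' The `alr_ref`/`lr_ref` columns are treated as given reference data: the
#' table contains two rows with identical listed doses but different
#' reference predictions, so these columns cannot be a pure function of the
#' listed inputs and are never recomputed by the package.
#'
#' @param path Path to the fixture CSV; defaults to the copy installed with
#'   the package.  Exposed for testing the integrity check.
#' @return A validated observation tibble with 15 rows and columns
#'   `source`, doses, `phagocytosis` (= `sp`), `superoxide`, `alr_ref`,
#'   `lr_ref`.
#' @export
#' @examples
#' fx <- validation_fixture()
#' nrow(fx)
validation_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_validation.csv",
                        package = "spermophagy", mustWork = TRUE)
  }
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .fixture_md5)) {
    abort(sprintf(
      "Validation fixture at %s is corrupted (md5 %s, expected %s).",
      path, sum, .fixture_md5),
      class = "spermophagy_fixture_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[names(raw) == "phagocytosis"] <- "sp"
  out <- as_observations(raw, fill_missing_doses = FALSE)
  out$phagocytosis <- out$sp
  out
}
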