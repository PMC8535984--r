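#' Packaged reference data
#'
#' Small plain-text data sets shipped with the package:
#'
#' * `accident_deaths_2000_2020` — annual work-safety accident deaths in
#'   China, 2000-2020 (21 values), compiled from national statistical and
#'   work-safety yearbooks. Columns `year`, `value`.
#' * `accident_model_fits` — the accident-death series together with
#'   published GM(1,1) and Gaussian-grey fitted values and their relative
#'   errors, used for arithmetic consistency checks. Columns `year`,
#'   `true_value`, `gm_predicted`, `gm_relative_error`, `ggm_predicted`,
#'   `ggm_relative_error`.
#' * `accident_economy_correlations` — published grey relational degrees,
#'   Pearson coefficients and composite coefficients between three accident
#'   indicators and five economic indicators, with a comprehensive-index row
#'   per block. Columns `block`, `indicator`, then one column per economic
#'   indicator.
#'
#' @param name One of the fixture names above.
#' @return A tibble; the data source is attached as attribute `provenance`.
#' @examples
#' grey_fixture("accident_deaths_2000_2020")
#' @export
grey_fixture <- function(name) {
  files <- c(
    accident_deaths_2000_2020 = "accident_deaths_2000_2020.csv",
    accident_model_fits = "accident_model_fits.csv",
    accident_economy_correlations = "accident_economy_correlations.csv"
  )
  if (length(name) != 1 || !name %in% names(files)) {
    abort(paste0("unknown fixture `", paste(name, collapse = ", "),
                 "`; available: ", paste(names(files), collapse = ", "), "."),
          class = "greycast_invalid_input")
  }
  path <- system.file("extdata", files[[name]], package = "greycast",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(out, "provenance") <- switch(
    name,
    accident_deaths_2000_2020 =
      "Annual work-safety accident deaths, China, 2000-2020 (national statistical / work-safety yearbooks).",
    accident_model_fits =
      "Published grey-model fitted values and relative errors accompanying the accident-death series.",
    accident_economy_correlations =
      "Published correlation coefficients between accident and economic indicators."
  )
  out
}

#' @rdname grey_fixture
#' @export
grey_fixtures <- function() {
  c("accident_deaths_2000_2020", "accident_model_fits",
    "accident_economy_correlations")
}
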