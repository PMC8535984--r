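#' Specification of a synthetic annual series
#'
#' Three generator families cover the structural shapes the package models:
#'
#' * `economy_like` — a monotonically growing indicator with smooth
#'   multiplicative drift (`growth` per year) and lognormal year-to-year
#'   noise on the log scale (`noise_sd`), emulating national economic
#'   indicators that rise steadily over two decades.
#' * `accident_like` — a rise-then-decline series whose cumulative sum
#'   follows the Gaussian-exponential grey trajectory with parameters
#'   (`a`, `b`, `mu`, `sigma`), plus multiplicative noise; increments peak
#'   in the first quarter of the series, echoing accident counts that climb
#'   for a few years and then fall.
#' * `grey_exact` — noise-free increments of the Gaussian grey trajectory;
#'   refitting such a series must recover the development coefficient.
#'
#' Noise is multiplicative lognormal so generated values stay positive.
#'
#' @param kind `"economy_like"`, `"accident_like"` or `"grey_exact"`.
#' @param n Series length (>= 4); default 21, a two-decade annual window.
#' @param start_year First calendar year; default 2000.
#' @param seed Integer seed; the same spec and seed give bit-identical series.
#' @param first_value First value of the series.
#' @param growth Annual multiplicative growth factor (economy_like).
#' @param noise_sd Standard deviation of log-scale noise (>= 0).
#' @param a,b Grey development coefficient and action quantity
#'   (accident_like, grey_exact).
#' @param mu,sigma Gaussian location and width of the trajectory.
#' @return An object of class `synthetic_spec` (a validated list).
#' @examples
#' synthetic_spec("economy_like", growth = 1.08, seed = 42)
#' @export
synthetic_spec <- function(kind = c("economy_like", "accident_like", "grey_exact"),
                           n = 21, start_year = 2000, seed = 1,
                           first_value = NULL, growth = 1.10, noise_sd = NULL,
                           a = NULL, b = NULL, mu = 0, sigma = 1) {
  kind <- match.arg(kind)
  if (n < 4) abort("`n` must be at least 4.", class = "greycast_invalid_input")
  if (sigma <= 0) abort("`sigma` must be positive.", class = "greycast_invalid_input")
  first_value <- first_value %||%
    switch(kind, economy_like = 10000, accident_like = 120000, grey_exact = 1000)
  noise_sd <- noise_sd %||% switch(kind, economy_like = 0.05,
                                   accident_like = 0.05, grey_exact = 0)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "greycast_invalid_input")
  if (kind == "economy_like" && growth <= 0) {
    abort("`growth` must be positive.", class = "greycast_invalid_input")
  }
  if (kind != "economy_like") {
    a <- a %||% switch(kind, accident_like = 0.03, grey_exact = 0.05)
    b <- b %||% switch(kind,
                       accident_like = a * (first_value + 3.0e6),
                       grey_exact = a * (first_value + 1e5))
    if (a == 0) abort("`a` must be nonzero.", class = "greycast_invalid_input")
    if (kind == "grey_exact" && noise_sd != 0) {
      abort("`grey_exact` series are noise-free; set `noise_sd = 0`.",
            class = "greycast_invalid_input")
    }
  }
  structure(
    list(kind = kind, n = as.integer(n), start_year = as.integer(start_year),
         seed = as.integer(seed), first_value = first_value, growth = growth,
         noise_sd = noise_sd, a = a, b = b, mu = mu, sigma = sigma),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic annual series from a spec
#'
#' Deterministic given the spec (including its seed); randomness is drawn in
#' a locally scoped RNG so the caller's random state is untouched.
#'
#' @param spec A [synthetic_spec()] object.
#' @return A tibble with columns `year` and `value`, all values positive.
#' @examples
#' generate_series(synthetic_spec("economy_like", n = 6, noise_sd = 0, growth = 1.1))
#' @export
generate_series <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be created by `synthetic_spec()`.",
          class = "greycast_invalid_input")
  }
  k <- seq_len(spec$n)
  base <- switch(
    spec$kind,
    economy_like = spec$first_value * spec$growth^(k - 1),
    accident_like = ,
    grey_exact = {
      cum <- grey_cumulative(spec$first_value, spec$a, spec$b, k = k,
                             mode = "gaussian", mu = spec$mu,
                             sigma = spec$sigma, anchor = TRUE)
      iago(cum)
    }
  )
  if (any(!is.finite(base)) || any(base <= 0)) {
    abort("spec yields nonpositive or nonfinite values; adjust parameters.",
          class = "greycast_generation_error")
  }
  values <- if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, base * exp(stats::rnorm(spec$n, 0, spec$noise_sd)))
  } else {
    base
  }
  tibble(year = spec$start_year + k - 1L, value = values)
}

#' Generate a panel of one or more references plus comparison series
#'
#' Builds a wide panel suitable for [grey_relational()] and
#' [correlation_table()]: accident-like reference column(s) and economy-like
#' comparison columns sharing the same years. Comparison seeds are derived
#' from `seed` so each column gets an independent stream; pass explicit
#' specs to control any column (a comparison spec identical to the reference
#' spec reproduces the reference column exactly).
#'
#' @param seed Integer master seed.
#' @param n Series length; default 21.
#' @param start_year First calendar year; default 2000.
#' @param n_references Number of accident-like reference columns (named
#'   `accident_index` or `accident_index_1..`); default 1.
#' @param comparisons Named list of `synthetic_spec` objects for the
#'   comparison columns, or `NULL` for five default economy-like indicators
#'   (`resident_consumption`, `energy_consumption`, `education_funds`,
#'   `wage_level`, `research_input`) with mildly different growth rates.
#' @param reference_spec Optional `synthetic_spec` (or list of specs, one per
#'   reference) overriding the default accident-like reference(s).
#' @return A tibble: `year`, reference column(s), comparison columns.
#' @examples
#' generate_panel(seed = 1)
#' @export
generate_panel <- function(seed = 1, n = 21, start_year = 2000,
                           n_references = 1, comparisons = NULL,
                           reference_spec = NULL) {
  if (is.null(comparisons)) {
    growths <- c(resident_consumption = 1.09, energy_consumption = 1.06,
                 education_funds = 1.12, wage_level = 1.10,
                 research_input = 1.14)
    comparisons <- purrr::imap(growths, function(g, nm) {
      synthetic_spec("economy_like", n = n, start_year = start_year,
                     seed = seed + match(nm, names(growths)), growth = g)
    })
  }
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    abort("`comparisons` must be a named list of specs.",
          class = "greycast_invalid_input")
  }
  if (is.null(reference_spec)) {
    reference_spec <- purrr::map(seq_len(n_references), function(i) {
      synthetic_spec("accident_like", n = n, start_year = start_year,
                     seed = seed + 100L + i)
    })
  } else if (inherits(reference_spec, "synthetic_spec")) {
    reference_spec <- list(reference_spec)
  }
  ref_names <- if (length(reference_spec) == 1) "accident_index" else
    paste0("accident_index_", seq_along(reference_spec))
  all_specs <- c(stats::setNames(reference_spec, ref_names), comparisons)
  bad_n <- purrr::map_int(all_specs, "n") != n
  if (any(bad_n)) {
    abort(paste0("spec length mismatch in: ",
                 paste(names(all_specs)[bad_n], collapse = ", ")),
          class = "greycast_invalid_input")
  }
  cols <- purrr::map(all_specs, ~ generate_series(.x)$value)
  dplyr::bind_cols(
    tibble(year = start_year + seq_len(n) - 1L),
    as_tibble(cols)
  )
}
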