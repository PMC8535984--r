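#' Validate an annual series data frame
#'
#' Checks the contract assumed by every grey-model operation: a `year` column
#' of consecutive integer calendar years, a strictly positive `value` column,
#' and at least four observations.
#'
#' @param data A data frame with columns `year` and `value`.
#' @return The input as a tibble, invisibly usable downstream.
#' @keywords internal
validate_series <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `year` and `value`.",
          class = "greycast_invalid_input")
  }
  missing_cols <- setdiff(c("year", "value"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "greycast_invalid_input")
  }
  data <- as_tibble(data[c("year", "value")])
  n <- nrow(data)
  if (n < 4) {
    abort(paste0("Grey models need at least 4 observations; got ", n, "."),
          class = "greycast_invalid_input")
  }
  if (anyNA(data$year) || anyNA(data$value)) {
    abort("`year` and `value` must not contain missing values.",
          class = "greycast_invalid_input")
  }
  if (any(diff(data$year) != 1)) {
    abort("`year` must be strictly increasing consecutive calendar years.",
          class = "greycast_invalid_input")
  }
  bad <- which(data$value <= 0)
  if (length(bad) > 0) {
    abort(paste0("All values must be positive; offending year(s): ",
                 paste(data$year[bad], collapse = ", "), "."),
          class = "greycast_invalid_input")
  }
  data
}

#' Order-ratio admissibility screen
#'
#' Computes the order ratios lambda(k) = x(k-1)/x(k) of a raw series and
#' checks them against the admissible interval
#' (exp(-2/(n+1)), exp(2/(n+1))). A series whose ratios all fall inside the
#' interval is considered well-suited to grey modelling; ratios outside it
#' flag abrupt level shifts that a smooth grey trajectory cannot track.
#' The check is advisory: it reports violations, it does not stop a fit.
#'
#' @param data A data frame with columns `year` and `value` (n >= 4,
#'   positive values, consecutive years).
#' @return An object of class `order_ratio_report`: a list with `ratios`
#'   (tibble of `year`, `lambda`), `lower_bound`, `upper_bound`,
#'   `admissible`, and `violations` (years whose incoming ratio falls
#'   outside the interval).
#' @examples
#' deaths <- grey_fixture("accident_deaths_2000_2020")
#' order_ratio_test(deaths)
#' @export
order_ratio_test <- function(data) {
  data <- validate_series(data)
  n <- nrow(data)
  lambda <- data$value[-n] / data$value[-1]
  lower <- exp(-2 / (n + 1))
  upper <- exp(2 / (n + 1))
  outside <- lambda <= lower | lambda >= upper
  out <- list(
    ratios = tibble(year = data$year[-1], lambda = lambda),
    lower_bound = lower,
    upper_bound = upper,
    admissible = !any(outside),
    violations = data$year[-1][outside]
  )
  class(out) <- "order_ratio_report"
  out
}

#' @export
print.order_ratio_report <- function(x, ...) {
  cat(sprintf("Order-ratio admissibility check (n = %d)\n",
              nrow(x$ratios) + 1L))
  cat(sprintf("  admissible interval: (%.5f, %.5f)\n",
              x$lower_bound, x$upper_bound))
  if (x$admissible) {
    cat("  all order ratios fall inside the interval.\n")
  } else {
    cat(sprintf("  %d ratio(s) outside the interval at year(s): %s\n",
                length(x$violations), paste(x$violations, collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.order_ratio_report <- function(x, ...) {
  dplyr::mutate(
    x$ratios,
    admissible = .data$lambda > x$lower_bound & .data$lambda < x$upper_bound
  )
}
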