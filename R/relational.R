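#' Dimensionless normalization of a series panel
#'
#' Grey relational analysis compares sequences of very different magnitudes
#' (death counts vs. yuan), so each series is first made dimensionless.
#' The default divides every series by its own first element, so every
#' normalized series starts at 1 and proportional series become identical.
#' `"as_printed"` divides every column at time k by the first comparison
#' column's value at time k (a published variant that depends on column
#' order); `"none"` is the identity.
#'
#' @param data A data frame with a `year` column and one numeric column per
#'   series.
#' @param method `"initial_value"` (default), `"none"`, or `"as_printed"`.
#' @return A tibble of the same shape with normalized series.
#' @examples
#' panel <- tibble::tibble(year = 1:4, a = c(2, 4, 6, 8), b = c(10, 20, 30, 40))
#' gra_normalize(panel)
#' @export
gra_normalize <- function(data, method = c("initial_value", "none", "as_printed")) {
  method <- match.arg(method)
  data <- check_panel(data)
  if (method == "none") return(data)
  series_cols <- setdiff(names(data), "year")
  if (method == "initial_value") {
    firsts <- purrr::map_dbl(data[series_cols], 1)
    if (any(firsts == 0)) {
      abort(paste0("first value is zero in column(s): ",
                   paste(series_cols[firsts == 0], collapse = ", "),
                   "; initial-value normalization undefined."),
            class = "greycast_invalid_input")
    }
    data[series_cols] <- purrr::map2(data[series_cols], firsts, `/`)
    return(data)
  }
  # as_printed: divide every column by the first series column, elementwise
  base <- data[[series_cols[1]]]
  if (any(base == 0)) {
    abort("the first series column contains zeros; as-printed normalization undefined.",
          class = "greycast_invalid_input")
  }
  data[series_cols] <- purrr::map(data[series_cols], ~ .x / base)
  data
}

check_panel <- function(data) {
  if (!is.data.frame(data) || !"year" %in% names(data)) {
    abort("panel must be a data frame with a `year` column.",
          class = "greycast_invalid_input")
  }
  series_cols <- setdiff(names(data), "year")
  if (length(series_cols) < 1) {
    abort("panel needs at least one series column besides `year`.",
          class = "greycast_invalid_input")
  }
  if (!all(purrr::map_lgl(data[series_cols], is.numeric))) {
    abort("all series columns must be numeric.", class = "greycast_invalid_input")
  }
  if (anyNA(data[series_cols])) {
    abort("panel series must not contain missing values.",
          class = "greycast_invalid_input")
  }
  as_tibble(data)
}

#' Pointwise deviations between a reference and comparison series
#'
#' Computes Delta_i(k) = |y(k) - x_i(k)| for every comparison series i and
#' time k, together with the global minimum and maximum deviation over all
#' i and k (the extrema entering the grey relational coefficient).
#'
#' @param data A panel data frame (`year` + numeric series columns).
#' @param reference Name of the reference column.
#' @param comparisons Character vector of comparison column names; default
#'   all non-year, non-reference columns.
#' @return A tibble with columns `comparison`, `year`, `delta`, carrying
#'   attributes `global_min` and `global_max`.
#' @export
gra_deviations <- function(data, reference, comparisons = NULL) {
  data <- check_panel(data)
  series_cols <- setdiff(names(data), "year")
  if (!reference %in% series_cols) {
    abort(paste0("reference column `", reference, "` not found in panel."),
          class = "greycast_invalid_input")
  }
  comparisons <- comparisons %||% setdiff(series_cols, reference)
  missing_cols <- setdiff(comparisons, series_cols)
  if (length(missing_cols) > 0) {
    abort(paste0("comparison column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "greycast_invalid_input")
  }
  y <- data[[reference]]
  out <- purrr::map_dfr(comparisons, function(nm) {
    tibble(comparison = nm, year = data$year, delta = abs(y - data[[nm]]))
  })
  attr(out, "global_min") <- min(out$delta)
  attr(out, "global_max") <- max(out$delta)
  out
}

#' Grey relational coefficients
#'
#' For each deviation Delta_i(k), the coefficient is
#' `(min + rho * max) / (Delta_i(k) + rho * max)` with the global extrema
#' `min`/`max` over all series and times, and resolution coefficient `rho`.
#' Coefficients lie in (0, 1]; a cell attains 1 exactly where its deviation
#' equals the global minimum of 0. When all series are identical
#' (`max = 0`), every coefficient is defined as the limit value 1 with a
#' warning.
#'
#' @param deviations Output of [gra_deviations()].
#' @param resolution The resolution coefficient rho in (0, 1); default 0.5.
#' @return A tibble with columns `comparison`, `year`, `xi`.
#' @export
gra_coefficients <- function(deviations, resolution = 0.5) {
  if (!is.numeric(resolution) || resolution <= 0 || resolution >= 1) {
    abort("`resolution` must lie in (0, 1).", class = "greycast_invalid_input")
  }
  gmin <- attr(deviations, "global_min")
  gmax <- attr(deviations, "global_max")
  if (is.null(gmin) || is.null(gmax)) {
    gmin <- min(deviations$delta)
    gmax <- max(deviations$delta)
  }
  if (gmax == 0) {
    warn("all series identical (global max deviation 0); coefficients set to 1.",
         class = "greycast_degenerate_warning")
    xi <- rep(1, nrow(deviations))
  } else {
    xi <- (gmin + resolution * gmax) / (deviations$delta + resolution * gmax)
  }
  tibble(comparison = deviations$comparison, year = deviations$year, xi = xi)
}

#' Grey relational degree
#'
#' Averages the grey relational coefficients over time for each comparison
#' series, giving one similarity number gamma_i in (0, 1] per series.
#'
#' @param coefficients Output of [gra_coefficients()].
#' @return A tibble with columns `comparison` and `gamma`, in first-appearance
#'   order of the comparisons.
#' @export
gra_degree <- function(coefficients) {
  out <- dplyr::summarise(
    dplyr::group_by(coefficients, .data$comparison),
    gamma = mean(.data$xi), .groups = "drop"
  )
  out[match(unique(coefficients$comparison), out$comparison), ]
}

#' Pearson correlation between two series
#'
#' Sample Pearson correlation coefficient; invariant to positive affine
#' transforms of either series (hence unchanged by initial-value
#' normalization). Errors on degenerate (zero-variance) input.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2.",
          class = "greycast_invalid_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance: Pearson correlation undefined.",
          class = "greycast_degenerate")
  }
  cor(x, y)
}

#' Composite correlation coefficient
#'
#' Blends the grey relational degree and the Pearson coefficient as
#' `blend * gamma + (1 - blend) * epsilon`, capturing both shape similarity
#' (grey) and linear co-movement (Pearson) in one number.
#'
#' @param gamma,epsilon Numeric vectors of equal length.
#' @param blend The proportional coefficient phi in \[0, 1\]; default 0.5.
#' @return Numeric vector of composite coefficients.
#' @examples
#' composite_correlation(0.766539, 0.956225)  # 0.861382
#' @export
composite_correlation <- function(gamma, epsilon, blend = 0.5) {
  if (!is.numeric(blend) || blend < 0 || blend > 1) {
    abort("`blend` must lie in [0, 1].", class = "greycast_invalid_input")
  }
  if (length(gamma) != length(epsilon)) {
    abort("`gamma` and `epsilon` must have equal length.",
          class = "greycast_invalid_input")
  }
  blend * gamma + (1 - blend) * epsilon
}

#' Grey relational analysis of one reference series against comparisons
#'
#' Runs the full pipeline: dimensionless normalization (for the grey part;
#' the Pearson part uses the raw series, to which it is invariant anyway),
#' pointwise deviations, grey relational coefficients, grey relational
#' degree, Pearson correlation and the blended composite coefficient.
#'
#' @param data A panel data frame (`year` + numeric series columns).
#' @param reference Name of the reference column.
#' @param comparisons Character vector of comparison column names; default
#'   all other series columns.
#' @param resolution Resolution coefficient rho in (0, 1); default 0.5.
#' @param blend Proportional coefficient phi in \[0, 1\]; default 0.5.
#' @param normalize Normalization method, see [gra_normalize()].
#' @return An object of class `grey_relational`: list with `summary`
#'   (tibble of `comparison`, `gamma`, `epsilon`, `rho`), `coefficients`
#'   (long tibble of xi), `deviations`, and the configuration.
#' @examples
#' panel <- generate_panel(seed = 7)
#' grey_relational(panel, reference = "accident_index")
#' @export
grey_relational <- function(data, reference, comparisons = NULL,
                            resolution = 0.5, blend = 0.5,
                            normalize = c("initial_value", "none", "as_printed")) {
  normalize <- match.arg(normalize)
  data <- check_panel(data)
  comparisons <- comparisons %||% setdiff(names(data), c("year", reference))
  norm <- gra_normalize(data[c("year", reference, comparisons)], method = normalize)
  dev <- gra_deviations(norm, reference, comparisons)
  xi <- gra_coefficients(dev, resolution = resolution)
  deg <- gra_degree(xi)
  eps <- purrr::map_dbl(comparisons, ~ pearson_correlation(data[[.x]], data[[reference]]))
  summary <- tibble(
    comparison = deg$comparison,
    gamma = deg$gamma,
    epsilon = eps[match(deg$comparison, comparisons)],
    rho = composite_correlation(deg$gamma, eps[match(deg$comparison, comparisons)],
                                blend = blend)
  )
  structure(
    list(summary = summary, coefficients = xi, deviations = dev,
         reference = reference, resolution = resolution, blend = blend,
         normalize = normalize),
    class = "grey_relational"
  )
}

#' @export
print.grey_relational <- function(x, ...) {
  cat(sprintf("Grey relational analysis (reference: %s, rho = %g, phi = %g)\n",
              x$reference, x$resolution, x$blend))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.grey_relational <- function(x, ...) x$summary

#' @export
autoplot.grey_relational <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, c("gamma", "epsilon", "rho"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "coefficient", fill = NULL,
                  title = paste("Relational analysis vs", object$reference)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Comprehensive index row: mean over the accident-indicator rows
#'
#' Given exactly three rows of per-indicator coefficients (one per accident
#' indicator, columns = economic indicators), returns their column means —
#' the "comprehensive accident index" row appended to each block of a
#' correlation table.
#'
#' @param block A data frame with exactly 3 rows and numeric columns.
#' @return A one-row tibble of column means.
#' @export
comprehensive_index <- function(block) {
  num <- dplyr::select(as_tibble(block), dplyr::where(is.numeric))
  if (nrow(num) != 3) {
    abort(paste0("comprehensive index needs exactly the 3 accident-indicator rows; got ",
                 nrow(num), "."),
          class = "greycast_invalid_input")
  }
  dplyr::summarise(num, dplyr::across(dplyr::everything(), mean))
}

#' Assemble a three-block correlation table
#'
#' For each accident (reference) indicator, computes the grey relational
#' degree, Pearson coefficient and composite coefficient against every
#' economic (comparison) indicator, then stacks them as three blocks
#' (`gamma`, `epsilon`, `rho`) of rows, appending to each block a
#' "comprehensive index" row equal to the mean of the three indicator rows.
#' With 3 references the table has 12 rows.
#'
#' @param data A panel data frame containing all reference and comparison
#'   columns plus `year`.
#' @param references Character vector of reference (accident indicator)
#'   column names.
#' @param comparisons Character vector of comparison (economic indicator)
#'   column names; default all remaining series columns.
#' @inheritParams grey_relational
#' @return A tibble of class `correlation_table` with columns `block`,
#'   `indicator`, then one numeric column per comparison.
#' @examples
#' panel <- generate_panel(seed = 3, n_references = 3)
#' correlation_table(panel,
#'   references = c("accident_index_1", "accident_index_2", "accident_index_3"))
#' @export
correlation_table <- function(data, references, comparisons = NULL,
                              resolution = 0.5, blend = 0.5,
                              normalize = c("initial_value", "none", "as_printed")) {
  normalize <- match.arg(normalize)
  data <- check_panel(data)
  comparisons <- comparisons %||% setdiff(names(data), c("year", references))
  results <- purrr::map(references, function(ref) {
    grey_relational(data[c("year", ref, comparisons)], reference = ref,
                    comparisons = comparisons, resolution = resolution,
                    blend = blend, normalize = normalize)$summary
  })
  names(results) <- references
  blocks <- purrr::map_dfr(c("gamma", "epsilon", "rho"), function(meas) {
    rows <- purrr::map_dfr(references, function(ref) {
      s <- results[[ref]]
      wide <- tibble::as_tibble_row(stats::setNames(s[[meas]], s$comparison))
      dplyr::bind_cols(tibble(block = meas, indicator = ref), wide)
    })
    idx <- comprehensive_index(rows[comparisons])
    dplyr::bind_rows(rows, dplyr::bind_cols(
      tibble(block = meas, indicator = "comprehensive_index"), idx))
  })
  class(blocks) <- c("correlation_table", class(blocks))
  blocks
}
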