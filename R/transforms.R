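#' Accumulated generating operation (AGO)
#'
#' Turns a raw positive sequence x0 into its running cumulative sum x1,
#' the smoothing step every grey model fits on. `iago()` is the exact
#' inverse: first value kept, successive differences thereafter.
#'
#' @param x A numeric vector.
#' @return A numeric vector of the same length.
#' @examples
#' ago(c(1, 2, 3))   # 1 3 6
#' iago(ago(c(1, 2, 3)))
#' @export
ago <- function(x) {
  if (length(x) == 0) abort("empty sequence.", class = "greycast_invalid_input")
  cumsum(x)
}

#' @rdname ago
#' @export
iago <- function(x) {
  if (length(x) == 0) abort("empty sequence.", class = "greycast_invalid_input")
  c(x[1], diff(x))
}

#' Background values of a cumulative sequence
#'
#' The background value z1(k), k = 2..n, pairs consecutive cumulative levels
#' in the grey differential equation. The classical GM(1,1) form is the
#' arithmetic mean of adjacent x1 values; the Gaussian form weights the two
#' levels by the time-dependent factors (k - mu)/sigma^2 and
#' (k - 1 - mu)/sigma^2 arising from the Gaussian-exponential trajectory.
#'
#' @param x1 Numeric vector, the cumulative (AGO) sequence, length >= 2.
#' @param mode `"classical"` (arithmetic mean) or `"gaussian"`.
#' @param mu,sigma Gaussian location and width (used in gaussian mode;
#'   `sigma` must be positive).
#' @return Numeric vector of length `length(x1) - 1` (indices k = 2..n).
#' @examples
#' background_values(c(1, 3), mode = "classical")         # 2
#' background_values(c(1, 3), mode = "gaussian")          # 3.5
#' @export
background_values <- function(x1, mode = c("classical", "gaussian"),
                              mu = 0, sigma = 1) {
  mode <- match.arg(mode)
  n <- length(x1)
  if (n < 2) abort("need at least two cumulative values.",
                   class = "greycast_invalid_input")
  k <- 2:n
  if (mode == "classical") {
    return((x1[k] + x1[k - 1]) / 2)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be a positive number.", class = "greycast_invalid_input")
  }
  0.5 * ((k - mu) / sigma^2 * x1[k] + (k - 1 - mu) / sigma^2 * x1[k - 1])
}

#' Design system of the grey differential equation
#'
#' Stacks the grey derivatives Y = x0(2..n) and the regressor matrix B whose
#' rows are `[-z1(k), 1]` in classical mode or
#' `[-z1(k), (k - 1/2 - mu)/sigma^2]` in gaussian mode, so that the model
#' parameters solve Y = B (a, b)'.
#'
#' @param values Numeric vector, the raw series x0.
#' @inheritParams background_values
#' @return A list with elements `Y` (length n - 1) and `B` ((n-1) x 2 matrix).
#' @export
grey_design <- function(values, mode = c("classical", "gaussian"),
                        mu = 0, sigma = 1) {
  mode <- match.arg(mode)
  n <- length(values)
  x1 <- ago(values)
  z <- background_values(x1, mode = mode, mu = mu, sigma = sigma)
  k <- 2:n
  second <- if (mode == "classical") rep(1, n - 1) else (k - 0.5 - mu) / sigma^2
  list(Y = values[-1], B = cbind(-z, second, deparse.level = 0))
}

#' Least-squares estimate of the grey parameters
#'
#' Solves the overdetermined system Y = B (a, b)' in the least-squares sense,
#' yielding the development coefficient `a` and grey action quantity `b`.
#' Solved via QR decomposition, which computes the same minimiser as the
#' normal-equations formula (B'B)^-1 B'Y.
#'
#' @param Y Numeric vector of grey derivatives.
#' @param B Numeric matrix with `length(Y)` rows and two columns.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
grey_estimate <- function(Y, B) {
  if (!is.matrix(B) || nrow(B) != length(Y) || ncol(B) != 2) {
    abort("`B` must be a matrix with two columns and one row per element of `Y`.",
          class = "greycast_invalid_input")
  }
  dec <- qr(B)
  if (dec$rank < 2) {
    abort("design matrix is rank deficient; grey parameters are not identifiable.",
          class = "greycast_singular")
  }
  est <- qr.coef(dec, Y)
  c(a = est[1], b = est[2])
}

#' Cumulative trajectory of a fitted grey model
#'
#' Evaluates the whitened solution of the grey differential equation at
#' indices `k`. Classical mode: `(first - b/a) exp(-a (k - 1)) + b/a`.
#' Gaussian mode: `(first - b/a) N exp(-a (k - mu)^2 / (2 sigma^2)) + b/a`,
#' where the normalising factor N is `exp(+a (1 - mu)^2 / (2 sigma^2))` when
#' `anchor = TRUE` so that the trajectory passes through `first` at k = 1
#' (the standard grey-model anchoring), and the raw
#' `exp(-a (1 - mu)^2 / (2 sigma^2))` factor when `anchor = FALSE`
#' (compatibility variant that does not anchor).
#'
#' @param first First raw observation x0(1).
#' @param a,b Development coefficient and grey action quantity.
#' @param k Integer vector of time indices (1-based) at which to evaluate.
#' @inheritParams background_values
#' @param anchor Logical; gaussian mode only, see Details.
#' @return Numeric vector of cumulative values at the requested indices.
#' @export
grey_cumulative <- function(first, a, b, k, mode = c("classical", "gaussian"),
                            mu = 0, sigma = 1, anchor = TRUE) {
  mode <- match.arg(mode)
  if (!is.finite(a) || a == 0) {
    abort("development coefficient `a` is zero; the model is degenerate (b/a undefined).",
          class = "greycast_degenerate")
  }
  level <- b / a
  if (mode == "classical") {
    return((first - level) * exp(-a * (k - 1)) + level)
  }
  if (sigma <= 0) abort("`sigma` must be positive.", class = "greycast_invalid_input")
  norm_sign <- if (anchor) 1 else -1
  (first - level) *
    exp(norm_sign * a * (1 - mu)^2 / (2 * sigma^2)) *
    exp(-a * (k - mu)^2 / (2 * sigma^2)) + level
}

#' Relative-error diagnostics between observed and fitted values
#'
#' Computes signed per-year relative errors `(fitted - observed) / denom`,
#' where the denominator is either the observed value (the textbook average
#' relative error convention) or the fitted value (the convention that
#' reproduces published grey-model error tables). Also returns the average
#' and maximum absolute relative error.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param denominator `"observed"` or `"fitted"`.
#' @param years Optional vector of labels used in error messages and output.
#' @return A list with `table` (tibble of `year`, `observed`, `fitted`,
#'   `relative_error`), `delta` (mean absolute relative error), and
#'   `max_abs_relative_error`.
#' @examples
#' grey_errors(c(130491), c(153846.738), denominator = "fitted")
#' @export
grey_errors <- function(observed, fitted,
                        denominator = c("observed", "fitted"),
                        years = seq_along(observed)) {
  denominator <- match.arg(denominator)
  if (length(observed) != length(fitted)) {
    abort("`observed` and `fitted` must have equal length.",
          class = "greycast_invalid_input")
  }
  denom <- if (denominator == "observed") observed else fitted
  zero <- which(denom == 0)
  if (length(zero) > 0) {
    abort(paste0("zero ", denominator, " value at year(s): ",
                 paste(years[zero], collapse = ", "), "; relative error undefined."),
          class = "greycast_invalid_input")
  }
  rel <- (fitted - observed) / denom
  list(
    table = tibble(year = years, observed = observed, fitted = fitted,
                   relative_error = rel),
    delta = mean(abs(rel)),
    max_abs_relative_error = max(abs(rel))
  )
}
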