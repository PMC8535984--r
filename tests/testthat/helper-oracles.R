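# Independent brute-force oracles, written directly from the defining
# formulas with plain loops. They deliberately share no code with the
# package internals they check.

# Grey relational analysis oracle: takes a reference vector and a list of
# comparison vectors, returns xi matrix, gamma, epsilon, rho.
oracle_gra <- function(y, xs, resolution = 0.5, blend = 0.5) {
  m <- length(xs)
  n <- length(y)
  yn <- y / y[1]
  xn <- lapply(xs, function(x) x / x[1])
  delta <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) delta[i, k] <- abs(yn[k] - xn[[i]][k])
  }
  gmin <- min(delta)
  gmax <- max(delta)
  xi <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      xi[i, k] <- (gmin + resolution * gmax) / (delta[i, k] + resolution * gmax)
    }
  }
  gamma <- numeric(m)
  for (i in seq_len(m)) gamma[i] <- sum(xi[i, ]) / n
  eps <- numeric(m)
  for (i in seq_len(m)) {
    x <- xs[[i]]
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    eps[i] <- num / den
  }
  rho <- blend * gamma + (1 - blend) * eps
  list(xi = xi, gamma = gamma, epsilon = eps, rho = rho)
}

# Residual sum of squares of the grey differential system for given (a, b).
grey_rss <- function(Y, B, a, b) sum((Y - B %*% c(a, b))^2)

# Series that satisfies the classical discrete grey equation exactly:
# x0(k) + a * (x1(k) + x1(k-1))/2 = b, solved forward from x1(1) = first.
exact_classical_series <- function(a, b, first, n) {
  x1 <- numeric(n)
  x1[1] <- first
  for (k in 2:n) {
    x1[k] <- (x1[k - 1] * (1 - a / 2) + b) / (1 + a / 2)
  }
  c(x1[1], diff(x1))
}

# Series that satisfies the gaussian discrete grey equation exactly:
# x0(k) + a * z(k) = b * (k - 1/2 - mu) / sigma^2.
exact_gaussian_series <- function(a, b, first, n, mu = 0, sigma = 1) {
  x1 <- numeric(n)
  x1[1] <- first
  for (k in 2:n) {
    wk <- (k - mu) / sigma^2
    wk1 <- (k - 1 - mu) / sigma^2
    # x1(k) - x1(k-1) + a/2 (wk x1(k) + wk1 x1(k-1)) = b (k - 1/2 - mu)/sigma^2
    x1[k] <- (x1[k - 1] * (1 - a * wk1 / 2) + b * (k - 0.5 - mu) / sigma^2) /
      (1 + a * wk / 2)
  }
  c(x1[1], diff(x1))
}

series_df <- function(values, start_year = 2000) {
  tibble::tibble(year = start_year + seq_along(values) - 1L, value = values)
}
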