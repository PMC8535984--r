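make_panel <- function(...) {
  cols <- list(...)
  tibble::tibble(year = 2000 + seq_along(cols[[1]]) - 1, !!!cols)
}

test_that("initial-value normalization rescales every series to start at 1", {
  panel <- make_panel(a = c(2, 4, 6), b = c(10, 20, 40))
  norm <- gra_normalize(panel)
  expect_equal(norm$a, c(1, 2, 3))
  expect_equal(norm$b, c(1, 2, 4))
  # idempotent on already-normalized series
  expect_equal(gra_normalize(norm), norm)
  # proportional series normalize to identical sequences
  set.seed(9)
  base <- runif(6, 1, 5)
  p2 <- make_panel(u = 3 * base, v = 11 * base)
  n2 <- gra_normalize(p2)
  expect_equal(n2$u, n2$v)
  expect_error(gra_normalize(make_panel(a = c(0, 1, 2), b = c(1, 2, 3))),
               class = "greycast_invalid_input")
  # as-printed variant divides by the first series column elementwise
  ap <- gra_normalize(panel, method = "as_printed")
  expect_equal(ap$a, c(1, 1, 1))
  expect_equal(ap$b, c(5, 5, 40 / 6))
})

test_that("deviations carry global extrema over all series and times", {
  panel <- make_panel(y = c(1, 2), x1 = c(1, 3))
  dev <- gra_deviations(panel, "y")
  expect_equal(dev$delta, c(0, 1))
  expect_equal(attr(dev, "global_min"), 0)
  expect_equal(attr(dev, "global_max"), 1)
  # identical comparison: all deviations zero
  dev0 <- gra_deviations(make_panel(y = c(1, 2, 3), x = c(1, 2, 3)), "y")
  expect_true(all(dev0$delta == 0))
  # permuting comparison series leaves the global extrema unchanged
  p3 <- make_panel(y = c(1, 2, 3), a = c(2, 2, 2), b = c(0, 5, 1))
  d_ab <- gra_deviations(p3, "y", c("a", "b"))
  d_ba <- gra_deviations(p3, "y", c("b", "a"))
  expect_equal(attr(d_ab, "global_min"), attr(d_ba, "global_min"))
  expect_equal(attr(d_ab, "global_max"), attr(d_ba, "global_max"))
})

test_that("relational coefficients follow the resolution formula", {
  panel <- make_panel(y = c(1, 2), x1 = c(1, 3))
  dev <- gra_deviations(panel, "y")
  xi <- gra_coefficients(dev, resolution = 0.5)
  expect_equal(xi$xi, c(1, 0.5 / 1.5))  # best cell 1, worst (0 + .5)/(1 + .5)
  # strictly decreasing in the deviation
  expect_true(all(diff(xi$xi[order(dev$delta)]) <= 0))
  # increasing resolution weakly increases coefficients above the minimum
  xi_hi <- gra_coefficients(dev, resolution = 0.9)
  above_min <- dev$delta > attr(dev, "global_min")
  expect_true(all(xi_hi$xi[above_min] >= xi$xi[above_min]))
  # degenerate all-identical panel: coefficients 1 with a warning
  dev0 <- gra_deviations(make_panel(y = c(1, 2, 3), x = c(1, 2, 3)), "y")
  expect_warning(xi0 <- gra_coefficients(dev0),
                 class = "greycast_degenerate_warning")
  expect_true(all(xi0$xi == 1))
  expect_error(gra_coefficients(dev, resolution = 1),
               class = "greycast_invalid_input")
})

test_that("grey degree is the time average of coefficients", {
  xi <- tibble::tibble(comparison = rep("a", 2), year = 1:2, xi = c(1, 1 / 3))
  expect_equal(gra_degree(xi)$gamma, 2 / 3)
  # gamma stays in (0, 1] across random panels
  set.seed(14)
  for (i in 1:10) {
    panel <- make_panel(y = runif(5, 1, 9), a = runif(5, 1, 9), b = runif(5, 1, 9))
    res <- grey_relational(panel, "y")
    expect_true(all(res$summary$gamma > 0 & res$summary$gamma <= 1))
    expect_true(all(res$coefficients$xi > 0 & res$coefficients$xi <= 1))
  }
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 3), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_correlation(x, rep(2, 4)), class = "greycast_degenerate")
  # invariance under positive affine transforms of either argument
  set.seed(5)
  for (i in 1:10) {
    u <- runif(6); v <- runif(6)
    expect_equal(pearson_correlation(3.2 * u + 7, 0.4 * v - 2),
                 pearson_correlation(u, v), tolerance = 1e-12)
  }
})

test_that("composite coefficient is the exact convex blend", {
  expect_equal(round(composite_correlation(0.766539, 0.956225, 0.5), 6), 0.861382)
  expect_equal(composite_correlation(0.7, 0.9, blend = 1), 0.7)
  expect_equal(composite_correlation(0.7, 0.9, blend = 0), 0.9)
  # monotone in both arguments
  expect_gt(composite_correlation(0.8, 0.5), composite_correlation(0.7, 0.5))
  expect_gt(composite_correlation(0.8, 0.6), composite_correlation(0.8, 0.5))
  expect_error(composite_correlation(0.5, 0.5, blend = 1.2),
               class = "greycast_invalid_input")
})

test_that("full pipeline matches the brute-force oracle on small panels", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(3:5, 1)
    m <- sample(1:4, 1)
    y <- runif(n, 0.5, 10)
    xs <- replicate(m, runif(n, 0.5, 10), simplify = FALSE)
    names(xs) <- paste0("x", seq_len(m))
    rho <- runif(1, 0.1, 0.9)
    phi <- runif(1)
    panel <- tibble::tibble(year = seq_len(n), y = y, !!!xs)
    res <- grey_relational(panel, "y", resolution = rho, blend = phi)
    ora <- oracle_gra(y, xs, resolution = rho, blend = phi)
    expect_equal(res$summary$gamma, ora$gamma, tolerance = 1e-12)
    expect_equal(res$summary$epsilon, ora$epsilon, tolerance = 1e-12)
    expect_equal(res$summary$rho, ora$rho, tolerance = 1e-12)
    xi_wide <- tidyr::pivot_wider(res$coefficients, names_from = "year",
                                  values_from = "xi")
    expect_equal(unname(as.matrix(xi_wide[, -1])), unname(ora$xi),
                 tolerance = 1e-12)
  }
})

test_that("comprehensive index averages exactly three indicator rows", {
  block <- tibble::tibble(a = c(0.769856, 0.757859, 0.766227),
                          b = c(0.853095, 0.774943, 0.816935))
  idx <- comprehensive_index(block)
  expect_equal(round(idx$a, 6), 0.764647)
  expect_equal(round(idx$b, 6), 0.814991)
  same <- tibble::tibble(a = rep(0.5, 3))
  expect_equal(comprehensive_index(same)$a, 0.5)
  expect_error(comprehensive_index(block[1:2, ]),
               class = "greycast_invalid_input")
})

test_that("correlation table satisfies its internal identities", {
  panel <- generate_panel(seed = 19, n_references = 3)
  refs <- paste0("accident_index_", 1:3)
  tab <- correlation_table(panel, references = refs, blend = 0.5)
  expect_equal(nrow(tab), 12)
  expect_equal(unique(tab$block), c("gamma", "epsilon", "rho"))
  comp_cols <- setdiff(names(tab), c("block", "indicator"))
  expect_length(comp_cols, 5)
  for (blk in c("gamma", "epsilon", "rho")) {
    rows <- as.matrix(tab[tab$block == blk &
                            tab$indicator != "comprehensive_index", comp_cols])
    idx <- as.numeric(tab[tab$block == blk &
                            tab$indicator == "comprehensive_index", comp_cols])
    expect_equal(unname(colMeans(rows)), idx, tolerance = 1e-12)
  }
  g <- as.matrix(tab[tab$block == "gamma", comp_cols])
  e <- as.matrix(tab[tab$block == "epsilon", comp_cols])
  r <- as.matrix(tab[tab$block == "rho", comp_cols])
  expect_equal(r, 0.5 * g + 0.5 * e, tolerance = 1e-12)
})

test_that("a comparison identical to the reference scores 1 everywhere", {
  ref_spec <- synthetic_spec("accident_like", seed = 42)
  comps <- list(
    twin = ref_spec,
    econ = synthetic_spec("economy_like", seed = 43)
  )
  panel <- generate_panel(seed = 42, comparisons = comps,
                          reference_spec = ref_spec)
  res <- grey_relational(panel, "accident_index")
  twin <- res$summary[res$summary$comparison == "twin", ]
  expect_equal(twin$gamma, 1)
  expect_equal(twin$epsilon, 1)
  expect_equal(twin$rho, 1)
  other <- res$summary[res$summary$comparison == "econ", ]
  expect_lt(abs(other$epsilon), 1)
})
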