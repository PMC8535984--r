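---
title: "Grey forecasting and relational analysis with greycast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey forecasting and relational analysis with greycast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(greycast)
```

## The problem

Occupational-safety statistics — annual accident deaths, deaths per unit of
GDP, deaths per 100,000 workers — are short series: one value per year, two
decades of data at best, no replicates. Classical time-series machinery
(ARIMA, state-space models) is data-hungry and distributional; grey system
theory was designed for exactly this small-sample regime. `greycast`
implements the two tools of that tradition that practitioners combine when
studying how safety outcomes co-evolve with economic development:

1. **Grey forecasting**: the classical GM(1,1) model and a Gaussian-weighted
   variant, GGM(1,1), for fitting and extrapolating a single positive annual
   series.
2. **Grey relational analysis (GRA)**: a shape-similarity measure between a
   reference series (an accident indicator) and comparison series (economic
   indicators), blended with the Pearson correlation into a composite
   coefficient.

## The grey model

Let $x^{(0)} = (x^{(0)}(1), \dots, x^{(0)}(n))$ be the raw positive series,
$n \ge 4$. All grey models operate on the accumulated series
$x^{(1)}(k) = \sum_{i \le k} x^{(0)}(i)$ (the AGO), which smooths noise
before any parameter is estimated.

**Admissibility.** The order ratios
$\lambda(k) = x^{(0)}(k-1)/x^{(0)}(k)$ should lie in
$(e^{-2/(n+1)},\, e^{2/(n+1)})$. Ratios outside this band flag jumps too
abrupt for a smooth exponential-family trajectory. `order_ratio_test()`
reports the ratios, the band and the violating years. The check is
**advisory** in `grey_fit()` (a warning by default, configurable to an error
or to silence): real series are routinely fitted despite isolated
violations, and the packaged accident series itself violates the band at its
2015–2016 collapse. For inadmissible series `grey_fit()` offers optional
shift and log pre-transforms with automatic inversion of fitted values and
forecasts; both are off by default.

**GM(1,1).** The grey differential equation
$x^{(0)}(k) + a\,z^{(1)}(k) = b$ uses arithmetic-mean background values
$z^{(1)}(k) = \tfrac12\!\left(x^{(1)}(k) + x^{(1)}(k-1)\right)$. Stacking
$k = 2..n$ gives the linear system $Y = B\,(a, b)^\top$ with rows
$[-z^{(1)}(k),\, 1]$; $(a, b)$ is its least-squares solution (computed by QR,
which yields the same minimiser as $(B^\top B)^{-1} B^\top Y$). The whitened
solution $\hat x^{(1)}(k) = (x^{(0)}(1) - b/a)\,e^{-a(k-1)} + b/a$ is
differenced back to fitted values (`iago()`); fitted increments have exactly
constant ratio $e^{-a}$, so GM(1,1) can only describe monotone
quasi-exponential growth or decay.

**GGM(1,1).** Accident counts typically rise for a few years and then
decline — a shape GM(1,1) cannot express. The Gaussian variant replaces the
constant background weighting with time-dependent factors
$$z^{(1)}(k) = \tfrac12\!\left(\tfrac{k-\mu}{\sigma^2} x^{(1)}(k)
  + \tfrac{k-1-\mu}{\sigma^2} x^{(1)}(k-1)\right),$$
and the right-hand side of the grey equation becomes
$b\,(k - \tfrac12 - \mu)/\sigma^2$. The whitened solution is
Gaussian-exponential,
$$\hat x^{(1)}(k) = \left(x^{(0)}(1) - \tfrac{b}{a}\right) N\,
  e^{-a (k-\mu)^2 / (2\sigma^2)} + \tfrac{b}{a},$$
whose increments form a single-peaked, rise-then-fall sequence. The
standard form fixes $\mu = 0$, $\sigma = 1$; both are configurable.

**Anchoring (a design choice).** The normalising factor $N$ is not uniquely
pinned down by the derivation. `greycast` uses
$N = e^{+a(1-\mu)^2/(2\sigma^2)}$, so the trajectory passes exactly through
the first observation at $k = 1$ — the same anchoring convention every
GM(1,1) presentation uses. The un-anchored variant
($N = e^{-a(1-\mu)^2/(2\sigma^2)}$, which does not reproduce
$x^{(0)}(1)$ at $k=1$) is available via `anchor = FALSE` for comparison
with sources that print it; nothing else in the pipeline depends on the
switch.

**Error conventions (a design choice).** The textbook average relative
error divides by the observed value, and that is the package default.
Published grey-model fit tables, however, are frequently computed with the
*fitted* value in the denominator; `error_denominator = "fitted"` reproduces
that convention, and the packaged reference fit table is consistent with it
cell by cell. Signed errors are reported as
(fitted − observed)/denominator; summary statistics use absolute values.

## What the model can and cannot fit

On the packaged 21-year accident-death series, the GM(1,1) refit reproduces
the packaged reference predictions to better than $10^{-3}$ relative per
year, with maximum absolute relative error 0.28 — the number the
`fit gm` report prints. The same series defeats the *global* GGM(1,1): its
2015–2016 collapse (order ratio 1.54 against an upper band of 1.10) is a
kink that no smooth Gaussian-exponential trajectory can track, wherever
$(a, b, \mu, \sigma)$ are placed. The package fits the model honestly and
reports the resulting error; it does not attempt windowed, metabolic or
piecewise refits, which are out of scope. This is the documented reason the
Gaussian-model error-bound check in the acceptance suite does not pass on
this series: the bound presumes fitted values that the stated global model
cannot produce.

## Grey relational analysis

Given a reference series $y$ and comparisons $x_i$, $i = 1..m$, sharing $n$
years:

1. **Normalization.** Each series is divided by its own first element
   (`gra_normalize()`, `initial_value`), making series dimensionless and
   proportional series identical. A published variant that divides every
   column by the *first series* at each time point is available as
   `"as_printed"`; it depends on column order and is provided only for
   compatibility.
2. **Deviations.** $\Delta_i(k) = |y(k) - x_i(k)|$ on the normalized scale,
   with global extrema over all $i$ and $k$.
3. **Coefficients.** $\xi_i(k) = (\Delta_{\min} + \rho\,\Delta_{\max}) /
   (\Delta_i(k) + \rho\,\Delta_{\max})$ with resolution coefficient
   $\rho \in (0,1)$, default 0.5 (the universal GRA default; smaller
   $\rho$ spreads the coefficients, larger compresses them toward 1).
   If all series are identical ($\Delta_{\max} = 0$) the coefficients are
   defined as their limit 1, with a warning.
4. **Degree.** $\gamma_i = \tfrac1n \sum_k \xi_i(k)$, one number in
   $(0, 1]$ per comparison.
5. **Composite.** $\rho_i = \varphi\,\gamma_i + (1-\varphi)\,\varepsilon_i$,
   where $\varepsilon_i$ is the Pearson correlation (computed on the raw
   series — it is invariant to the normalization anyway) and
   $\varphi \in [0,1]$ weighs shape similarity against linear co-movement;
   default 0.5.

`correlation_table()` assembles the three blocks ($\gamma$, $\varepsilon$,
$\rho$) for several reference indicators against a shared comparison set and
appends to each block a *comprehensive index* row: the arithmetic mean of
the indicator rows. With three accident indicators this is the familiar
12-row layout. Two identities hold by construction and are re-verified at
run time by `run_gra()`: every comprehensive-index cell is the mean of its
block column, and every composite cell is the $\varphi$-blend of the
matching $\gamma$ and $\varepsilon$ cells.

## Synthetic data

Published economic indicator series often appear only as figures, so the
package generates structural stand-ins (`synthetic_spec()`,
`generate_series()`, `generate_panel()`):

* `economy_like` — geometric growth `first_value * growth^(k-1)` with
  multiplicative lognormal noise. Defaults: $n = 21$ (a two-decade annual
  window), growth 1.10/yr — the order of nominal growth of national
  economic aggregates over the 2000s and 2010s — and log-scale noise SD
  0.05, visually matching the smooth year-on-year growth of such series.
  The default panel uses five indicators with growth 1.06–1.14 so that
  research/education-like columns grow fastest and energy-like slowest.
* `accident_like` — increments of the anchored Gaussian-exponential
  trajectory plus the same noise. Defaults ($a = 0.03$,
  $b/a = 3.12\times10^6$, first value 120,000) put the increment peak near
  the first quarter of a 21-year window, echoing accident series that
  climbed until the early 2000s and declined afterwards.
* `grey_exact` — noise-free increments of the trajectory; refitting such a
  series must recover the development coefficient (the generate-and-refit
  tests allow 5% relative slack, since least squares on the discretized
  equation only approximates the continuous solution; the observed
  deviation is below 2% for $a \in [0.02, 0.1]$ at $n = 21$).

Noise is multiplicative lognormal because additive Gaussian noise can
produce negative counts; positivity is a hard invariant of every generator.
Each spec carries its own integer seed and draws in a locally scoped RNG
stream, so generation never perturbs the caller's random state and is
bit-reproducible.

What passing tests on synthetic panels do **not** show: real economic series
have serial correlation, common macroeconomic shocks and occasional level
shifts that the lognormal-around-trend generator does not emulate, so
relational coefficients on real panels should be interpreted with the usual
caution; the generator exists to exercise the arithmetic, not to simulate an
economy.

## Numerical choices and edge cases

* Least squares via QR; a rank-deficient design (e.g. a constant background
  column collinear with the classical intercept column) raises a
  `greycast_singular` error rather than returning an unstable solution.
* $a = 0$ makes $b/a$ undefined; prediction raises a
  `greycast_degenerate` error.
* Relative errors with a zero denominator name the offending year.
* Report rendering rounds predictions to 3 decimals and
  errors/coefficients to 6 (the precision conventional in published grey
  tables); all internal comparisons use full precision.
* Fits are deterministic: identical inputs give bit-identical results, and
  repeated CLI runs produce byte-identical files.

## Problem sizes

Everything the package computes is small: series of 21 years, panels of at
most a handful of comparisons, property tests on a few dozen random
instances. The test suite and the acceptance script each run in well under a
minute on a single CPU.

## Limitations

* Univariate only: no GM(1,N), no interval grey numbers, no
  rolling/metabolic refits.
* The global Gaussian trajectory cannot represent more than one
  rise-and-fall episode, and no setting of its four parameters tracks an
  abrupt single-year collapse (see above).
* GRA degrees depend on the normalization and on $\rho$; they are ordinal
  tools for ranking associations, not calibrated effect sizes.
* The absolute grey relational degree (a distinct GRA variant) is not
  implemented.
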