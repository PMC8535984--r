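# greycast

Grey forecasting and grey relational analysis for short, positive annual
indicator series — the kind occupational-safety and public-health analysts
work with: one value per year, twenty-odd years of data, no replicates.

Safety outcomes (accident deaths, deaths per unit of GDP, deaths per 100,000
workers) co-evolve with economic development (consumption, energy use,
education and research spending, wages). Two questions recur: *where is an
indicator heading*, and *which economic indicators move most closely with
it*? `greycast` answers both with the small-sample tools of grey system
theory, implemented tidyverse-style: every user-facing function takes a data
frame and returns a tibble, fitted objects support `tidy()`, `glance()`,
`augment()`, `predict()` and `autoplot()`.

## The models

**GM(1,1).** For a positive series $x^{(0)}(1..n)$, form the accumulated
series $x^{(1)}(k)=\sum_{i\le k}x^{(0)}(i)$ and fit the grey differential
equation $x^{(0)}(k) + a\,z^{(1)}(k) = b$, with background values
$z^{(1)}(k)=\tfrac12(x^{(1)}(k)+x^{(1)}(k-1))$, by least squares. The
whitened solution $\hat x^{(1)}(k) = (x^{(0)}(1)-b/a)e^{-a(k-1)} + b/a$ is
differenced back into fitted/forecast values. Fitted increments decay by a
constant factor $e^{-a}$: GM(1,1) describes monotone trends only.

**GGM(1,1).** A Gaussian-weighted variant for series that rise and then
fall. Background values are weighted by $(k-\mu)/\sigma^2$ and
$(k-1-\mu)/\sigma^2$, the equation's right side becomes
$b(k-\tfrac12-\mu)/\sigma^2$, and the solution is Gaussian-exponential:
$\hat x^{(1)}(k) = (x^{(0)}(1)-b/a)\,N\,e^{-a(k-\mu)^2/(2\sigma^2)} + b/a$,
anchored so $\hat x^{(1)}(1)=x^{(0)}(1)$. Its increments are single-peaked.
Standard form: $\mu=0$, $\sigma=1$.

**Grey relational analysis.** After initial-value normalization, deviations
$\Delta_i(k)=|y(k)-x_i(k)|$ from the reference become coefficients
$\xi_i(k)=(\Delta_{\min}+\rho\Delta_{\max})/(\Delta_i(k)+\rho\Delta_{\max})$
(resolution $\rho=0.5$), averaged over time into the grey relational degree
$\gamma_i\in(0,1]$. The composite coefficient blends it with the Pearson
correlation: $\rho_i=\varphi\gamma_i+(1-\varphi)\varepsilon_i$,
$\varphi=0.5$. `correlation_table()` assembles the familiar three-block
(γ / ε / ρ) table over several reference indicators, each block closed by a
comprehensive-index row (the mean of its indicator rows).

See the methods vignette (`vignettes/grey-forecasting.Rmd`) for the full
derivations, conventions and design decisions.

## Worked example

The package ships the 21-year accident-death series (China, 2000–2020) as a
fixture:

```r
library(greycast)

deaths <- grey_fixture("accident_deaths_2000_2020")
fit <- grey_fit(deaths, model = "gm", error_denominator = "fitted",
                order_ratio = "quiet")
fit
#> GM(1,1) fit to 21 annual observations (2000-2020)
#>   development coefficient a = 0.073470
#>   grey action quantity    b = 168409.698
#>   mean |relative error|     = 0.105358 (denominator: fitted)
#>   max  |relative error|     = 0.280389
#>   note: order-ratio screen violated at 2006, 2007, 2008, 2009, 2016, 2017, 2018, 2019
```

The development coefficient `a = 0.0735` says the fitted annual values decay
by `exp(-0.0735)` ≈ 7.1% per year; the maximum relative error 0.28 shows how
poorly a monotone model handles a series that first rises and then collapses
(the order-ratio note flags exactly those years). Per-year detail and
forecasts:

```r
head(format_fit_report(fit), 4)
#>    year true_value predicted_value relative_error
#> 1  2000     120351         120351          0
#> 2  2001     130491         153847.         0.152
#> 3  2002     139393         142949.         0.0249
#> 4  2003     137070         132823.        -0.0320

predict(fit, horizon = 3)
#>    year forecast
#> 1  2021   35394.
#> 2  2022   32887.
#> 3  2023   30558.
```

Relational analysis against a synthetic economic panel (five economy-like
comparison series; real economic series can be supplied as extra columns of
the same wide data frame):

```r
panel <- generate_panel(seed = 1)
grey_relational(panel, reference = "accident_index")
#> Grey relational analysis (reference: accident_index, rho = 0.5, phi = 0.5)
#> # A tibble: 5 × 4
#>   comparison           gamma epsilon      rho
#> 1 resident_consumption 0.799  -0.784  0.00729
#> 2 energy_consumption   0.845  -0.778  0.0331
#> 3 education_funds      0.749  -0.795 -0.0228
#> 4 wage_level           0.785  -0.788 -0.00172
#> 5 research_input       0.716  -0.793 -0.0384
```

Here every γ is high (all normalized series have broadly similar shapes) but
every Pearson ε is negative — rising economy, falling accidents — so the
composite ρ sits near zero: the two ingredients measure different things,
which is the point of blending them.

A command-line wrapper is installed with the package
(`system.file("cli", "greycast", package = "greycast")`) exposing
`fit`, `forecast`, `gra` and `simulate` subcommands over CSV files.

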