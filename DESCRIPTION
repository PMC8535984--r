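Package: greycast
Title: Grey Forecasting and Grey Relational Analysis for Small-Sample Annual Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits the classical grey forecasting model GM(1,1) and its
    Gaussian-weighted variant GGM(1,1) to short annual indicator series
    (counts or rates), with order-ratio admissibility screening, accumulated
    generating transforms, least-squares parameter estimation, forecasting,
    and relative-error diagnostics. Also implements grey relational analysis
    between a reference series and comparison series, the Pearson correlation,
    and a blended composite correlation coefficient, with table-style report
    assembly. Includes a packaged 21-year occupational accident-death series,
    seeded synthetic-series generators for economy-like and accident-like
    indicators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
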