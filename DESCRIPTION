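Package: lakecs
Title: Fractional-Diffusion Modelling of Radiocesium Decline in Closed Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and predicting the long-term decline of
    caesium-137 activity concentration in closed lakes and their fish. Provides
    numerically robust evaluation of the one-parameter Mittag-Leffler function
    on the negative real axis (truncated power series, Gorenflo integral
    representation, and power-law tail asymptotics), forward prediction models
    (fractional-diffusion, one- and two-component exponential decay, and the
    Bulgakov sediment-diffusion model), relative-error Levenberg-Marquardt
    fitting with blind-test backtesting and long-horizon prediction, a
    continuous-time random-walk Monte-Carlo simulator validating the
    subdiffusive premise, and a synthetic concentration-series generator with
    multiplicative lognormal noise. Results are returned as tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot() support.
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
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
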