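Package: sccsutva
Title: Sufficient Component Cause Models for Exploring SUTVA Violations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Declarative sufficient component cause ("causal pie") models for
    binary outcomes, with tools to derive the potential outcomes and response
    types they imply, classify individuals as doomed, causal, preventive or
    immune, and quantify how the population causal effect (risk difference)
    depends on unrepresented versions of treatment and on interference between
    units -- the two facets of the stable unit treatment value assumption
    (SUTVA). Includes a seeded Monte Carlo engine that runs idealized
    randomized trials on synthetic populations, an exchangeability diagnostic,
    mixture decompositions of observed effects over version and interference
    strata, packaged example models, and a small command-line interface.
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
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
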