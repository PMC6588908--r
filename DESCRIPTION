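Package: plymod
Title: Static Microsimulation of Productive Life Years Lost to Ischemic
    Heart Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A static microsimulation pipeline projecting the indirect
    costs of ischemic heart disease (IHD) among older workers (45-64
    years) out to 2030: lost personal income, extra welfare payments,
    lost income-tax revenue and lost GDP arising from people who are out
    of the labour force because of their own ill-health with an IHD main
    condition.  Includes a synthetic-population generator emulating the
    survey base file and the economic donor pool, hot-deck synthetic
    matching of weekly income/welfare/tax, GREGWT-style calibration of
    survey weights to population and employment benchmarks, chronic
    disease prevalence trend adjustment, real-terms uprating, matched
    counterfactual Monte Carlo simulation with percentile confidence
    intervals, and national cost aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    MASS,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
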