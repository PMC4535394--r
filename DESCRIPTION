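Package: simon2stage
Title: Exact Inference for Simon Two-Stage Trials with Deviated Second-Stage
    Sample Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact small-sample inference for single-arm phase II trials run
    under Simon's two-stage design when the realised second-stage sample size
    differs (non-informatively) from the planned one. Provides the conditional
    likelihood UMVUE of the response rate, likelihood-ratio-ordered mid-p
    values and acceptance-region confidence intervals, the Koyama-Chen
    conditional method for comparison, exact operating characteristics and
    design search, and a Monte Carlo study of confidence-interval width,
    coverage, power and bias under random second-stage deviations. Results are
    returned as tibbles so analyses compose with the pipe.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
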