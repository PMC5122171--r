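Package: epvsim
Title: Monte Carlo Evaluation of Logistic Regression at Low Events per Variable
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying the small-sample behaviour of
    binary logistic regression when the number of events per estimated
    coefficient (EPV) is low. Provides quota sampling of datasets with exactly
    fixed sample size and event count, maximum-likelihood and Firth
    penalized-likelihood estimation with Wald and profile penalized-likelihood
    confidence intervals, four separation diagnostics (a re-estimation tracing
    detector, a coefficient-threshold rule, likelihood non-convergence, and an
    exact linear-programming classifier of complete and quasi-complete
    separation), per-scenario accuracy summaries (bias, relative bias,
    coverage, interval width, mean square error), and orchestration of
    factorial simulation studies with configurable policies for handling
    separated datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
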