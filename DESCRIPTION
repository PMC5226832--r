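Package: screensleep
Title: Bayesian Switchpoint Inference of Sleep Patterns from Smartphone
    Screen Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-day sleep and wake times from counts of smartphone
    screen-on or app-launch events using hierarchical Bayesian Poisson
    switchpoint models.  Five model variants of increasing complexity
    (pooled to fully hierarchical) are fitted by Markov chain Monte Carlo,
    compared by the deviance information criterion, and turned into
    per-day sleep matrices, posterior sleep-probability curves, sleep
    duration and mid-sleep summaries, and cohort-level aggregates.
    Includes an exact-enumeration posterior oracle for the pooled model,
    a rule-based longest-gap baseline, evaluation against wearable
    sleep-tracker ground truth, and a synthetic event-stream generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
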