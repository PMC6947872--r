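Package: seqbayes
Title: Bayesian and Frequentist Group-Sequential Trial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and comparison of group-sequential stopping rules
    for clinical trials with normally distributed test statistics and for
    single-arm binary endpoints. Computes first-crossing (stopping)
    probabilities by Armitage-type recursive numerical integration, builds
    Pocock, O'Brien-Fleming and alpha-spending frequentist designs, calibrates
    Bayesian posterior-probability stopping rules with conjugate normal or
    beta priors to a target frequentist type I error, maps Bayesian and
    frequentist designs onto each other exactly in the one-parameter case,
    and profiles the type I error of two-arm designs with independent
    per-arm priors, where exact error control off a reference control mean
    is impossible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
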