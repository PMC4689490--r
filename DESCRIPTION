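Package: epiburden
Title: Burden-of-Disease Estimation with an Illness-Death Consistency Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the disability-adjusted life-year (DALY)
    burden of a chronic condition from stratified surveillance data. Fits a
    three-state illness-death model (well, diseased, dead, with remission) so
    that observed incidence, prevalence, remission and cause-specific
    mortality are internally consistent; computes years lived with disability
    by both the prevalence- and incidence-based approaches, years of life
    lost against a standard life table, and assembles DALYs with
    disability-weight sensitivity analysis, Monte-Carlo parameter
    uncertainty and bootstrap uncertainty intervals. Includes a synthetic
    cohort generator emulating health-and-demographic-surveillance data for
    validation, and packaged stratum-level fixtures from a rural South
    African epilepsy surveillance site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
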