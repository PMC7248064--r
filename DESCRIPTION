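Package: mafd
Title: Minimum Adult Frog Density Estimation from Calling-Male Surveys
Version: 0.1.0
Authors@R:
    person("Survey", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts counts of vocalising male anurans from large-scale
    audial surveys into minimum adult population density (MAFD) and
    range-wide minimum population size. Implements the category-stratified
    calling-male density estimator Dc, its conversion to adult density via
    published vocalisation, presence and sex-ratio parameters (Ma, Mp, Ms),
    survey-quality metrics (waterbody detection probability, inter-year
    breeding-site fidelity, contribution of the most productive survey),
    a visual-observation correction yielding the fraction of the population
    covered by acoustic estimates, Monte-Carlo propagation of parameter
    uncertainty onto national population totals, and a synthetic survey
    generator with known truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
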