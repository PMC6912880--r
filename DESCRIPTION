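Package: resurvey
Title: Long-Term Vegetation Resurvey Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term vegetation resurvey data from
    paired historical and modern community surveys. Implements
    abundance-based temporal turnover (Morisita-Horn dissimilarity),
    effective species numbers (Hill order 2), multiple-assemblage beta
    diversity with bootstrap uncertainty, cover-weighted Grime CSR strategy
    proportions, growing-season detection and thermal-sum trends from daily
    climate series, and a Bayesian regression layer (Gibbs sampling,
    PSIS-LOO model comparison, Bayesian R-squared). Includes a synthetic
    paired-survey generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
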