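Package: fracepi
Title: Fracture Epidemiology, Burden Projection and Competing-Risk
    Fracture Probability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-based osteoporotic fracture epidemiology:
    ingestion and deduplication of line-listed low-energy fracture records,
    age- and sex-specific incidence with exact Poisson (Garwood) confidence
    intervals, imputation of non-hip fracture rates from a reference
    population's site-to-hip ratios, calendar-year burden projections under
    stable or drifting rates, and a competing-mortality life-table engine for
    10-year and remaining-lifetime fracture probabilities of the kind used to
    calibrate country-specific fracture-risk models. Includes a synthetic-data
    generator with known ground truth for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
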