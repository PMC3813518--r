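Package: mmtrends
Title: Robust Abundance Trend Assessment for Marine Mammal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assesses recovery in wildlife populations from heterogeneous
    abundance time series. Provides confidence-weighted high-breakdown
    robust regression (MM-type, bisquare) of linear and log-linear trends
    over the three most recent generations, a four-way trend
    classification (significantly increasing, significantly decreasing,
    non-significant, unknown), selection of non-nested population sets,
    taxon and habitat group summaries, species-level aggregation for
    comparison with external trend assessments, and historical-decline
    versus recent-recovery statistics. Includes a synthetic abundance
    data generator with known growth rates, depletion-recovery histories,
    irregular survey intervals, rank-dependent lognormal observation
    error and nested populations, so every stage of the pipeline can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
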