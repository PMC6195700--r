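Package: lotterymb
Title: Competitive Lottery Statistics for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects competitive-lottery ("winner-take-all") assembly in
    microbial community profiles. Given a feature-by-sample abundance table
    with taxonomic lineages, the package computes winner prevalence and
    normalized winner diversity for every taxonomic group at every rank,
    classifies groups as lottery-like, fixed-winner or non-lottery,
    detects longitudinal winner turnover within hosts, compares lottery
    parameters across datasets, and contrasts genome gene content between
    lottery-like and non-lottery-like groups. A synthetic-data module
    generates communities under a two-step assembly model (group
    allocation, then within-group schema) with stick-breaking abundance
    nulls and Poisson read-sampling noise, so the whole pipeline can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
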