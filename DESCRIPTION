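Package: soilecotox
Title: Soil Microbial and Enzymatic Ecotoxicology of Fungicide-Treated Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Indices and dose-response statistics for assessing the impact of
    pesticide contamination on soil biology. Implements the colony development
    (CD) and ecophysiological (EP) biodiversity indices for culturable
    microorganisms, the Orwin-Wardle resistance (RS) and resilience (RL)
    indices for soil enzyme activities, a shared first-order dissipation model
    for predicted environmental concentrations (PEC) with DT50 estimation,
    and the supporting assessment statistics: dose correlation with
    significance flags, two-way eta-squared variance partitioning, compact
    letter displays for Tukey's range test, Ward clustering of response
    profiles and PCA of resistance matrices. Ships tidy transcriptions of a
    published azoxystrobin soil-contamination experiment as fixtures, a
    seeded synthetic-experiment generator with ground-truth parameter
    recovery, and table-reproduction reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
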