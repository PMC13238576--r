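Package: heatwavecc
Title: Excess Heat Factor Heatwaves and Space-Time-Stratified Case-Crossover
    Analysis of Daily Health Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects heatwaves from daily climate series using the Excess
    Heat Factor (EHF), in a temperature-only variant and a heat-index variant
    that folds in relative humidity, classifies heatwave days into
    low/severe/extreme severity tiers against a reference-period climatology,
    and estimates heatwave effects on daily emergency department presentation
    counts with a space-time-stratified case-crossover design fitted by
    conditional quasi-Poisson regression. Includes climate-field ingestion
    and zonal aggregation, ICD-10-AM condition grouping, descriptive and
    trend reporting, and a synthetic-data generator emulating the structure
    of the restricted source data so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
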