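Package: hf183monitor
Title: HF183 Human Fecal Marker Monitoring and Site Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for qPCR-based monitoring of the HF183
    human-associated fecal Bacteroides marker in coastal drainages.
    Fits per-laboratory master standard curves with studentized-residual
    outlier removal and derives limits of detection and quantification,
    converts quantification cycles to concentrations with Poisson-model
    substitution of censored replicates, classifies samples into wet- and
    dry-weather strata from rain-gauge records, computes per-site detection
    frequencies under seven positivity definitions together with
    geometric-mean concentrations and Enterococcus exceedance metrics, and
    ranks sites by the extent of human fecal contamination with Spearman
    rank-concordance diagnostics. Includes a seeded generator of complete
    synthetic monitoring campaigns (plates, metadata, rain series) for
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
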