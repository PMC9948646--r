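Package: bilayerscreen
Title: Gramicidin-Based Screening for Bilayer-Modifying Potency and
    Likely Cytotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytics for gramicidin-based fluorescence-quench screens of
    bilayer-modifying potency. Models and fits Tl+-induced quench of
    ANTS-loaded large unilamellar vesicles (Stern-Volmer quenching with a
    modified stretched-exponential influx time course), extracts initial
    quench rates with quality control, converts rates into normalized
    potency (NormRate), bilayer free-energy shifts, and membrane/aqueous
    drug concentrations, and provides the cohort statistics that link
    bilayer-modifying potency to HepG2 cytotoxicity (contingency-table
    odds ratios with Woolf intervals, probability-versus-bin curves,
    Mann-Whitney comparisons, box-plot summaries, and silhouette cluster
    diagnostics). Includes a synthetic-data generator for dispersed
    vesicle populations, stopped-flow traces, and drug-library tables so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
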