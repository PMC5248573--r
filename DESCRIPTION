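Package: celladapt
Title: Single-Cell Fate Calling and Drug-Adaptation Analytics for
    BRAF-Mutant Melanoma Imaging Data
Version: 0.1.0
Authors@R:
    person("Morgan", "Carver", email = "mcarver@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying adaptive resistance of BRAF-mutant
    melanoma cells to RAF/MEK inhibition from live-cell imaging and
    plate-based assays. Includes seeded synthetic-data generators for
    geminin reporter traces, endpoint viability plates, two-line
    expression tables, compound-screen plates and biopsy-like per-cell
    marker tables; per-cell trace analysis (moving-average smoothing,
    S/G2 phase calling, division/death event detection, minimum doubling
    time, fate classification into dead/arrested/adapted); cohort fate
    statistics and growth curves; pharmacology (apoptosis scoring,
    relative viability, growth-rate-inhibition values, Hill dose-response
    fits, sequential-dosing summaries); cross-cell-line differential
    expression filtering, Chebyshev clustering preparation, z-scored
    marker landscapes and AUC-based marker correlation; and screen hit
    selection plus per-cell marker gating with background exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
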