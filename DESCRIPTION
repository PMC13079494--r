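Package: pfastrace
Title: Targeted PFAS Quantification and Wastewater Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for targeted multi-residue per- and
    polyfluoroalkyl substance (PFAS) monitoring in influent wastewater by
    LC-MS/MS multiple reaction monitoring. Covers internal-standard
    calibration and back-calculation, signal-to-noise based instrumental
    and method limits (IDL/IQL, MDL/MQL), validation metrics (accuracy,
    precision, recovery) with quantification-status classification,
    wastewater-based-epidemiology daily and population-normalised loads
    with left-censored (<LOD/<LOQ) handling, and environmental risk
    quotients against freshwater PNECs. Includes a synthetic
    measurement-campaign generator with known ground truth so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
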