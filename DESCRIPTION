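Package: cddpflux
Title: Isotope Tracing, DNA-Damage Scoring and Platinum Quantitation for
    Cisplatin Oxidative-Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for in vitro cisplatin oxidative-stress studies in
    tumour cells: mass isotopomer distribution (MID) estimation from targeted
    MS isotopologue intensities with natural-abundance correction and
    per-isotopologue condition contrasts; single-cell gamma-H2AX scoring
    (watershed nucleus segmentation, control-derived positivity threshold,
    local-maxima foci counting); internal-standard ICP-MS platinum calibration
    with 1/x^2 weighting and DNA-bound fraction quantitation; and endpoint
    arithmetic for clonogenic, senescence, redox and plate-reader assays.
    Includes seeded synthetic-data generators with ground truth for every
    input, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    pracma,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
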