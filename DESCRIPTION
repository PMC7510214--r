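Package: smnscreen
Title: Two-Tier Melt-Curve and MLPA Screening Simulation for Spinal
    Muscular Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a two-tiered newborn-screening workflow
    for spinal muscular atrophy (SMA) on dried blood spots. The first tier
    classifies probe melt-curve profiles carrying SMN1 (63 C), SMN2 (56 C)
    and DNA-quantity (49 C) transitions via Savitzky-Golay derivative peak
    calling, plate-level control QC (blanks, SD074 threshold DNA, SD075
    positive DNA) and a ratio-based referral rule that deliberately masks
    carriers; the second tier confirms referrals and determines integer
    SMN1/SMN2 exon-7 copy numbers from MLPA probe heights by median
    reference-probe normalization. A seeded synthetic-data generator
    emulates screening cohorts, 96-well plates, melt curves and MLPA
    profiles so the whole decision procedure can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
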