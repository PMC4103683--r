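Package: spicula
Title: Ratiometric Calcium Imaging and Mating-Behavior Analysis for C. elegans Males
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying male Caenorhabditis elegans copulation and
    ejaculation. Converts dual-channel (G-CaMP/mDsRed) region-of-interest
    fluorescence series into photobleach-corrected ratiometric percent dF/F0
    traces, extracts event-aligned calcium transient kinetics (onset, peak
    latency, rise and post-peak slopes, biphasic second rises), scores mating
    ethograms (refractory period, sperm-transfer ranking, insertion and vulva
    metrics, potency), and provides exact small-sample statistics (two-sided
    Fisher test by hypergeometric enumeration, exact Mann-Whitney, paired t,
    one-way ANOVA with Newman-Keuls or Bonferroni multiple comparisons).
    Includes a synthetic dual-channel bout and mating-trial generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
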