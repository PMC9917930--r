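Package: cortidecay
Title: Temporal Decay of Glucocorticoid-Responsive Transcription on Two-Color Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal transcriptomic responses to
    overnight corticosterone measured on two-color microarrays sampled at
    three times of the resting (light) phase. Provides a synthetic-data
    generator with planted temporal expression patterns, normexp background
    correction and loess/quantile normalization, separate-channel linear
    modelling with intra-spot correlation and empirical-Bayes variance
    moderation, Benjamini-Hochberg FDR control, classification of probes
    into temporal decay categories (long-lasting, intermediate,
    short-lasting, reversal, secondary) with fold-change magnitude bins and
    a low-intensity filter, consensus probe annotation from two sources
    with synonym resolution, qPCR validation computations (dilution-series
    amplification efficiency, Pfaffl relative quantification, platform
    correlation), overlap reports against referential gene lists, and the
    classical statistics used alongside (Mann-Whitney normal approximation,
    variance-homogeneity battery with a square-root-transform decision
    rule, two-way ANOVA with Fisher LSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    car,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
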