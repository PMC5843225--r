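Package: ooadrift
Title: Allele-Frequency Clines Along the Out-of-Africa Expansion with
    Genetic-Drift-Aware Regression and 4C-seq Contact Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to test whether allele frequencies at a locus track
    cumulative human migratory distance from Africa once the correlation
    induced by shared genetic drift is accounted for. Implements the
    arcsine-square-root transform of allelic proportions, generalized
    least squares by maximum likelihood with a drift pseudo-correlation
    matrix derived from microsatellite genetic distances, AIC model
    search over marker interactions, and an empirical inflation-factor
    multiple-testing correction calibrated on null markers. Companion
    modules cover Hardy-Weinberg tests, two-locus EM haplotype
    estimation and linkage disequilibrium, a 4C-seq fragment-end
    processing pipeline (in silico digestion, filtering, smoothing,
    normalization, contact asymmetry), allele-specific 3C delta-Ct
    quantification, and synthetic-data generators for all of the above.
    Ships a per-population table of migratory distances and SIRPB1-region
    SNP frequencies as a worked example.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
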