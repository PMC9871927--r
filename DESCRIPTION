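Package: degeneR
Title: Serial-Passage Degeneration Dynamics, Pooled-Sequencing Variant
    Filtering and Fitness Statistics for Solventogenic Clostridia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying strain degeneration of solventogenic
    clostridia under serial subculture. Provides a stochastic Wright-Fisher
    serial-passage simulator with sporulation, heat-shock and extended-transfer
    bottlenecks and mutation spawning; a synthetic ultra-deep pooled-sequencing
    pileup generator with orientation strata; a variant-filtering cascade
    (dual-criterion consensus scoring, per-orientation allele-frequency
    filter, multiallelic splitting and trajectory-level recurrence, starter
    background, rRNA-exclusion and depth-artifact rules); mutation-spectrum
    and hotspot-enrichment statistics; and relative-fitness and
    frequency-dependence analyses, together with VCF/BED/GFF3/TSV readers and
    writers and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
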