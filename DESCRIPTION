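Package: coreader
Title: Dual m6A Reader Binding Analysis with ADAR-Corrected Differential
    Editing, iCLIP Site Definition and Sequence Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for establishing facilitated m6A reading by
    pairs of RNA-binding proteins. Implements HyperTRIBE-style differential
    RNA-editing detection with mutation-type, replicate-agreement and
    effect-size filters; a Bayesian hierarchical binomial model that corrects
    differential editing between genetic backgrounds for unequal ADAR
    expression, with random-effect contrasts, Z-scores and FDR control; the
    post-peak-calling iCLIP binding-site cascade (summit merging, 9-nt site
    definition, artifact removal, quantile reproducibility filtering, control
    subtraction, target assignment); convolutional sequence models for m6A
    site curation, position refinement and dual-reader binding prediction
    with first-layer filter-to-PWM de novo motif extraction and GLM-based
    protein-specific motif scoring; and site-geometry statistics
    (feature-matched backgrounds, distance and metagene profiles,
    expression-matched permutation overlap tests, single-cell Fisher
    co-expression). A self-consistent synthetic-data generator with known
    ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Matrix,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
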