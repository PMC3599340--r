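Package: rnasomatic
Title: Somatic Variant Screening from Paired Tumor/Normal RNA-Seq Callsets
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening somatic variants from RNA-Seq derived
    variant calls in paired tumor/normal designs. Implements a six-stage
    filter cascade (variant quality, an empirically trained per-sample
    coverage ceiling, paired-coverage support, known-variant subtraction,
    shared-call subtraction, and a local mismatch-cluster filter),
    mutation-spectrum and transition/transversion characterization with
    exact contingency and rank-sum tests, coding-consequence
    classification of disruptive variants from gene models, cross-sample
    recurrence summaries, gene ontology enrichment by hypergeometric
    test with true-path annotation propagation, and a fully
    deterministic synthetic-data generator producing paired callsets
    with ground-truth labels for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
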