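Package: svbenchr
Title: Benchmarking and Integration of Structural Variant Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking structural variant (SV) call sets from
    long-read sequencing pipelines and for integrating calls across
    pipelines. Call sets are normalized into a canonical record model
    (deletions and insertions, 0-based half-open coordinates), evaluated
    against truth sets with reciprocal-overlap matching for deletions and
    window matching for insertions, and summarized as precision, recall and
    F1 overall, per size bin, and after repeat-region filtering. Call sets
    from multiple pipelines can be merged into a consensus set filtered by
    supporting-pipeline count, or integrated with a random-forest classifier
    trained on caller-reported VCF INFO features. A built-in simulator
    implants deletions and insertions into a reference sequence, emits the
    matching truth set, and corrupts it into noisy pipeline-like call sets
    with caller-dependent feature availability, so the whole workflow can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    withr,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
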