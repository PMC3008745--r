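Package: somaticExome
Title: Somatic Variant Discovery for Tumor/Normal Exome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a tumor/normal exome
    somatic-mutation discovery workflow: high-confidence substitution
    calling from per-site pileups, bimodal somatic/germline
    classification against matched normal tissue, transcript-model
    consequence annotation, a multi-stage prioritization cascade
    (population frequency, damaging predictions, conservation,
    expression, gene categories), read-depth copy-number segmentation
    with a two-standard-deviation calling rule, and sequencing-versus-
    array genotype concordance. Ships a seeded synthetic-data generator
    that emulates tumor/normal pileups under binomial read sampling with
    known truth, so every stage is exercised end-to-end with
    microsatellite-instable (hypermutated) and microsatellite-stable
    presets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
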