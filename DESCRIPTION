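Package: splicedef
Title: Exon-Definition Splicing Prediction and Variant Effect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts internal exon isoforms in pre-mRNA sequences under the
    exon definition model and classifies splicing changes induced by sequence
    variants. Implements trainable Bayesian oligonucleotide sensors for
    canonical acceptor and donor splice sites and for the non-canonical 5'GC
    donor, positional log-odds (LOD) profiles for exonic/intronic splicing
    enhancers and silencers, a splice-site-strength-conditioned Beta-mixture
    model of exon length fit by expectation maximization, a combined
    exon-definition LOD score, a variant-effect engine with a seven-class
    splicing-event taxonomy, sensitivity/specificity evaluation over exon
    boundaries, and a synthetic corpus generator providing ground truth for
    every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
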