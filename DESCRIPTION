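Package: maizeMQTL
Title: Meta-QTL Analysis of Maize Grain Drying Rate and Grain Water Content
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete meta-QTL (MQTL) inference pipeline for quantitative
    trait loci governing maize grain drying rate (GDR) and grain water
    content (GWC). Published QTLs from heterogeneous linkage-mapping
    experiments are placed on a single consensus genetic map (confidence
    intervals imputed from population size and R-squared where missing,
    order-conflicting markers resolved by longest increasing subsequence,
    positions projected homothetically through shared markers), then
    clustered per linkage group with a variance-weighted one-dimensional
    Gaussian mixture whose component number is selected by AIC over K = 1-10.
    Consensus loci supported by two or more independent experiments are
    anchored to physical coordinates by linear interpolation between
    marker anchors, candidate genes are extracted from a GFF3 annotation,
    and gene sets are characterised by hypergeometric GO enrichment and
    max-normalised FPKM expression-window classification. A deterministic
    synthetic-data generator with full ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, QTL, GenomeAnnotation, GeneExpression
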