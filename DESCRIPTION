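Package: methSurvTF
Title: Transcription Factor Motif Enrichment in Survival-Associated DNA
    Methylation Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers transcription factors associated with clinical outcome
    from array-style DNA methylation data. Provides per-CpG differential
    methylation and univariate Cox proportional-hazards survival screens,
    construction of 102-bp genomic windows around significant CpGs with
    greedy removal of overlapping windows, position weight matrix scanning
    with exact p-value score thresholds, Fisher's exact motif enrichment
    with relative-enrichment scores and Benjamini-Hochberg correction,
    k-means clustering of CpG beta-value profiles, and first-neighbour
    TF-TF interaction subnetworks. A synthetic-data generator emulates the
    full input bundle (genome, CpG annotation, beta matrix, clinical table,
    motif set, TF edge list) with planted ground truth so that every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    survival,
    igraph,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Survival, MotifAnnotation, Epigenetics,
    Transcription, NetworkInference
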