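Package: binsplice
Title: Differential Exon and 3' UTR Usage from Annotation-Derived Counting Bins
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differential exon usage and alternative-polyadenylation
    driven changes in 3' UTR length from RNA-seq data. Gene annotations are
    flattened into disjoint counting bins, 3' UTR bins are further segmented
    and extended using annotated poly(A) sites, aligned reads are counted per
    bin, and bin usage is tested with a moderated t-statistic comparing each
    bin's log fold change to the precision-weighted average of the other bins
    of its gene. Both the classical diffSplice statistic and an improved
    variant with bin-level empirical-Bayes variance shrinkage are provided,
    with Simes aggregation to gene-level p-values, UTR-restricted gene
    results, gene-level effect-size scores, and a count-level simulator of
    differential 3' UTR usage for benchmarking.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    limma,
    edgeR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialSplicing, AlternativePolyadenylation,
    GeneExpression, Transcriptomics
RoxygenNote: 7.3.3
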