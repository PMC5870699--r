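Package: miRPeaks
Title: Entropy-Based Prediction of MicroRNA Loci from Small RNA
    Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts plant and animal microRNA loci from genome-mapped
    small RNA sequencing reads. Candidate loci are detected as abundance
    peaks using an absolute-log Kullback-Leibler divergence against a
    uniform background, filtered on read-alignment patterns
    (repetitiveness, size-class distribution, precise Drosha/Dicer
    excision), and confirmed by folding the surrounding sequence into a
    hairpin precursor selected by adjusted minimum free energy. Includes
    a dinucleotide-shuffle structure p-value, a log-odds prediction
    score, wild-type versus biogenesis-mutant fold-change validation,
    and a deterministic simulator of genomes with implanted hairpin
    loci for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SmallRNA, Transcriptomics, SequenceMatching,
    StructuralPrediction
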