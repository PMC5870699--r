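#' Quantify loci across read sets
#'
#' Sums, per locus and sample, the abundance of same-strand mapped reads
#' overlapping the locus span. Library size is the total genome-mapped
#' abundance of the sample (multi-placement reads counted once via their
#' unique sequence).
#'
#' @param loci GRanges of loci (e.g. [matureLoci()] of a prediction set,
#'   or control loci).
#' @param readSets named list of mapped-read GRanges (see [mapReads()]).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (raw abundance) and `librarySize` in `colData`.
#' @export
quantifyLoci <- function(loci, readSets) {
  stopifnot(length(readSets) >= 1, !is.null(names(readSets)))
  counts <- sapply(readSets, function(reads) {
    if (length(reads) == 0L) return(numeric(length(loci)))
    hits <- findOverlaps(loci, reads, minoverlap = 1L)
    ab <- mcols(reads)$abundance[subjectHits(hits)]
    out <- numeric(length(loci))
    if (length(hits)) {
      agg <- tapply(ab, queryHits(hits), sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  })
  counts <- matrix(counts, nrow = length(loci),
                   dimnames = list(NULL, names(readSets)))
  libSizes <- vapply(readSets, function(reads) {
    if (length(reads) == 0L) return(0)
    uniq <- !duplicated(mcols(reads)$sequence)
    sum(mcols(reads)$abundance[uniq])
  }, numeric(1))
  SummarizedExperiment(
    assays = list(counts = counts), rowRanges = loci,
    colData = DataFrame(librarySize = libSizes, row.names = names(readSets)))
}

#' Median-scaled reads-per-million normalization
#'
#' Rescales each sample's abundances by its genome-mapped library size,
#' to the median library size of the experiment:
#' value' = value / librarySize * median(librarySizes). Samples of equal
#' depth are left unchanged, and the transform is idempotent once
#' library sizes are recomputed from the normalized data.
#'
#' @param x a SummarizedExperiment from [quantifyLoci()], or a numeric
#'   matrix.
#' @param librarySizes per-sample totals (required for the matrix
#'   method; taken from `colData` otherwise).
#' @return Same shape as the input, with a `normalized` assay added (SE)
#'   or the normalized matrix.
#' @export
normalizeRpmMedian <- function(x, librarySizes = NULL) {
  if (is(x, "SummarizedExperiment")) {
    libs <- colData(x)$librarySize
    if (any(libs <= 0)) stop("zero library size")
    norm <- sweep(assay(x, "counts"), 2L, libs, "/") * median(libs)
    assays(x)$normalized <- norm
    return(x)
  }
  if (is.null(librarySizes)) stop("librarySizes required for matrix input")
  if (any(librarySizes <= 0)) stop("zero library size")
  sweep(x, 2L, librarySizes, "/") * median(librarySizes)
}

#' Log2 fold change with pseudo-count
#'
#' log2((wt + pseudo) / (mut + pseudo)); positive values mean
#' downregulation in the mutant. The pseudo-count keeps zero-count loci
#' finite.
#'
#' @param wt,mut normalized abundances (vectors of equal length).
#' @param pseudo pseudo-count in normalized units (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(wt, mut, pseudo = 1) {
  stopifnot(all(wt >= 0), all(mut >= 0))
  log2((wt + pseudo) / (mut + pseudo))
}

#' Fraction of loci downregulated in the mutant
#'
#' A locus is called downregulated when its normalized expression is at
#' least 2-fold lower in the mutant, i.e. log2 fold change >= 1
#' (boundary inclusive). Also returns the sorted fold-change vector for
#' cumulative plotting.
#'
#' @param wt,mut normalized abundance vectors over the same loci.
#' @param pseudo pseudo-count for [log2FoldChange()].
#' @return list(fraction, lfc, sortedLfc).
#' @export
downregulatedFraction <- function(wt, mut, pseudo = 1) {
  if (length(wt) == 0L) stop("empty locus set")
  lfc <- log2FoldChange(wt, mut, pseudo)
  list(fraction = mean(lfc >= 1), lfc = lfc, sortedLfc = sort(lfc))
}

#' Evaluate predictions against a miRNA annotation
#'
#' A prediction matches the annotation when its mature span overlaps an
#' annotated mature miRNA on the same strand by at least 1 nt.
#' Specificity is the percentage of predictions that match (NA with zero
#' predictions). Sensitivity is the percentage of *expressed* annotated
#' miRNAs that were detected, where a precursor is expressed when at
#' least one mapped read is incident to it.
#'
#' @param predictions a [MirnaPredictions-class] object or mature
#'   GRanges.
#' @param annotation GRanges from [readMirnaAnnotation()].
#' @param mappedReads GRanges of all mapped reads of the sample.
#' @return list(specificity, sensitivity, nHighConfidence,
#'   nLowConfidence, nNovel, nExpressed, nDetected).
#' @export
evaluateAgainstAnnotation <- function(predictions, annotation,
                                      mappedReads) {
  mature <- if (is(predictions, "MirnaPredictions"))
    matureLoci(predictions) else predictions
  annMature <- annotation[annotation$type == "miRNA"]
  annPrec <- annotation[annotation$type == "miRNA_primary_transcript"]
  if (length(annPrec) == 0L) annPrec <- annMature
  matched <- countOverlaps(mature, annMature, minoverlap = 1L) > 0
  specificity <- if (length(mature) == 0L) NA_real_
                 else 100 * sum(matched) / length(mature)
  expressed <- countOverlaps(annPrec, mappedReads, minoverlap = 1L,
                             ignore.strand = FALSE) > 0
  detected <- expressed & countOverlaps(annPrec, mature,
                                        minoverlap = 1L) > 0
  sensitivity <- if (sum(expressed) == 0L) 0
                 else 100 * sum(detected) / sum(expressed)
  conf <- annMature$confidence[unique(
    subjectHits(findOverlaps(mature, annMature, minoverlap = 1L)))]
  list(specificity = specificity, sensitivity = sensitivity,
       nHighConfidence = sum(!is.na(conf) &
                               conf %in% c("high", "high_confidence")),
       nLowConfidence = sum(is.na(conf) |
                              !conf %in% c("high", "high_confidence")),
       nNovel = sum(!matched), nExpressed = sum(expressed),
       nDetected = sum(detected))
}

#' Wild-type versus mutant validation of predictions
#'
#' Maps the two read sets, quantifies the predicted loci (and optional
#' control loci) in both, normalizes to the median library size and
#' reports log2 fold changes and the downregulated fraction for each
#' locus set. Genuine miRNAs should be depleted in biogenesis-pathway
#' mutants; control loci (e.g. tRNA/snoRNA fragments) should not.
#'
#' @param predictions a [MirnaPredictions-class] object or mature
#'   GRanges.
#' @param wtReads,mutReads read data.frames ([readSrnaFasta()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @param controls optional GRanges of control loci, processed
#'   identically.
#' @param pseudo pseudo-count for fold changes.
#' @return list(se, lfc, fraction, cumulative, controlLfc,
#'   controlFraction).
#' @export
runValidate <- function(predictions, wtReads, mutReads, genome,
                        controls = NULL, pseudo = 1) {
  mature <- if (is(predictions, "MirnaPredictions"))
    matureLoci(predictions) else predictions
  if (length(mature) == 0L) stop("empty prediction set")
  wtMapped <- mapReads(wtReads, genome)
  mutMapped <- mapReads(mutReads, genome)
  if (length(wtMapped) == 0L || length(mutMapped) == 0L)
    stop("a sample has zero genome-mapped reads")
  sets <- list(wildtype = wtMapped, mutant = mutMapped)
  se <- normalizeRpmMedian(quantifyLoci(mature, sets))
  norm <- assay(se, "normalized")
  dr <- downregulatedFraction(norm[, "wildtype"], norm[, "mutant"], pseudo)
  out <- list(se = se, lfc = dr$lfc, fraction = dr$fraction,
              cumulative = data.frame(
                lfc = dr$sortedLfc,
                cumFraction = seq_along(dr$sortedLfc) /
                  length(dr$sortedLfc)),
              controlLfc = NULL, controlFraction = NA_real_)
  if (!is.null(controls) && length(controls)) {
    seC <- normalizeRpmMedian(quantifyLoci(controls, sets))
    normC <- assay(seC, "normalized")
    drC <- downregulatedFraction(normC[, "wildtype"], normC[, "mutant"],
                                 pseudo)
    out$controlLfc <- drC$lfc
    out$controlFraction <- drC$fraction
  }
  out
}
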