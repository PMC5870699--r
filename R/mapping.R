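.emptyMappedReads <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(id = character(), sequence = character(),
                         abundance = integer(), genomeHits = integer())
  gr
}

#' Map small RNA reads to a genome
#'
#' Exact, full-length, both-strand placement of non-redundant reads with
#' 0 gaps and 0 mismatches (the PatMaN contract). Reads not mapping
#' anywhere are discarded. Matching uses Biostrings preprocessed
#' dictionaries, one per read length. `N` never matches, in reads or in
#' the genome; reads containing non-ACGT characters are dropped.
#'
#' @param reads data.frame with `id`, `sequence`, `abundance` columns
#'   (see [readSrnaFasta()]).
#' @param genome a named [Biostrings::DNAStringSet].
#' @return A GRanges with one range per placement and metadata columns
#'   `id`, `sequence` (read 5'->3'), `abundance` and `genomeHits` (total
#'   placements of the sequence genome-wide, both strands). Multi-mapping
#'   reads keep their full abundance at every placement.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAAAT"))
#' reads <- data.frame(id = "r1", sequence = "ACGTACGT", abundance = 5)
#' mapReads(reads, genome)
#' @export
mapReads <- function(reads, genome) {
  clean <- !grepl("[^ACGT]", reads$sequence)
  reads <- reads[clean, , drop = FALSE]
  if (nrow(reads) == 0L) return(.emptyMappedReads())
  chroms <- names(genome)
  out <- vector("list", 0L)
  fwd <- DNAStringSet(reads$sequence)
  nFwd <- length(fwd)
  # one preprocessed dictionary for both strands; a trusted band over the
  # shortest read length supports the variable widths, with 0 mismatches
  # outside the band so matches are still exact and full-length
  pd <- PDict(c(fwd, reverseComplement(fwd)),
              tb.start = 1L, tb.width = min(nchar(reads$sequence)))
  for (chrom in chroms) {
    m <- matchPDict(pd, genome[[chrom]])
    counts <- elementNROWS(m)
    if (sum(counts) == 0L) next
    ir <- unlist(m)
    patIdx <- rep.int(seq_len(2L * nFwd), counts)
    isFwd <- patIdx <= nFwd
    readI <- ifelse(isFwd, patIdx, patIdx - nFwd)
    gr <- GRanges(chrom, ir, strand = ifelse(isFwd, "+", "-"))
    mcols(gr) <- DataFrame(id = reads$id[readI],
                           sequence = reads$sequence[readI],
                           abundance = as.integer(reads$abundance[readI]))
    out[[length(out) + 1L]] <- gr
  }
  if (length(out) == 0L) return(.emptyMappedReads())
  gr <- do.call(c, out)
  hits <- table(mcols(gr)$sequence)
  gr$genomeHits <- as.integer(hits[mcols(gr)$sequence])
  seqlengths(gr) <- setNames(width(genome), names(genome))[seqlevels(gr)]
  gr <- gr[order(match(as.character(seqnames(gr)), chroms), start(gr),
                 as.character(strand(gr)), mcols(gr)$sequence)]
  gr
}

#' @importFrom GenomeInfoDb seqlengths<-
NULL
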