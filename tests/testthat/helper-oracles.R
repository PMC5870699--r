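# Independent oracles used across the suite. These are deliberately
# naive implementations, kept separate from the package code paths.

# two-line absolute-log divergence summation
kldOracle <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) total <- total + abs(log(p[i] / q[i])) * p[i]
  total
}

# standard (unsigned) Kullback-Leibler divergence
kldStandard <- function(p, q) sum(p * log(p / q))

# naive both-strand sliding-window exact mapper
naiveMap <- function(sequence, genomeString) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  hits <- data.frame(start = integer(), end = integer(),
                     strand = character())
  L <- nchar(sequence)
  G <- nchar(genomeString)
  rc <- revcomp(sequence)
  for (i in seq_len(G - L + 1L)) {
    sub <- substr(genomeString, i, i + L - 1L)
    if (sub == sequence)
      hits <- rbind(hits, data.frame(start = i, end = i + L - 1L,
                                     strand = "+"))
    if (sub == rc)
      hits <- rbind(hits, data.frame(start = i, end = i + L - 1L,
                                     strand = "-"))
  }
  hits
}

# dinucleotide count histogram
dinucCounts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 2L) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1L]))
}

# random probability vector (strictly positive, sums to 1)
randomDistribution <- function(n) {
  x <- runif(n, min = 0.01)
  x / sum(x)
}

# GRanges of mapped-read-like records from a coordinate table
makeReads <- function(df, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(df$start, df$end),
    strand = if (!is.null(df$strand)) df$strand else "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = if (!is.null(df$id)) df$id else paste0("r", seq_len(nrow(df))),
    sequence = if (!is.null(df$sequence)) df$sequence
               else strrep("A", df$end - df$start + 1L),
    abundance = as.integer(df$abundance),
    genomeHits = if (!is.null(df$genomeHits)) as.integer(df$genomeHits)
                 else 1L)
  gr
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
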