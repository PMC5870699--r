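#' Absolute-log Kullback-Leibler divergence
#'
#' Divergence statistic used for peak detection:
#' \deqn{D(P\|Q) = \sum_i |\ln(P(i)/Q(i))| \, P(i)}
#' Taking the absolute value of the log ratio makes every term
#' nonnegative, so subwindows below as well as above the uniform level
#' contribute; the statistic is 0 exactly when P equals Q componentwise.
#' It dominates the standard (unsigned) Kullback-Leibler divergence.
#'
#' @param p,q probability vectors of equal length with strictly positive
#'   components, each summing to 1.
#' @return A nonnegative scalar.
#' @examples
#' kld(rep(1/4, 4), rep(1/4, 4))      # 0: uniform, no peak
#' kld(c(2/3, 1/3), c(1/2, 1/2))      # ~0.327
#' @export
kld <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length")
  if (any(p <= 0) || any(q <= 0))
    stop("p and q must be strictly positive")
  sum(abs(log(p / q)) * p)
}

.nSubwindows <- function(windowLen, lSw) as.integer(ceiling(windowLen / lSw))

#' Tile a genome into overlapping strand-aware windows
#'
#' Windows of length `lW` advance by `lW - lO`; the final partial window
#' at each chromosome end is included, and each strand is tiled
#' independently.
#'
#' @param genome a named [Biostrings::DNAStringSet], or a named integer
#'   vector of chromosome lengths.
#' @param params a [WindowParams-class] object.
#' @return A data.frame with columns `chrom`, `strand`, `start` (1-based)
#'   and `end` (clipped at the chromosome end).
#' @export
tileWindows <- function(genome, params) {
  lens <- if (is.numeric(genome)) genome else setNames(width(genome),
                                                       names(genome))
  step <- params@lW - params@lO
  rows <- lapply(names(lens), function(chrom) {
    # tile until the previous window has reached within one step of the
    # chromosome end; a chromosome shorter than the window gets exactly
    # one (clipped) window
    starts <- seq.int(1L, max(1L, lens[[chrom]] - step + 1L), by = step)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + params@lW - 1L, lens[[chrom]]),
               stringsAsFactors = FALSE)
  })
  base <- do.call(rbind, rows)
  out <- rbind(cbind(base, strand = "+", stringsAsFactors = FALSE),
               cbind(base, strand = "-", stringsAsFactors = FALSE))
  out[order(out$chrom, out$start, out$strand),
      c("chrom", "strand", "start", "end")]
}

.fivePrime <- function(reads) {
  ifelse(as.character(strand(reads)) == "-", end(reads), start(reads))
}

#' Subwindow abundance distribution of one window
#'
#' Assigns every read whose 5' end falls inside the window to the
#' subwindow containing that 5' end (the 5' end is the Dicer-defined,
#' most homogeneous coordinate of a miRNA read stack), accumulates raw
#' abundances per subwindow, and converts to a probability vector after
#' adding the pseudo-count `offset` to every subwindow:
#' P(i) = (r_sw(i) + offset) / sum_j (r_sw(j) + offset).
#'
#' @param reads GRanges of mapped reads (with `abundance`).
#' @param chrom,strandChar,windowStart,windowEnd window identity
#'   (1-based inclusive coordinates).
#' @param params a [WindowParams-class] object.
#' @return A list with elements `chrom`, `strand`, `windowStart`,
#'   `windowEnd`, `rSw` (raw abundance per subwindow), `P`, `Q`
#'   (scalar 1/#sw) and `nSub`.
#' @export
windowDistribution <- function(reads, chrom, strandChar, windowStart,
                               windowEnd, params) {
  nSub <- .nSubwindows(windowEnd - windowStart + 1L, params@lSw)
  rSw <- numeric(nSub)
  if (length(reads)) {
    sel <- as.character(seqnames(reads)) == chrom &
      as.character(strand(reads)) == strandChar
    p5 <- .fivePrime(reads[sel])
    inWin <- p5 >= windowStart & p5 <= windowEnd
    if (any(inWin)) {
      idx <- ((p5[inWin] - windowStart) %/% params@lSw) + 1L
      ab <- mcols(reads[sel][inWin])$abundance
      agg <- tapply(ab, idx, sum)
      rSw[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  tot <- sum(rSw + params@offset)
  list(chrom = chrom, strand = strandChar, windowStart = windowStart,
       windowEnd = windowEnd, rSw = rSw,
       P = (rSw + params@offset) / tot, Q = 1 / nSub, nSub = nSub)
}

.distKld <- function(rSw, offset) {
  n <- length(rSw)
  p <- (rSw + offset) / sum(rSw + offset)
  kld(p, rep(1 / n, n))
}

# core peak-extraction loop on plain vectors (p5 = 5' end positions,
# ab = abundances); returns indices of emitted reads in extraction order
.peakCore <- function(p5, ab, windowStart, windowEnd, params) {
  nSub <- .nSubwindows(windowEnd - windowStart + 1L, params@lSw)
  subIdx <- ((p5 - windowStart) %/% params@lSw) + 1L
  rSw <- numeric(nSub)
  agg <- tapply(ab, subIdx, sum)
  rSw[as.integer(names(agg))] <- as.numeric(agg)
  alive <- rep(TRUE, length(p5))
  emitted <- integer(0)
  while (.distKld(rSw, params@offset) > params@rudVal) {
    peakSub <- which.max(rSw)
    inSub <- which(alive & subIdx == peakSub)
    if (length(inSub) == 0L) break  # defensive; cannot occur with offset > 0
    s <- inSub[order(-ab[inSub], p5[inSub])][1L]
    # plateau test: local re-tiling of plateauRange nt centred on s
    half <- params@plateauRange %/% 2L
    locLo <- max(windowStart, p5[s] - half)
    locHi <- min(windowEnd, p5[s] + half)
    nLoc <- .nSubwindows(locHi - locLo + 1L, params@lSw)
    locR <- numeric(nLoc)
    inLoc <- which(alive & p5 >= locLo & p5 <= locHi)
    if (length(inLoc)) {
      li <- ((p5[inLoc] - locLo) %/% params@lSw) + 1L
      lagg <- tapply(ab[inLoc], li, sum)
      locR[as.integer(names(lagg))] <- as.numeric(lagg)
    }
    # a read whose abundance does not exceed the pseudo-count is at the
    # assumed background level and is never a peak (the offset exists to
    # keep low-expression reads from being classified as peaks)
    isPeak <- ab[s] > params@offset && nLoc >= 2L &&
      .distKld(locR, params@offset) > params@rudVal
    if (isPeak) emitted <- c(emitted, s)
    rSw[peakSub] <- rSw[peakSub] - ab[s]
    alive[s] <- FALSE
  }
  emitted
}

#' Iterative peak extraction from one window
#'
#' While the divergence of the subwindow distribution from uniform
#' exceeds `rudVal`: identify the subwindow with the highest abundance,
#' take its most abundant read `s`, and re-test a `plateauRange`-wide
#' region centred on `s`'s 5' end with the same statistic; if the local
#' region is itself non-uniform `s` is emitted as a candidate peak,
#' otherwise it is rejected as a plateau. Either way `s`'s abundance is
#' removed and the distribution recomputed, so the loop terminates after
#' at most one iteration per distinct read. Several peaks (e.g. miRNA and
#' miRNA*) can be emitted from one window.
#'
#' Ties are broken deterministically: equal subwindow peaks go to the
#' lowest subwindow index; equal-abundance reads to the leftmost 5' end.
#'
#' @param dist output of [windowDistribution()].
#' @param reads GRanges of mapped reads on the window's chromosome and
#'   strand (at least those inside the window).
#' @param params a [WindowParams-class] object.
#' @return A GRanges of candidate reads (possibly empty) with metadata
#'   `id`, `sequence`, `abundance`, `genomeHits`, `extractionOrder`.
#' @export
extractCandidates <- function(dist, reads, params) {
  sel <- as.character(seqnames(reads)) == dist$chrom &
    as.character(strand(reads)) == dist$strand
  reads <- reads[sel]
  p5 <- .fivePrime(reads)
  inWin <- p5 >= dist$windowStart & p5 <= dist$windowEnd
  reads <- reads[inWin]
  p5 <- p5[inWin]
  emitted <- .peakCore(p5, mcols(reads)$abundance, dist$windowStart,
                       dist$windowEnd, params)
  out <- reads[emitted]
  out$extractionOrder <- seq_along(emitted)
  out
}

#' Genome-wide candidate collection
#'
#' Runs [windowDistribution()] and [extractCandidates()] over every
#' window produced by [tileWindows()] (skipping windows without reads,
#' which are uniform by construction) and deduplicates candidates
#' emitted by overlapping windows.
#'
#' @param reads GRanges of mapped reads.
#' @param genome genome or named length vector, as in [tileWindows()].
#' @param params a [WindowParams-class] object.
#' @return GRanges of unique candidate reads.
#' @export
collectCandidates <- function(reads, genome, params) {
  wins <- tileWindows(genome, params)
  chromStrand <- paste(as.character(seqnames(reads)),
                       as.character(strand(reads)))
  p5all <- .fivePrime(reads)
  abAll <- mcols(reads)$abundance
  keepIdx <- integer(0)
  for (cs in unique(paste(wins$chrom, wins$strand))) {
    sub <- wins[paste(wins$chrom, wins$strand) == cs, ]
    csIdx <- which(chromStrand == cs)
    if (length(csIdx) == 0L) next
    ord <- csIdx[order(p5all[csIdx])]
    p5 <- p5all[ord]
    ab <- abAll[ord]
    for (i in seq_len(nrow(sub))) {
      lo <- findInterval(sub$start[i] - 1L, p5) + 1L
      hi <- findInterval(sub$end[i], p5)
      if (lo > hi) next
      emitted <- .peakCore(p5[lo:hi], ab[lo:hi], sub$start[i], sub$end[i],
                           params)
      keepIdx <- c(keepIdx, ord[lo:hi][emitted])
    }
  }
  keepIdx <- unique(keepIdx)
  out <- reads[keepIdx]
  out$extractionOrder <- seq_along(keepIdx)
  out
}
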