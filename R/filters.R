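#' Repetitive-locus filter
#'
#' High-confidence miRNAs are unlikely to derive from repetitive regions,
#' so candidates whose sequence maps to the genome strictly more than
#' `repeats` times (both strands) are discarded.
#'
#' @param candidate a single-element GRanges candidate with a
#'   `genomeHits` metadata column.
#' @param params a [LocusFilterParams-class] object.
#' @return A list with `keep` (logical) and `reason` (NA when kept).
#' @export
repeatFilter <- function(candidate, params) {
  if (mcols(candidate)$genomeHits > params@repeats) {
    list(keep = FALSE, reason = "repetitive locus")
  } else {
    list(keep = TRUE, reason = NA_character_)
  }
}

#' Size-class distribution filter
#'
#' Builds an abundance histogram over read lengths
#' `[sizeMin, sizeMax]` from all reads incident to the putative precursor
#' region, adds the +1 pseudo-count per class, and compares it to the
#' uniform distribution with the absolute-log divergence. The candidate
#' is kept only when the distribution is non-uniform (divergence >
#' `rudVal`) *and* the dominant length class lies within the expected
#' miRNA range `[minLen, maxLen]` -- a degradation locus has either a
#' flat length profile or a dominant class outside the miRNA range.
#'
#' @param candidate single-element candidate GRanges (unused beyond
#'   interface symmetry; may be NULL).
#' @param incidentReads GRanges of reads incident to the candidate's
#'   prospective folding window, same strand.
#' @param params a [LocusFilterParams-class] object.
#' @return list(keep, reason, kld, dominantLength).
#' @export
sizeClassFilter <- function(candidate, incidentReads, params) {
  if (length(incidentReads) == 0L)
    return(list(keep = FALSE, reason = "no reads", kld = NA_real_,
                dominantLength = NA_integer_))
  classes <- params@sizeMin:params@sizeMax
  counts <- numeric(length(classes))
  len <- width(incidentReads)
  ab <- mcols(incidentReads)$abundance
  inRange <- len >= params@sizeMin & len <= params@sizeMax
  if (any(inRange)) {
    agg <- tapply(ab[inRange], len[inRange], sum)
    counts[match(as.integer(names(agg)), classes)] <- as.numeric(agg)
  }
  p <- (counts + 1) / sum(counts + 1)
  d <- kld(p, rep(1 / length(classes), length(classes)))
  dominant <- classes[which.max(counts)]
  keep <- d > params@rudVal && dominant >= params@minLen &&
    dominant <= params@maxLen
  reason <- if (keep) NA_character_
            else if (d <= params@rudVal) "uniform size-class distribution"
            else "dominant size class outside miRNA range"
  list(keep = keep, reason = reason, kld = d, dominantLength = dominant)
}

#' Group reads into excision clusters
#'
#' A cluster is the set of reads mapping to the same location whose start
#' and end coordinates both lie within `clearCut` nt of the cluster
#' seed's. Construction is a greedy single pass over reads sorted by
#' start (ties: end, then descending abundance): a read joins the open
#' cluster iff both its start and end are within `clearCut` of the seed's
#' coordinates, otherwise it opens a new cluster. Every read belongs to
#' exactly one cluster.
#'
#' @param reads GRanges of same-strand reads.
#' @param params a [LocusFilterParams-class] object.
#' @return A list of GRanges, one per cluster, each with a
#'   `totalAbundance` attribute and `seedStart`/`seedEnd` attributes.
#' @export
buildClusters <- function(reads, params) {
  if (length(reads) == 0L) return(list())
  ord <- order(start(reads), end(reads), -mcols(reads)$abundance)
  reads <- reads[ord]
  clusters <- list()
  members <- integer(0)
  seedStart <- seedEnd <- NA_integer_
  flush <- function() {
    cl <- reads[members]
    attr(cl, "seedStart") <- seedStart
    attr(cl, "seedEnd") <- seedEnd
    attr(cl, "totalAbundance") <- sum(mcols(cl)$abundance)
    clusters[[length(clusters) + 1L]] <<- cl
  }
  for (i in seq_along(reads)) {
    if (length(members) == 0L) {
      members <- i
      seedStart <- start(reads)[i]
      seedEnd <- end(reads)[i]
    } else if (abs(start(reads)[i] - seedStart) <= params@clearCut &&
               abs(end(reads)[i] - seedEnd) <= params@clearCut) {
      members <- c(members, i)
    } else {
      flush()
      members <- i
      seedStart <- start(reads)[i]
      seedEnd <- end(reads)[i]
    }
  }
  flush()
  clusters
}

.overlapLen <- function(aStart, aEnd, bStart, bEnd) {
  pmax(0L, pmin(aEnd, bEnd) - pmax(aStart, bStart) + 1L)
}

#' Precise-processing (Drosha/Dicer excision) filter
#'
#' Tests whether the read stack around a candidate shows the sharp
#' excision boundaries expected of Drosha/Dicer products:
#' (i) reads sharing the candidate's start *and* end coordinates within
#' `clearCut` nt must account for at least `clearCutPercent`% of the
#' candidate cluster's abundance (sharp 5'/3' ends); and
#' (ii) reads from *other* clusters overlapping the candidate by more
#' than `clearCut` nt must account for less than `overlapPercent`% of
#' the candidate cluster's abundance (no smeared degradation signal).
#'
#' @param candidate single-element candidate GRanges.
#' @param clusters output of [buildClusters()] on the reads of the
#'   candidate's window; must contain the candidate.
#' @param params a [LocusFilterParams-class] object.
#' @return list(keep, reason, variantFraction, overlapFraction)
#'   (fractions in percent).
#' @export
preciseProcessingFilter <- function(candidate, clusters, params) {
  cs <- start(candidate)
  ce <- end(candidate)
  cseq <- mcols(candidate)$sequence
  own <- NA_integer_
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (any(start(cl) == cs & end(cl) == ce & mcols(cl)$sequence == cseq)) {
      own <- k
      break
    }
  }
  if (is.na(own)) stop("candidate not found in any cluster")
  ownCl <- clusters[[own]]
  total <- attr(ownCl, "totalAbundance")
  variants <- abs(start(ownCl) - cs) <= params@clearCut &
    abs(end(ownCl) - ce) <= params@clearCut
  variantAb <- sum(mcols(ownCl)$abundance[variants])
  variantPct <- 100 * variantAb / total
  if (variantPct < params@clearCutPercent) {
    return(list(keep = FALSE, reason = "ragged 5'/3' ends",
                variantFraction = variantPct, overlapFraction = NA_real_))
  }
  overlapAb <- 0
  for (k in seq_along(clusters)) {
    if (k == own) next
    cl <- clusters[[k]]
    ov <- .overlapLen(start(cl), end(cl), cs, ce)
    overlapAb <- overlapAb + sum(mcols(cl)$abundance[ov > params@clearCut])
  }
  overlapPct <- 100 * overlapAb / total
  if (overlapPct >= params@overlapPercent) {
    return(list(keep = FALSE, reason = "overlapping degradation",
                variantFraction = variantPct, overlapFraction = overlapPct))
  }
  list(keep = TRUE, reason = NA_character_,
       variantFraction = variantPct, overlapFraction = overlapPct)
}
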