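#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson shuffle: the sequence is viewed as an Eulerian walk
#' on the graph whose vertices are nucleotides and whose edges are the
#' observed dinucleotides; a random last-edge tree to the terminal
#' vertex is drawn and the remaining edges permuted, yielding a uniform
#' random sequence with *exactly* the original dinucleotide (and hence
#' mononucleotide) counts.
#'
#' @param seq character string (RNA or DNA, any alphabet).
#' @return A shuffled string with identical first/last characters and
#'   identical dinucleotide counts.
#' @export
dinucleotideShuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < 4L) stop("sequence must be at least 4 nt long")
  verts <- unique(chars)
  if (length(verts) == 1L) return(seq)
  vi <- match(chars, verts)
  edges <- split(vi[-1L], vi[-n])          # out-edges per source vertex
  last <- vi[n]
  srcs <- as.integer(names(edges))
  repeat {
    # pick a candidate last edge for every vertex except the terminal one
    lastEdge <- rep(NA_integer_, length(verts))
    for (v in srcs) {
      if (v == last) next
      outs <- edges[[as.character(v)]]
      lastEdge[v] <- outs[sample.int(length(outs), 1L)]
    }
    # the chosen last edges must form a tree rooted at the terminal vertex
    ok <- TRUE
    for (v in seq_along(verts)) {
      if (is.na(lastEdge[v])) next
      seen <- v
      cur <- v
      while (cur != last) {
        cur <- lastEdge[cur]
        if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (ok) break
  }
  walk <- integer(n)
  walk[1L] <- vi[1L]
  remaining <- lapply(seq_along(verts), function(v) {
    outs <- edges[[as.character(v)]]
    if (is.null(outs)) return(integer(0))
    if (!is.na(lastEdge[v])) {
      # remove one copy of the reserved last edge, shuffle the rest
      drop <- which(outs == lastEdge[v])[1L]
      rest <- outs[-drop]
      c(if (length(rest) > 1L) rest[sample.int(length(rest))] else rest,
        lastEdge[v])
    } else {
      if (length(outs) > 1L) outs[sample.int(length(outs))] else outs
    }
  })
  ptr <- rep(1L, length(verts))
  for (i in 2:n) {
    v <- walk[i - 1L]
    walk[i] <- remaining[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
  }
  paste(verts[walk], collapse = "")
}

#' Structure randomization p-value
#'
#' Estimates the probability that a sequence with the same dinucleotide
#' composition folds at least as stably as the observed precursor:
#' p = (1 + #\{shuffles with MFE <= MFE(seq)\}) / (nShuffles + 1).
#' Deterministic for a fixed seed.
#'
#' @param seq precursor sequence (RNA or DNA).
#' @param nShuffles number of dinucleotide-preserving shuffles.
#' @param seed RNG seed.
#' @param backend folding backend for the global MFE (internal only for
#'   now; the argument exists for interface stability).
#' @return p-value in `[1/(nShuffles+1), 1]`.
#' @export
randomizationPvalue <- function(seq, nShuffles = 99L, seed = 42L,
                                backend = "internal") {
  if (nchar(seq) < 4L) stop("sequence must be at least 4 nt long")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  obs <- foldGlobal(seq)$mfe
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(nShuffles), function(i) {
      foldGlobal(dinucleotideShuffle(seq))$mfe <= obs
    }, logical(1)))
  })
  (1 + hits) / (nShuffles + 1)
}

.clampLog2Odds <- function(x) pmin(10, pmax(-10, x))

#' Log-odds prediction score
#'
#' Three-term score in the spirit of probabilistic miRNA scoring models:
#' a structure term from the randomization p-value, a star-evidence term
#' and a read-signature term. The score ranks predictions; it never
#' changes the prediction set.
#'
#' @param pRandom structure randomization p-value in (0, 1].
#' @param starDetected logical; was a miRNA* read observed?
#' @param starAbundance abundance of the star read (0 when undetected).
#' @param signatureFraction fraction of the locus abundance lying within
#'   `clearCut` of the mature/star/loop positions.
#' @return list(pRandom, sStruct, sStar, sSignature, total). `sStruct` =
#'   log2((1-p)/p) and `sSignature` = log2(f/(1-f)), both clamped to
#'   `[-10, 10]`; `sStar` is +3 for a star with abundance >= 2, +1 for
#'   any detected star, else 0.
#' @examples
#' predictionScore(0.5, FALSE, 0, 0.5)$total  # 0, the neutral point
#' @export
predictionScore <- function(pRandom, starDetected, starAbundance,
                            signatureFraction) {
  stopifnot(pRandom > 0, pRandom <= 1,
            signatureFraction >= 0, signatureFraction <= 1)
  sStruct <- .clampLog2Odds(log2((1 - pRandom) / pRandom))
  sStar <- if (starDetected && starAbundance >= 2) 3
           else if (starDetected) 1 else 0
  sSignature <- .clampLog2Odds(log2(signatureFraction /
                                    (1 - signatureFraction)))
  list(pRandom = pRandom, sStruct = sStruct, sStar = sStar,
       sSignature = sSignature, total = sStruct + sStar + sSignature)
}
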