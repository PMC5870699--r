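#' Enumerate locally stable secondary structures
#'
#' Folds an RNA sequence and returns every locally stable closed
#' structure found in it, each with its subspan (1-based, relative to the
#' input), dot-bracket string and minimum free energy. Two backends
#' satisfy the same contract:
#'
#' * `"internal"`: the package's own dynamic-programming folder
#'   (maximum base pairing with GC/AU/GU pair energies, helix stacking
#'   bonus and a 3 nt minimum hairpin loop). Dependency-free and
#'   deterministic; energies are on a simplified scale.
#' * `"rnalfold"`: shells out to the ViennaRNA `RNALfold` executable
#'   when it is on the PATH, parsing its locally stable structure list.
#'
#' @param seq RNA or DNA string (T is read as U).
#' @param backend `"internal"` or `"rnalfold"`.
#' @param maxEnergy only structures with MFE at or below this value are
#'   reported (internal backend).
#' @param minSpan shortest reported structure span (nt).
#' @return A data.frame with columns `start`, `end`, `mfe`, `structure`.
#' @examples
#' foldSequence("GGGGAAAACCCC")
#' @export
foldSequence <- function(seq, backend = c("internal", "rnalfold"),
                         maxEnergy = -1, minSpan = 8L) {
  backend <- match.arg(backend)
  rna <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", rna)) stop("invalid RNA alphabet in sequence")
  if (backend == "internal") {
    df <- .foldLocalCpp(rna, maxEnergy = maxEnergy, minSpan = as.integer(minSpan))
  } else {
    df <- .runRnalfold(rna)
  }
  stopifnot(all(df$end <= nchar(rna)), all(df$start >= 1))
  df[order(df$mfe, df$end - df$start, df$start), , drop = FALSE]
}

.runRnalfold <- function(rna) {
  exe <- Sys.which("RNALfold")
  if (!nzchar(exe)) stop("RNALfold executable not found on PATH")
  out <- suppressWarnings(system2(exe, stdout = TRUE, stderr = TRUE,
                                  input = rna))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("RNALfold failed: ", paste(out, collapse = "\n"))
  pat <- "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+([0-9]+)"
  hits <- regmatches(out, regexec(pat, out))
  keep <- lengths(hits) == 4L
  starts <- vapply(hits[keep], function(x) as.integer(x[4L]), integer(1))
  structs <- vapply(hits[keep], `[`, character(1), 2L)
  mfes <- vapply(hits[keep], function(x) as.numeric(x[3L]), numeric(1))
  data.frame(start = starts, end = starts + nchar(structs) - 1L,
             mfe = mfes, structure = structs, stringsAsFactors = FALSE)
}

#' Global minimum free energy of a sequence
#'
#' Folds the whole sequence (internal backend) and returns its structure
#' and MFE; used by the randomization p-value.
#'
#' @param seq RNA or DNA string.
#' @return list(structure, mfe).
#' @export
foldGlobal <- function(seq) {
  rna <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", rna)) stop("invalid RNA alphabet in sequence")
  .foldGlobalCpp(rna)
}

#' Adjusted minimum free energy
#'
#' Normalizes an MFE per 100 nt so precursors of different lengths are
#' comparable: aMFE = MFE / foldLength * 100.
#'
#' @param mfe minimum free energy, kcal/mol.
#' @param foldLength folded sequence length, nt.
#' @return aMFE in kcal/mol per 100 nt.
#' @examples
#' computeAmfe(-30, 150)  # -20
#' @export
computeAmfe <- function(mfe, foldLength) {
  if (any(foldLength <= 0)) stop("foldLength must be > 0")
  mfe / foldLength * 100
}

#' Pair table of a dot-bracket structure
#'
#' @param dotbracket dot-bracket string (balanced).
#' @return Integer vector `pt` with `pt[i]` = partner of position i, or
#'   `NA` if unpaired.
#' @export
pairTable <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1L]]
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

#' Count hairpin loops of a structure
#'
#' A hairpin loop is an innermost loop: a "(" directly followed (across
#' dots) by its matching ")". A simple stem-loop has exactly one.
#'
#' @param dotbracket dot-bracket string.
#' @return Integer loop count.
#' @export
countHairpinLoops <- function(dotbracket) {
  length(gregexpr("\\([.]*\\)", dotbracket)[[1L]][
    gregexpr("\\([.]*\\)", dotbracket)[[1L]] > 0])
}

#' Structural filters on a hairpin candidate
#'
#' Applies the precursor-level checks, each reported independently:
#' (1) minimum hairpin length; (2) maximum aMFE; (3) the mature sequence
#' must lie entirely on one arm (not span the terminal loop); (4)
#' minimum number of paired mature bases; (5) maximum run of consecutive
#' unpaired mature bases; (6) maximum number of hairpin loops.
#'
#' @param structure dot-bracket string of the candidate precursor.
#' @param mfe its minimum free energy.
#' @param matureStart,matureEnd mature coordinates, 1-based relative to
#'   the precursor.
#' @param params a [StructureParams-class] object.
#' @return list(pass, reasons, amfe).
#' @export
structuralFilters <- function(structure, mfe, matureStart, matureEnd,
                              params) {
  n <- nchar(structure)
  stopifnot(matureStart >= 1, matureEnd <= n, matureStart <= matureEnd)
  amfe <- computeAmfe(mfe, n)
  pt <- pairTable(structure)
  mat <- matureStart:matureEnd
  reasons <- character(0)
  if (n < params@minHairpinLen)
    reasons <- c(reasons, "hairpin too short")
  if (amfe > params@maxAmfe)
    reasons <- c(reasons, "aMFE above maximum")
  if (params@requireMatureNotInLoop) {
    partners <- pt[mat]
    paired <- which(!is.na(partners))
    # mature spans the terminal loop if some of its bases pair leftwards
    # and others rightwards
    if (length(paired) &&
        any(partners[paired] < mat[paired]) &&
        any(partners[paired] > mat[paired]))
      reasons <- c(reasons, "mature spans terminal loop")
  }
  nPaired <- sum(!is.na(pt[mat]))
  if (nPaired < params@minPairedInMature)
    reasons <- c(reasons, "too few paired mature bases")
  runs <- rle(is.na(pt[mat]))
  maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (maxRun > params@maxUnpairedRun)
    reasons <- c(reasons, "long unpaired run in mature")
  if (countHairpinLoops(structure) > params@maxLoops)
    reasons <- c(reasons, "too many loops")
  list(pass = length(reasons) == 0L, reasons = reasons, amfe = amfe)
}

#' Select the precursor among passing structures
#'
#' The structure with the lowest aMFE wins; ties go to the shortest fold
#' length, then to the leftmost start.
#'
#' @param passing data.frame with columns `start`, `end`, `mfe`,
#'   `structure` (and optionally `amfe`).
#' @return The selected row (one-row data.frame), or NULL for an empty
#'   input (no admissible precursor).
#' @export
selectPrecursor <- function(passing) {
  if (is.null(passing) || nrow(passing) == 0L) return(NULL)
  len <- passing$end - passing$start + 1L
  amfe <- computeAmfe(passing$mfe, len)
  ord <- order(amfe, len, passing$start)
  passing[ord[1L], , drop = FALSE]
}

#' Infer the miRNA* from duplex geometry
#'
#' Projects the mature sequence through the pair table and applies the
#' canonical Dicer duplex geometry: the star strand pairs the mature with
#' a 2 nt 3' overhang on each duplex end. Positions are relative to the
#' precursor. Returns NULL when more than half of the mature bases are
#' unpaired (no credible duplex).
#'
#' @param structure precursor dot-bracket.
#' @param matureStart,matureEnd mature span, 1-based in the precursor.
#' @param overhang 3' overhang in nt (default 2).
#' @return list(start, end, clipped) or NULL.
#' @export
inferStar <- function(structure, matureStart, matureEnd, overhang = 2L) {
  pt <- pairTable(structure)
  n <- nchar(structure)
  mat <- matureStart:matureEnd
  paired <- mat[!is.na(pt[mat])]
  if (length(paired) <= length(mat) / 2) return(NULL)
  p1 <- paired[1L]                      # 5'-most paired mature base
  p2 <- paired[length(paired)]          # 3'-most paired mature base
  on5p <- pt[p1] > p1
  # project unpaired mature tails onto the opposite arm
  if (on5p) {
    rawEnd <- pt[p1] + (p1 - matureStart)
    rawStart <- pt[p2] - (matureEnd - p2)
    starStart <- rawStart + overhang
    starEnd <- rawEnd + overhang
  } else {
    rawEnd <- pt[p1] + (p1 - matureStart)
    rawStart <- pt[p2] - (matureEnd - p2)
    starStart <- rawStart - overhang
    starEnd <- rawEnd - overhang
  }
  clipped <- starStart < 1L || starEnd > n
  list(start = max(1L, as.integer(starStart)),
       end = min(n, as.integer(starEnd)), clipped = clipped)
}

#' Fold the window around a candidate and pick its precursor
#'
#' Extracts `maxFoldLen` nt of genomic sequence on each side of the
#' mature candidate, folds it, keeps the locally stable structures that
#' contain the mature span and pass [structuralFilters()], and selects
#' the lowest-aMFE survivor.
#'
#' @param candidate single-element mature GRanges.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param sparams a [StructureParams-class] object.
#' @param backend folding backend (see [foldSequence()]).
#' @return NULL if no structure passes, else a list with the precursor's
#'   genomic coordinates (`chrom`, `start`, `end`, `strand`), `sequence`
#'   (precursor 5'->3' on its strand, RNA), `structure`, `mfe`, `amfe`,
#'   mature coordinates within the precursor (`matureLocalStart`,
#'   `matureLocalEnd`) and the star inference (`star`, possibly NULL).
#' @export
foldCandidateWindow <- function(candidate, genome, sparams,
                                backend = "internal") {
  chrom <- as.character(seqnames(candidate))
  strandChar <- as.character(strand(candidate))
  chromLen <- length(genome[[chrom]])
  winStart <- max(1L, start(candidate) - sparams@maxFoldLen)
  winEnd <- min(chromLen, end(candidate) + sparams@maxFoldLen)
  dna <- subseq(genome[[chrom]], winStart, winEnd)
  if (strandChar == "-") dna <- reverseComplement(dna)
  winSeq <- chartr("T", "U", as.character(dna))
  # mature span in window-local, strand-oriented coordinates
  if (strandChar == "-") {
    matLocalStart <- winEnd - end(candidate) + 1L
  } else {
    matLocalStart <- start(candidate) - winStart + 1L
  }
  matLocalEnd <- matLocalStart + width(candidate) - 1L
  folds <- foldSequence(winSeq, backend = backend,
                        maxEnergy = min(-1, sparams@maxAmfe *
                                          sparams@minHairpinLen / 100))
  if (nrow(folds) == 0L) return(NULL)
  len <- folds$end - folds$start + 1L
  keep <- folds$start <= matLocalStart & folds$end >= matLocalEnd &
    len >= sparams@minHairpinLen &
    computeAmfe(folds$mfe, len) <= sparams@maxAmfe
  folds <- folds[keep, , drop = FALSE]
  if (nrow(folds) == 0L) return(NULL)
  # evaluate the remaining (string-level) filters in aMFE order and stop
  # at the first pass -- equivalent to filtering all then taking the
  # lowest-aMFE survivor, but avoids parsing structures that cannot win
  len <- folds$end - folds$start + 1L
  folds <- folds[order(computeAmfe(folds$mfe, len), len, folds$start), ,
                 drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(folds))) {
    ok <- structuralFilters(folds$structure[i], folds$mfe[i],
                            matLocalStart - folds$start[i] + 1L,
                            matLocalEnd - folds$start[i] + 1L, sparams)$pass
    if (ok) { best <- folds[i, , drop = FALSE]; break }
  }
  if (is.null(best)) return(NULL)
  pLen <- best$end - best$start + 1L
  # genomic coordinates of the precursor span
  if (strandChar == "-") {
    gEnd <- winEnd - best$start + 1L
    gStart <- winEnd - best$end + 1L
  } else {
    gStart <- winStart + best$start - 1L
    gEnd <- winStart + best$end - 1L
  }
  matInPrec <- matLocalStart - best$start + 1L
  star <- inferStar(best$structure, matInPrec,
                    matInPrec + width(candidate) - 1L,
                    overhang = sparams@starOverhang)
  list(chrom = chrom, start = gStart, end = gEnd, strand = strandChar,
       sequence = substr(winSeq, best$start, best$end),
       structure = best$structure, mfe = best$mfe,
       amfe = computeAmfe(best$mfe, pLen),
       matureLocalStart = matInPrec,
       matureLocalEnd = matInPrec + width(candidate) - 1L,
       star = star)
}
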