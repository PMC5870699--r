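#' @title Parameter classes
#'
#' @description S4 containers for the tunable parameters of each pipeline
#' stage. [animalParams()] and [plantParams()] build complete profiles;
#' individual values can be overridden through their `...` arguments.
#'
#' @name miRPeaksParams
NULL

#' Window / peak-detection parameters
#'
#' Geometry of the genomic windows scanned for abundance peaks and the
#' divergence threshold that defines a peak.
#'
#' @slot lW window length (nt).
#' @slot lO overlap between consecutive windows (nt); windows advance by
#'   `lW - lO`.
#' @slot lSw subwindow length (nt); abundances are aggregated per
#'   subwindow before computing the divergence.
#' @slot rudVal divergence threshold above which a window is considered
#'   to contain at least one peak (dimensionless).
#' @slot plateauRange width (nt) of the local region re-tested around a
#'   putative peak to reject plateaus.
#' @slot offset pseudo-count added to every subwindow abundance.
#'
#' @exportClass WindowParams
setClass("WindowParams", representation(
  lW = "integer", lO = "integer", lSw = "integer",
  rudVal = "numeric", plateauRange = "integer", offset = "numeric"
))

setValidity("WindowParams", function(object) {
  msg <- character()
  if (object@lO >= object@lW) msg <- c(msg, "lO must be < lW")
  if (object@lSw > object@lW) msg <- c(msg, "lSw must be <= lW")
  if (object@rudVal <= 0) msg <- c(msg, "rudVal must be > 0")
  if (object@plateauRange < object@lSw)
    msg <- c(msg, "plateauRange must be >= lSw")
  if (object@offset <= 0) msg <- c(msg, "offset must be > 0")
  if (length(msg)) msg else TRUE
})

#' Locus filter parameters
#'
#' Thresholds for the rule-based false-positive filters applied to peak
#' candidates: repetitive-locus, size-class and precise-processing
#' (Drosha/Dicer excision) filters.
#'
#' @slot repeats maximum allowed genome placements of a candidate read.
#' @slot minLen,maxLen expected mature miRNA size class (nt).
#' @slot sizeMin,sizeMax range of read lengths over which the size-class
#'   histogram is built (nt).
#' @slot clearCut slack (nt) within which two read start/end coordinates
#'   are considered equivalent.
#' @slot clearCutPercent minimum percentage of the candidate cluster's
#'   abundance that must sit at the candidate's coordinates (+/- clearCut).
#' @slot overlapPercent maximum percentage of the candidate cluster's
#'   abundance allowed in adjacent clusters overlapping the candidate by
#'   more than clearCut nt.
#' @slot rudVal divergence threshold shared with the peak detector.
#'
#' @exportClass LocusFilterParams
setClass("LocusFilterParams", representation(
  repeats = "integer", minLen = "integer", maxLen = "integer",
  sizeMin = "integer", sizeMax = "integer",
  clearCut = "integer", clearCutPercent = "numeric",
  overlapPercent = "numeric", rudVal = "numeric"
))

setValidity("LocusFilterParams", function(object) {
  msg <- character()
  if (object@minLen > object@maxLen) msg <- c(msg, "minLen must be <= maxLen")
  if (object@sizeMin > object@minLen || object@sizeMax < object@maxLen)
    msg <- c(msg, "[sizeMin, sizeMax] must contain [minLen, maxLen]")
  if (object@clearCutPercent <= 0 || object@clearCutPercent > 100)
    msg <- c(msg, "clearCutPercent must be in (0, 100]")
  if (object@overlapPercent <= 0 || object@overlapPercent > 100)
    msg <- c(msg, "overlapPercent must be in (0, 100]")
  if (object@repeats < 1) msg <- c(msg, "repeats must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Hairpin structure parameters
#'
#' Folding window geometry and the structural filters a candidate
#' precursor must pass.
#'
#' @slot maxFoldLen flanking sequence (nt) taken on each side of the
#'   mature candidate before folding.
#' @slot minHairpinLen minimum precursor length (nt).
#' @slot maxAmfe maximum (least negative) admissible adjusted minimum free
#'   energy, kcal/mol per 100 nt. Must be negative.
#' @slot minPairedInMature minimum number of paired bases within the
#'   mature sequence.
#' @slot maxUnpairedRun longest admissible run of unpaired bases within
#'   the mature sequence.
#' @slot maxLoops maximum number of hairpin loops in the precursor; 1
#'   restricts to simple stem-loops (animals), larger values admit plant
#'   multi-branched precursors.
#' @slot requireMatureNotInLoop if TRUE the mature sequence must lie
#'   entirely on one arm, not spanning the terminal loop.
#' @slot starOverhang 3' overhang (nt) used when inferring the miRNA*
#'   from the duplex geometry.
#'
#' @exportClass StructureParams
setClass("StructureParams", representation(
  maxFoldLen = "integer", minHairpinLen = "integer", maxAmfe = "numeric",
  minPairedInMature = "integer", maxUnpairedRun = "integer",
  maxLoops = "integer", requireMatureNotInLoop = "logical",
  starOverhang = "integer"
))

setValidity("StructureParams", function(object) {
  msg <- character()
  if (object@maxAmfe >= 0) msg <- c(msg, "maxAmfe must be < 0")
  if (object@minHairpinLen <= 2L * 21L)
    msg <- c(msg, "minHairpinLen must exceed twice the mature length")
  if (object@maxLoops < 1) msg <- c(msg, "maxLoops must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Scoring parameters
#'
#' @slot nShuffles number of dinucleotide-preserving shuffles for the
#'   structure randomization p-value.
#' @slot seed RNG seed for the shuffles.
#' @slot minScore optional score cut-off; `NA` (default) disables score
#'   filtering, which is the recommended setting since the score is a
#'   ranking aid, not a prediction criterion.
#'
#' @exportClass ScoreParams
setClass("ScoreParams", representation(
  nShuffles = "integer", seed = "integer", minScore = "numeric"
))

#' Full parameter profile
#'
#' Aggregates the per-stage parameter objects plus the folding backend
#' choice.
#'
#' @slot profile "animal" or "plant".
#' @slot window a [WindowParams-class] object.
#' @slot filter a [LocusFilterParams-class] object.
#' @slot structure a [StructureParams-class] object.
#' @slot score a [ScoreParams-class] object.
#' @slot backend folding backend: "internal" (built-in thermodynamic
#'   folder) or "rnalfold" (external ViennaRNA RNALfold executable).
#'
#' @exportClass PredictionParams
setClass("PredictionParams", representation(
  profile = "character", window = "WindowParams",
  filter = "LocusFilterParams", structure = "StructureParams",
  score = "ScoreParams", backend = "character"
))

setValidity("PredictionParams", function(object) {
  msg <- character()
  if (!object@profile %in% c("animal", "plant"))
    msg <- c(msg, "profile must be 'animal' or 'plant'")
  if (!object@backend %in% c("internal", "rnalfold"))
    msg <- c(msg, "backend must be 'internal' or 'rnalfold'")
  if (length(msg)) msg else TRUE
})

.makeWindowParams <- function(lW = 200L, lO = 100L, lSw = 25L,
                              rudVal = 0.35, plateauRange = 75L,
                              offset = 1) {
  new("WindowParams", lW = as.integer(lW), lO = as.integer(lO),
      lSw = as.integer(lSw), rudVal = rudVal,
      plateauRange = as.integer(plateauRange), offset = offset)
}

.makeFilterParams <- function(repeats = 20L, minLen = 21L, maxLen = 23L,
                              sizeMin = 16L, sizeMax = 28L, clearCut = 3L,
                              clearCutPercent = 75, overlapPercent = 50,
                              rudVal = 0.35) {
  new("LocusFilterParams", repeats = as.integer(repeats),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
      clearCut = as.integer(clearCut), clearCutPercent = clearCutPercent,
      overlapPercent = overlapPercent, rudVal = rudVal)
}

.makeStructureParams <- function(maxFoldLen, minHairpinLen, maxLoops,
                                 maxAmfe = -20, minPairedInMature = 14L,
                                 maxUnpairedRun = 5L,
                                 requireMatureNotInLoop = TRUE,
                                 starOverhang = 2L) {
  new("StructureParams", maxFoldLen = as.integer(maxFoldLen),
      minHairpinLen = as.integer(minHairpinLen), maxAmfe = maxAmfe,
      minPairedInMature = as.integer(minPairedInMature),
      maxUnpairedRun = as.integer(maxUnpairedRun),
      maxLoops = as.integer(maxLoops),
      requireMatureNotInLoop = requireMatureNotInLoop,
      starOverhang = as.integer(starOverhang))
}

.makeScoreParams <- function(nShuffles = 99L, seed = 42L,
                             minScore = NA_real_) {
  new("ScoreParams", nShuffles = as.integer(nShuffles),
      seed = as.integer(seed), minScore = as.numeric(minScore))
}

.buildProfile <- function(profile, structureDefaults, backend, ...) {
  dots <- list(...)
  pick <- function(fn, defaults = list()) {
    fm <- names(formals(fn))
    args <- modifyList(defaults, dots[intersect(names(dots), fm)])
    do.call(fn, args)
  }
  new("PredictionParams", profile = profile,
      window = pick(.makeWindowParams),
      filter = pick(.makeFilterParams),
      structure = pick(.makeStructureParams, structureDefaults),
      score = pick(.makeScoreParams),
      backend = backend)
}

#' Default parameter profiles
#'
#' `animalParams()` targets the compact, single-loop ~70 nt animal
#' pre-miRNA; `plantParams()` admits the longer (100-300 nt) and
#' potentially multi-branched plant precursors by widening the folding
#' window and allowing up to three hairpin loops.
#'
#' @param backend folding backend, `"internal"` or `"rnalfold"`.
#' @param ... overrides for any parameter of [WindowParams-class],
#'   [LocusFilterParams-class], [StructureParams-class] or
#'   [ScoreParams-class], passed by name (e.g. `rudVal = 0.4`).
#' @return A [PredictionParams-class] object.
#' @examples
#' p <- animalParams(rudVal = 0.4)
#' windowParams(p)
#' @export
animalParams <- function(backend = "internal", ...) {
  .buildProfile("animal",
                list(maxFoldLen = 100L, minHairpinLen = 50L, maxLoops = 1L),
                backend, ...)
}

#' @rdname animalParams
#' @export
plantParams <- function(backend = "internal", ...) {
  .buildProfile("plant",
                list(maxFoldLen = 300L, minHairpinLen = 60L, maxLoops = 3L),
                backend, ...)
}

#' Parameter accessors
#'
#' @param x a [PredictionParams-class] object.
#' @return The corresponding parameter sub-object.
#' @export
windowParams <- function(x) x@window

#' @rdname windowParams
#' @export
filterParams <- function(x) x@filter

#' @rdname windowParams
#' @export
structureParams <- function(x) x@structure

#' @rdname windowParams
#' @export
scoreParams <- function(x) x@score

#' @rdname windowParams
#' @export
foldingBackend <- function(x) x@backend

#' @export
setMethod("show", "PredictionParams", function(object) {
  cat("PredictionParams profile:", object@profile,
      " backend:", object@backend, "\n")
  w <- object@window
  cat("  windows: lW=", w@lW, " lO=", w@lO, " lSw=", w@lSw,
      " rudVal=", w@rudVal, " plateauRange=", w@plateauRange, "\n", sep = "")
  f <- object@filter
  cat("  filters: repeats<=", f@repeats, " size ", f@minLen, "-", f@maxLen,
      "nt clearCut=", f@clearCut, " clearCut%=", f@clearCutPercent,
      " overlap%=", f@overlapPercent, "\n", sep = "")
  s <- object@structure
  cat("  hairpin: maxFoldLen=", s@maxFoldLen, " minLen=", s@minHairpinLen,
      " maxAmfe=", s@maxAmfe, " maxLoops=", s@maxLoops, "\n", sep = "")
})

#' Serialize a parameter profile to a flat list
#'
#' Used to write the resolved configuration next to run outputs so every
#' run is reproducible from its output directory alone.
#'
#' @param params a [PredictionParams-class] object.
#' @return A named list of scalar values.
#' @export
paramsAsList <- function(params) {
  out <- list(profile = params@profile, backend = params@backend)
  for (part in c("window", "filter", "structure", "score")) {
    obj <- slot(params, part)
    for (nm in slotNames(obj)) {
      out[[paste(part, nm, sep = ".")]] <- slot(obj, nm)
    }
  }
  out
}
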