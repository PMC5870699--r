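#' Container for miRNA predictions
#'
#' Holds the final prediction set of a run: one mature locus per entry,
#' carried as a GRanges (mature span) whose metadata columns hold the
#' mature sequence and abundance, the star span/sequence/abundance
#' (NA when undetected), the precursor span, sequence, dot-bracket
#' structure, MFE and aMFE, the randomization p-value, the score
#' breakdown and the annotation status.
#'
#' @slot mature a GRanges with the per-prediction metadata.
#' @slot params the [PredictionParams-class] profile used.
#' @slot backend folding backend that actually ran.
#' @slot stageCounts named integer vector of candidate counts after each
#'   pipeline stage.
#' @slot discardReasons named integer vector histogram of discard
#'   reasons.
#'
#' @exportClass MirnaPredictions
setClass("MirnaPredictions", representation(
  mature = "GRanges", params = "PredictionParams", backend = "character",
  stageCounts = "integer", discardReasons = "integer"
))

#' @describeIn MirnaPredictions number of predictions.
#' @param x a MirnaPredictions object.
#' @export
setMethod("length", "MirnaPredictions", function(x) length(x@mature))

#' @export
setMethod("show", "MirnaPredictions", function(object) {
  cat("MirnaPredictions: ", length(object), " predicted loci (profile ",
      object@params@profile, ", backend ", object@backend, ")\n", sep = "")
  sc <- object@stageCounts
  if (length(sc))
    cat("  stage counts:", paste(names(sc), sc, sep = "=", collapse = " "),
        "\n")
  if (length(object@discardReasons))
    cat("  discards:", paste(names(object@discardReasons),
                             object@discardReasons, sep = "=",
                             collapse = "; "), "\n")
})

#' Mature loci of a prediction set
#'
#' @param x a [MirnaPredictions-class] object.
#' @return The underlying GRanges of mature loci.
#' @export
matureLoci <- function(x) x@mature

#' @rdname matureLoci
#' @export
stageCounts <- function(x) x@stageCounts

#' @rdname matureLoci
#' @export
discardReasons <- function(x) x@discardReasons

#' Predictions as a plain data.frame
#'
#' Flattens a [MirnaPredictions-class] object into the CSV column
#' layout; all coordinates are genome-forward and 1-based inclusive.
#'
#' @param x a [MirnaPredictions-class] object.
#' @return A data.frame with one row per prediction.
#' @export
predictionsAsDataFrame <- function(x) {
  gr <- x@mature
  mc <- mcols(gr)
  data.frame(
    chromosome = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    matureSequence = mc$sequence,
    matureStart = start(gr), matureEnd = end(gr),
    starSequence = mc$starSequence,
    starStart = mc$starStart, starEnd = mc$starEnd,
    starAbundance = mc$starAbundance,
    precursorStart = mc$precursorStart, precursorEnd = mc$precursorEnd,
    precursorLength = mc$precursorEnd - mc$precursorStart + 1L,
    mfe = mc$mfe, amfe = mc$amfe, pRandom = mc$pRandom,
    score = mc$score, scoreStruct = mc$scoreStruct,
    scoreStar = mc$scoreStar, scoreSignature = mc$scoreSignature,
    annotation = mc$annotation,
    matureAbundance = mc$abundance,
    stringsAsFactors = FALSE)
}
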