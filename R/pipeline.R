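.incidentReads <- function(reads, candidate, flank) {
  sel <- as.character(seqnames(reads)) == as.character(seqnames(candidate)) &
    as.character(strand(reads)) == as.character(strand(candidate)) &
    end(reads) >= start(candidate) - flank &
    start(reads) <= end(candidate) + flank
  reads[sel]
}

.annotationStatus <- function(mature, annotation) {
  if (is.null(annotation)) return("unannotated")
  ann <- annotation[annotation$type == "miRNA"]
  if (length(ann) == 0L) ann <- annotation
  hits <- findOverlaps(mature, ann, minoverlap = 1L)
  if (length(hits) == 0L) return("novel")
  conf <- ann$confidence[subjectHits(hits)[1L]]
  if (!is.na(conf) && conf %in% c("high", "high_confidence"))
    "high_confidence"
  else if (!is.na(conf)) "low_confidence"
  else "low_confidence"
}

#' Run the full miRNA prediction pipeline
#'
#' Maps the reads (unless pre-computed hits are supplied), detects
#' abundance-peak candidates with the divergence statistic, applies the
#' repeat, size-class and precise-processing filters, folds the
#' surrounding sequence and keeps candidates with an admissible hairpin
#' precursor, infers the miRNA*, and scores each surviving prediction.
#' Deterministic for fixed inputs and seed; an empty prediction set is a
#' valid outcome.
#'
#' @param genome named [Biostrings::DNAStringSet] (see
#'   [readGenomeFasta()]).
#' @param reads read data.frame from [readSrnaFasta()]; ignored when
#'   `hits` is given.
#' @param params a [PredictionParams-class] profile.
#' @param annotation optional GRanges from [readMirnaAnnotation()].
#' @param hits optional pre-computed PatMaN hits data.frame
#'   ([readPatman()]); bypasses internal mapping.
#' @param verbose print per-stage counts.
#' @return A [MirnaPredictions-class] object.
#' @export
runPredict <- function(genome, reads, params, annotation = NULL,
                       hits = NULL, verbose = FALSE) {
  mapped <- if (!is.null(hits)) patmanToMappedReads(hits, genome)
            else mapReads(reads, genome)
  if (length(mapped) == 0L)
    warning("no reads map to the genome; returning empty prediction set")
  wparams <- params@window
  fparams <- params@filter
  sparams <- params@structure
  scparams <- params@score
  candidates <- collectCandidates(mapped, genome, wparams)
  # deterministic candidate order: most abundant first, so each locus is
  # reported through its dominant (mature) read and the star / isomiR
  # candidates of the same precursor are absorbed into that prediction
  if (length(candidates)) {
    candidates <- candidates[order(-mcols(candidates)$abundance,
                                   as.character(seqnames(candidates)),
                                   start(candidates),
                                   as.character(strand(candidates)),
                                   mcols(candidates)$sequence)]
  }
  reasons <- character(0)
  counts <- c(mappedReads = length(mapped), candidates = length(candidates),
              afterRepeat = 0L, afterSizeClass = 0L, afterPrecise = 0L,
              predictions = 0L)
  rows <- list()
  accepted <- data.frame(chrom = character(), strand = character(),
                         start = integer(), end = integer())
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    inAccepted <- accepted$chrom == as.character(seqnames(cand)) &
      accepted$strand == as.character(strand(cand)) &
      accepted$start <= end(cand) & accepted$end >= start(cand)
    if (any(inAccepted)) { reasons <- c(reasons, "within predicted locus"); next }
    v <- repeatFilter(cand, fparams)
    if (!v$keep) { reasons <- c(reasons, v$reason); next }
    counts["afterRepeat"] <- counts["afterRepeat"] + 1L
    incident <- .incidentReads(mapped, cand, sparams@maxFoldLen)
    v <- sizeClassFilter(cand, incident, fparams)
    if (!v$keep) { reasons <- c(reasons, v$reason); next }
    counts["afterSizeClass"] <- counts["afterSizeClass"] + 1L
    clusters <- buildClusters(incident, fparams)
    v <- preciseProcessingFilter(cand, clusters, fparams)
    if (!v$keep) { reasons <- c(reasons, v$reason); next }
    counts["afterPrecise"] <- counts["afterPrecise"] + 1L
    prec <- foldCandidateWindow(cand, genome, sparams,
                                backend = params@backend)
    if (is.null(prec)) { reasons <- c(reasons, "no admissible hairpin"); next }
    counts["predictions"] <- counts["predictions"] + 1L
    # star read evidence: reads whose coordinates match the inferred star
    # span within clearCut on both ends
    starSeq <- NA_character_
    starAb <- NA_integer_
    starG <- c(NA_integer_, NA_integer_)
    if (!is.null(prec$star)) {
      if (prec$strand == "-") {
        starG <- c(prec$end - prec$star$end + 1L,
                   prec$end - prec$star$start + 1L)
      } else {
        starG <- c(prec$start + prec$star$start - 1L,
                   prec$start + prec$star$end - 1L)
      }
      starSeq <- chartr("U", "T",
                        substr(prec$sequence, prec$star$start,
                               prec$star$end))
      starReads <- incident[abs(start(incident) - starG[1L]) <=
                              fparams@clearCut &
                            abs(end(incident) - starG[2L]) <=
                              fparams@clearCut]
      starAb <- if (length(starReads))
        sum(mcols(starReads)$abundance) else NA_integer_
    }
    # signature fraction: abundance within clearCut of mature or star
    # over the total abundance on the precursor span
    onPrec <- incident[end(incident) >= prec$start &
                       start(incident) <= prec$end]
    atMature <- abs(start(onPrec) - start(cand)) <= fparams@clearCut &
      abs(end(onPrec) - end(cand)) <= fparams@clearCut
    atStar <- if (!is.null(prec$star) && !is.na(starG[1L])) {
      abs(start(onPrec) - starG[1L]) <= fparams@clearCut &
        abs(end(onPrec) - starG[2L]) <= fparams@clearCut
    } else rep(FALSE, length(onPrec))
    totalAb <- sum(mcols(onPrec)$abundance)
    sigFrac <- if (totalAb > 0)
      sum(mcols(onPrec)$abundance[atMature | atStar]) / totalAb else 0
    pRandom <- randomizationPvalue(prec$sequence,
                                   nShuffles = scparams@nShuffles,
                                   seed = scparams@seed)
    sc <- predictionScore(pRandom, starDetected = !is.na(starAb),
                          starAbundance = ifelse(is.na(starAb), 0, starAb),
                          signatureFraction = sigFrac)
    gr <- GRanges(prec$chrom, IRanges(start(cand), end(cand)),
                  strand = prec$strand)
    mcols(gr) <- DataFrame(
      id = mcols(cand)$id, sequence = mcols(cand)$sequence,
      abundance = mcols(cand)$abundance,
      genomeHits = mcols(cand)$genomeHits,
      starSequence = starSeq, starStart = starG[1L], starEnd = starG[2L],
      starAbundance = starAb,
      precursorStart = prec$start, precursorEnd = prec$end,
      precursorSequence = prec$sequence, structure = prec$structure,
      mfe = prec$mfe, amfe = prec$amfe, pRandom = pRandom,
      score = sc$total, scoreStruct = sc$sStruct, scoreStar = sc$sStar,
      scoreSignature = sc$sSignature,
      annotation = .annotationStatus(gr, annotation))
    rows[[length(rows) + 1L]] <- gr
    accepted <- rbind(accepted, data.frame(
      chrom = prec$chrom, strand = prec$strand, start = prec$start,
      end = prec$end))
  }
  mature <- if (length(rows)) do.call(c, unname(rows)) else {
    gr <- GRanges()
    mcols(gr) <- DataFrame(
      id = character(), sequence = character(), abundance = integer(),
      genomeHits = integer(), starSequence = character(),
      starStart = integer(), starEnd = integer(), starAbundance = integer(),
      precursorStart = integer(), precursorEnd = integer(),
      precursorSequence = character(), structure = character(),
      mfe = numeric(), amfe = numeric(), pRandom = numeric(),
      score = numeric(), scoreStruct = numeric(), scoreStar = numeric(),
      scoreSignature = numeric(), annotation = character())
    gr
  }
  if (!is.na(params@score@minScore) && length(mature))
    mature <- mature[mcols(mature)$score >= params@score@minScore]
  tab <- table(reasons)
  pred <- new("MirnaPredictions", mature = mature, params = params,
              backend = params@backend, stageCounts = counts,
              discardReasons = setNames(as.integer(tab), names(tab)))
  if (verbose) show(pred)
  pred
}

#' Write all run outputs to a directory
#'
#' Emits the PatMaN coordinates file of predicted matures
#' (`predictions.patman`), the results CSV (`predictions.csv`), one
#' plain-text alignment report per precursor under `alignments/`, a run
#' log with per-stage counts (`run_log.txt`) and the resolved
#' configuration (`config.yml`).
#'
#' @param predictions a [MirnaPredictions-class] object.
#' @param mapped the mapped reads GRanges used for the run (for the
#'   alignment reports); may be NULL to skip reports.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writePredictionOutputs <- function(predictions, mapped, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mature <- predictions@mature
  patman <- data.frame(
    target = as.character(seqnames(mature)),
    query = paste0(mcols(mature)$sequence, "_", mcols(mature)$abundance),
    start = start(mature), end = end(mature),
    strand = as.character(strand(mature)), mismatches = 0L,
    stringsAsFactors = FALSE)
  writePatman(patman, file.path(dir, "predictions.patman"))
  writeResultsCsv(predictions, file.path(dir, "predictions.csv"))
  if (!is.null(mapped) && length(mature)) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_along(mature)) {
      mc <- mcols(mature[i])
      prec <- list(chrom = as.character(seqnames(mature[i])),
                   start = mc$precursorStart, end = mc$precursorEnd,
                   strand = as.character(strand(mature[i])),
                   sequence = mc$precursorSequence,
                   structure = mc$structure, mfe = mc$mfe)
      sel <- as.character(seqnames(mapped)) == prec$chrom &
        as.character(strand(mapped)) == prec$strand &
        start(mapped) >= prec$start & end(mapped) <= prec$end
      inc <- mapped[sel]
      if (prec$strand == "-") {
        mcols(inc)$sequence <- mcols(inc)$sequence  # already read 5'->3'
      }
      writeAlignmentReport(prec, inc,
                           file.path(adir, sprintf("precursor_%03d.txt", i)))
    }
  }
  log <- c(sprintf("stage %s: %d", names(predictions@stageCounts),
                   predictions@stageCounts),
           if (length(predictions@discardReasons))
             sprintf("discard [%s]: %d", names(predictions@discardReasons),
                     predictions@discardReasons))
  writeLines(log, file.path(dir, "run_log.txt"))
  yaml::write_yaml(paramsAsList(predictions@params),
                   file.path(dir, "config.yml"))
  invisible(dir)
}
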