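#' Read a reference genome from FASTA
#'
#' Loads all records, uppercases them and converts U to T. The resulting
#' alphabet is restricted to A, C, G, T, N.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgu"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate chromosome id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(gsub("U", "T", toupper(as.character(raw))))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid characters in genome record: ", ids[bad][1L])
  genome <- DNAStringSet(seqs)
  names(genome) <- ids
  genome
}

#' Read abundance-annotated small RNA reads
#'
#' Parses adapter-trimmed, non-redundant small RNA reads whose abundance
#' is encoded in the FASTA header. Three dialects are supported:
#' `suffix_count` (">id_25" or ">id-25"), `paren_count` (">id(25)") and
#' `collapse` (redundant FASTA; identical sequences are merged and
#' counted).
#'
#' @param path path to a FASTA file.
#' @param dialect abundance encoding, see Description.
#' @return A data.frame with columns `id`, `sequence` (A/C/G/T,
#'   uppercase) and `abundance` (integer >= 1); sequences are unique.
#' @export
readSrnaFasta <- function(path,
                          dialect = c("suffix_count", "paren_count",
                                      "collapse")) {
  dialect <- match.arg(dialect)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  seqs <- toupper(gsub("U", "T", toupper(as.character(raw))))
  if (dialect == "collapse") {
    tab <- tapply(rep(1L, length(seqs)), seqs, sum)
    df <- data.frame(id = paste0("r", seq_along(tab)),
                     sequence = names(tab),
                     abundance = as.integer(tab),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    return(df)
  }
  pattern <- if (dialect == "suffix_count") "^(.*)[_-]([0-9]+)\\s*$"
             else "^(.*)\\(([0-9]+)\\)\\s*$"
  ok <- grepl(pattern, headers)
  if (!all(ok)) {
    stop("header without abundance token (", dialect, ") at record ",
         which(!ok)[1L], ": '", headers[!ok][1L], "'")
  }
  ab <- as.integer(sub(pattern, "\\2", headers))
  id <- sub(pattern, "\\1", headers)
  if (any(ab < 1L)) stop("abundance must be >= 1")
  if (anyDuplicated(seqs)) {
    dup <- seqs[duplicated(seqs)][1L]
    stop("input is not non-redundant; duplicated sequence: ", dup)
  }
  data.frame(id = id, sequence = seqs, abundance = ab,
             stringsAsFactors = FALSE)
}

#' Write small RNA reads with abundance-suffix headers
#'
#' Inverse of [readSrnaFasta()] for the `suffix_count` dialect.
#'
#' @param reads data.frame with `id`, `sequence`, `abundance` columns.
#' @param path output path.
#' @export
writeSrnaFasta <- function(reads, path) {
  lines <- as.vector(rbind(paste0(">", reads$id, "_", reads$abundance),
                           reads$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write PatMaN hit files
#'
#' PatMaN hits are tab-separated with columns target, query, start, end,
#' strand, mismatches; coordinates are 1-based inclusive. On the minus
#' strand the start column still holds the smaller coordinate.
#'
#' @param hits data.frame with columns `target`, `query`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @param path file path.
#' @return `readPatman` returns a data.frame in the layout above.
#' @export
writePatman <- function(hits, path) {
  df <- hits[, c("target", "query", "start", "end", "strand", "mismatches")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePatman
#' @export
readPatman <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(target = character(), query = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed PatMaN line ", which(nf != 6L)[1L], ": expected 6 fields")
  m <- do.call(rbind, fields)
  df <- data.frame(target = m[, 1L], query = m[, 2L],
                   start = suppressWarnings(as.integer(m[, 3L])),
                   end = suppressWarnings(as.integer(m[, 4L])),
                   strand = m[, 5L],
                   mismatches = suppressWarnings(as.integer(m[, 6L])),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$start) | is.na(df$end) | df$end < df$start |
    !df$strand %in% c("+", "-")
  if (any(bad)) stop("malformed PatMaN line ", which(bad)[1L])
  df
}

#' Convert mapped reads to and from PatMaN layout
#'
#' @param reads a GRanges of mapped reads with `sequence` and `abundance`
#'   metadata columns (as returned by [mapReads()]).
#' @return A PatMaN data.frame; query tokens are `<id>_<abundance>`.
#' @export
mappedReadsToPatman <- function(reads) {
  mc <- mcols(reads)
  id <- if (!is.null(mc$id)) mc$id else mc$sequence
  data.frame(target = as.character(seqnames(reads)),
             query = paste0(id, "_", mc$abundance),
             start = start(reads), end = end(reads),
             strand = as.character(strand(reads)),
             mismatches = 0L, stringsAsFactors = FALSE)
}

#' @rdname mappedReadsToPatman
#' @param hits a PatMaN data.frame, as from [readPatman()].
#' @param genome a [Biostrings::DNAStringSet]; used to recover the read
#'   sequence at each placement.
#' @export
patmanToMappedReads <- function(hits, genome) {
  if (nrow(hits) == 0L) return(.emptyMappedReads())
  seqs <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- subseq(genome[[hits$target[i]]], hits$start[i], hits$end[i])
    if (hits$strand[i] == "-") s <- reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  ab <- as.integer(sub("^.*_([0-9]+)$", "\\1", hits$query))
  id <- sub("_[0-9]+$", "", hits$query)
  gr <- GRanges(hits$target, IRanges(hits$start, hits$end),
                strand = hits$strand)
  mcols(gr) <- DataFrame(id = id, sequence = seqs, abundance = ab)
  hitsPerSeq <- table(seqs)
  gr$genomeHits <- as.integer(hitsPerSeq[seqs])
  gr
}

#' Read a miRNA annotation from GFF3
#'
#' Imports features of type `miRNA` (mature) and
#' `miRNA_primary_transcript` (precursor). A `confidence` attribute, when
#' present, is retained for high/low-confidence bookkeeping.
#'
#' @param path path to a GFF3 file.
#' @return A GRanges with metadata columns `type`, `Name` (if present)
#'   and `confidence` (NA when absent).
#' @export
readMirnaAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("miRNA", "miRNA_primary_transcript")]
  if (is.null(mcols(gr)$confidence)) gr$confidence <- NA_character_
  gr
}

.predictionCsvColumns <- c(
  "chromosome", "strand", "matureSequence", "matureStart", "matureEnd",
  "starSequence", "starStart", "starEnd", "starAbundance",
  "precursorStart", "precursorEnd", "precursorLength",
  "mfe", "amfe", "pRandom", "score", "scoreStruct", "scoreStar",
  "scoreSignature", "annotation", "matureAbundance")

#' Write prediction results as CSV
#'
#' One row per prediction: genomic coordinates of mature, star and
#' precursor, the precursor MFE/aMFE, the randomization p-value, the
#' score and its components, the annotation overlap (or "novel") and the
#' mature/star abundances. Star fields are empty strings when no star was
#' detected.
#'
#' @param predictions a [MirnaPredictions-class] object or the
#'   data.frame from [predictionsAsDataFrame()].
#' @param path output path.
#' @export
writeResultsCsv <- function(predictions, path) {
  df <- if (is(predictions, "MirnaPredictions"))
    predictionsAsDataFrame(predictions) else predictions
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(
      rep(list(character(0)), length(.predictionCsvColumns)),
      .predictionCsvColumns))
  } else {
    df <- df[, .predictionCsvColumns]
    for (col in c("starSequence", "starStart", "starEnd", "starAbundance")) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-precursor read alignment report
#'
#' Plain-text stack plot of the reads incident to one precursor: the
#' precursor sequence on the first line, one line per read padded to its
#' offset with its raw abundance at the end, and a final line with the
#' dot-bracket structure and the MFE. Reads are shown 5'->3' on the
#' precursor's own strand; minus-strand reads are reverse-complemented
#' into precursor orientation.
#'
#' @param precursor list with elements `chrom`, `start`, `end`, `strand`,
#'   `sequence`, `structure`, `mfe` (genomic coordinates, 1-based).
#' @param reads GRanges of incident reads with `sequence` and `abundance`
#'   metadata; all must fall within the precursor span.
#' @param path output path (or connection).
#' @export
writeAlignmentReport <- function(precursor, reads, path) {
  pLen <- precursor$end - precursor$start + 1L
  lines <- precursor$sequence
  if (length(reads)) {
    inside <- start(reads) >= precursor$start & end(reads) <= precursor$end
    if (!all(inside)) stop("read outside precursor span")
    off <- if (precursor$strand == "-") {
      precursor$end - end(reads)
    } else {
      start(reads) - precursor$start
    }
    ord <- order(off, -mcols(reads)$abundance)
    for (i in ord) {
      seqTxt <- mcols(reads)$sequence[i]
      pad <- strrep(".", off[i])
      tail <- strrep(".", max(0L, pLen - off[i] - nchar(seqTxt)))
      lines <- c(lines, paste0(pad, seqTxt, tail, "  ",
                               mcols(reads)$abundance[i]))
    }
  }
  lines <- c(lines, sprintf("%s (%.2f)", precursor$structure, precursor$mfe))
  writeLines(lines, path)
  invisible(path)
}
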