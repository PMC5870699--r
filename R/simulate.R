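#' Specification of one implanted locus
#'
#' Describes a synthetic locus to implant into a simulated genome:
#' either a miRNA-like stem-loop (mature/star read stacks over a
#' reverse-complementary hairpin) or a hairpin-free control stack
#' emulating a sharply processed non-miRNA RNA fragment (tRNA/snoRNA
#' like), which carries reads but no implanted secondary structure.
#'
#' @param position 1-based genomic start of the implant.
#' @param strand "+" or "-".
#' @param matureArm "5p" or "3p".
#' @param stemLen stem length (bp).
#' @param stemMismatches number of non-pairing mismatches introduced into
#'   the 3' arm of the stem (real miRNA duplexes are imperfect).
#' @param loopLen terminal loop length (nt).
#' @param matureAbundance,starAbundance read-stack abundances.
#' @param jitterProb per-read probability of a +/-1 nt end shift
#'   (isomiR-like raggedness).
#' @param ablated logical: is the locus depleted in the mutant sample?
#' @param hairpin logical: implant the stem-loop sequence? FALSE for
#'   control stacks.
#' @return A one-row data.frame (an implant spec).
#' @export
hairpinSpec <- function(position, strand = "+", matureArm = "5p",
                        stemLen = 25L, loopLen = 10L,
                        stemMismatches = 2L,
                        matureAbundance = 100L, starAbundance = 30L,
                        jitterProb = 0.1, ablated = FALSE,
                        hairpin = TRUE) {
  data.frame(position = as.integer(position), strand = strand,
             matureArm = matureArm, stemLen = as.integer(stemLen),
             loopLen = as.integer(loopLen),
             stemMismatches = as.integer(stemMismatches),
             matureAbundance = as.integer(matureAbundance),
             starAbundance = as.integer(starAbundance),
             jitterProb = jitterProb, ablated = ablated,
             hairpin = hairpin, stringsAsFactors = FALSE)
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# a base that neither Watson-Crick- nor wobble-pairs with `b`
.nonPairingBase <- function(b) {
  switch(b, A = "C", C = "C", G = "A", T = "C")
}

.revcomp <- function(s) as.character(reverseComplement(DNAString(s)))

#' Simulate a genome with implanted hairpin loci
#'
#' Background nucleotides are i.i.d. uniform; each hairpin implant
#' overwrites the background with stem + loop + reverse-complemented
#' stem at its stated position. An optional tandem-repeat block supports
#' repetitive-locus tests. Deterministic per seed.
#'
#' @param specs data.frame of implant specs (rbind of [hairpinSpec()]
#'   rows); implants must not overlap.
#' @param backgroundLen genome length (nt).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param repeatBlock optional list(unit = <string>, copies = <int>,
#'   position = <int>): a tandem repeat implanted verbatim.
#' @return list(genome = DNAStringSet, truth = data.frame) where `truth`
#'   records, per locus, the genomic mature/star/precursor spans, the
#'   intended abundances, the `ablated` flag and the locus type.
#' @export
simulateGenome <- function(specs, backgroundLen = 50000L, seed = 1L,
                           chrom = "chr1", repeatBlock = NULL) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), backgroundLen, replace = TRUE)
    truthRows <- list()
    spans <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      hpLen <- 2L * sp$stemLen + sp$loopLen
      lo <- sp$position
      hi <- sp$position + hpLen - 1L
      if (hi > backgroundLen) stop("implant ", i, " beyond genome end")
      if (nrow(spans) &&
          any(pmax(spans[, 1], lo) <= pmin(spans[, 2], hi)))
        stop("overlapping implants")
      spans <- rbind(spans, c(lo, hi))
      stem <- .randSeq(sp$stemLen)
      loop <- .randSeq(sp$loopLen)
      if (sp$hairpin) {
        hpChars <- strsplit(paste0(stem, loop, .revcomp(stem)), "")[[1L]]
        # break Watson-Crick (and wobble) pairing at a few interior stem
        # positions of the 3' arm, spread evenly over the duplex region
        m <- sp$stemMismatches
        if (m > 0L) {
          stemIdx <- pmin(sp$stemLen - 2L,
                          pmax(3L, round(seq_len(m) * sp$stemLen / (m + 1))))
          stemChars <- strsplit(stem, "")[[1L]]
          for (si in unique(stemIdx)) {
            hpChars[hpLen + 1L - si] <- .nonPairingBase(stemChars[si])
          }
        }
        chars[lo:hi] <- hpChars
      }
      # mature occupies hairpin positions 3..23 of the chosen arm so the
      # inferred star (2 nt 3' overhang) stays inside the precursor
      matLen <- 21L
      if (sp$matureArm == "5p") {
        mLo <- 3L; mHi <- mLo + matLen - 1L
      } else {
        mHi <- hpLen - 2L; mLo <- mHi - matLen + 1L
      }
      # star = duplex partner shifted by the 2 nt overhang
      pt <- function(k) hpLen + 1L - k
      if (sp$matureArm == "5p") {
        sLo <- pt(mHi) + 2L; sHi <- pt(mLo) + 2L
      } else {
        sLo <- pt(mHi) - 2L; sHi <- pt(mLo) - 2L
      }
      toGenomic <- function(localLo, localHi) {
        if (sp$strand == "+") c(lo + localLo - 1L, lo + localHi - 1L)
        else c(hi - localHi + 1L, hi - localLo + 1L)
      }
      mG <- toGenomic(mLo, mHi)
      sG <- toGenomic(sLo, sHi)
      truthRows[[i]] <- data.frame(
        locus = paste0("locus", i), chrom = chrom, strand = sp$strand,
        precStart = lo, precEnd = hi,
        matureStart = mG[1L], matureEnd = mG[2L],
        starStart = sG[1L], starEnd = sG[2L],
        matureAbundance = sp$matureAbundance,
        starAbundance = sp$starAbundance, jitterProb = sp$jitterProb,
        ablated = sp$ablated,
        type = if (sp$hairpin) "mirna" else "control",
        stringsAsFactors = FALSE)
    }
    if (!is.null(repeatBlock)) {
      unitChars <- strsplit(strrep(repeatBlock$unit, repeatBlock$copies),
                            "")[[1L]]
      lo <- repeatBlock$position
      hi <- lo + length(unitChars) - 1L
      if (hi > backgroundLen) stop("repeat block beyond genome end")
      chars[lo:hi] <- unitChars
    }
    genome <- DNAStringSet(setNames(paste(chars, collapse = ""), chrom))
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame()
    list(genome = genome, truth = truth)
  })
}

.stackReads <- function(genome, truth, lo, hi, strandChar, n, jitterProb) {
  if (n <= 0L) return(character(0))
  shift5 <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                   prob = c(jitterProb / 2, 1 - jitterProb, jitterProb / 2))
  shift3 <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                   prob = c(jitterProb / 2, 1 - jitterProb, jitterProb / 2))
  starts <- pmax(1L, lo + shift5)
  ends <- pmin(length(genome[[truth$chrom[1L]]]), hi + shift3)
  vapply(seq_len(n), function(k) {
    s <- subseq(genome[[truth$chrom[1L]]], starts[k], ends[k])
    if (strandChar == "-") s <- reverseComplement(s)
    as.character(s)
  }, character(1))
}

#' Simulate a small RNA read set over a simulated genome
#'
#' For every non-depleted locus of the ground truth, emits mature and
#' star read stacks at their stated abundances with isomiR-like +/-1 nt
#' jitter; in the mutant sample, stacks of `ablated` loci are multiplied
#' by `ablationFactor`, emulating a Dicer/DCL1/Drosha/DGCR8 knock-out.
#' Degradation background reads of random length (16-28 nt) and strand
#' are scattered uniformly at `degradationRate` reads per kb. Identical
#' sequences are collapsed into one record with summed abundance, so the
#' output satisfies the non-redundant input contract.
#'
#' @param sim output of [simulateGenome()].
#' @param sample "wildtype" or "mutant".
#' @param depthMultiplier scales every abundance.
#' @param degradationRate degradation reads per kb of genome.
#' @param ablationFactor abundance multiplier for ablated loci in the
#'   mutant sample (default 0.1).
#' @param seed RNG seed.
#' @return A read data.frame (`id`, `sequence`, `abundance`) in the same
#'   layout as [readSrnaFasta()].
#' @export
simulateReads <- function(sim, sample = c("wildtype", "mutant"),
                          depthMultiplier = 1, degradationRate = 20,
                          ablationFactor = 0.1, seed = 1L) {
  sampleName <- match.arg(sample)
  genome <- sim$genome
  truth <- sim$truth
  withr::with_seed(seed + ifelse(sampleName == "mutant", 10000L, 0L), {
    seqs <- character(0)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      fac <- if (sampleName == "mutant" && tr$ablated) ablationFactor else 1
      nMat <- round(tr$matureAbundance * depthMultiplier * fac)
      nStar <- round(tr$starAbundance * depthMultiplier * fac)
      seqs <- c(seqs,
                .stackReads(genome, truth, tr$matureStart, tr$matureEnd,
                            tr$strand, nMat, tr$jitterProb),
                if (tr$type == "mirna")
                  .stackReads(genome, truth, tr$starStart, tr$starEnd,
                              tr$strand, nStar, tr$jitterProb))
    }
    gLen <- sum(width(genome))
    nDeg <- round(degradationRate * gLen / 1000 * depthMultiplier)
    if (nDeg > 0) {
      degLen <- sample(16:28, nDeg, replace = TRUE)
      degStart <- vapply(degLen, function(l)
        sample.int(gLen - l + 1L, 1L), integer(1))
      degStrand <- sample(c("+", "-"), nDeg, replace = TRUE)
      chromName <- names(genome)[1L]
      degSeqs <- vapply(seq_len(nDeg), function(k) {
        s <- subseq(genome[[chromName]], degStart[k],
                    degStart[k] + degLen[k] - 1L)
        if (degStrand[k] == "-") s <- reverseComplement(s)
        as.character(s)
      }, character(1))
      seqs <- c(seqs, degSeqs)
    }
    tab <- tapply(rep(1L, length(seqs)), seqs, sum)
    data.frame(id = paste0(substr(sampleName, 1, 2), seq_along(tab)),
               sequence = names(tab), abundance = as.integer(tab),
               stringsAsFactors = FALSE)
  })
}

#' Build the default test fixture
#'
#' Convenience wrapper producing the standard study conditions used
#' throughout the test-suite: `nLoci` miRNA hairpin loci evenly spread
#' over a `genomeLen` nt genome (alternating strand and arm), of which
#' `nAblated` are depleted in the mutant, plus `nControls` hairpin-free
#' control stacks, with a degradation background.
#'
#' @param nLoci number of implanted miRNA loci.
#' @param genomeLen genome length (nt).
#' @param nAblated number of miRNA loci depleted in the mutant sample.
#' @param nControls number of hairpin-free control loci.
#' @param degradationRate degradation reads per kb.
#' @param seed RNG seed governing genome, truth and read sets.
#' @return list(genome, truth, wildtype, mutant): the simulated genome
#'   and ground truth plus wild-type and mutant read data.frames.
#' @export
simulateFixture <- function(nLoci = 10L, genomeLen = 50000L,
                            nAblated = 7L, nControls = 0L,
                            degradationRate = 20, seed = 1L) {
  nAblated <- min(nAblated, nLoci)
  total <- nLoci + nControls
  gap <- genomeLen %/% (total + 1L)
  specs <- do.call(rbind, lapply(seq_len(total), function(i) {
    hairpinSpec(position = i * gap,
                strand = if (i %% 2 == 0) "-" else "+",
                matureArm = if (i %% 4 < 2) "5p" else "3p",
                ablated = i <= nAblated,
                hairpin = i <= nLoci)
  }))
  sim <- simulateGenome(specs, backgroundLen = genomeLen, seed = seed)
  wt <- simulateReads(sim, "wildtype", degradationRate = degradationRate,
                      seed = seed)
  mut <- simulateReads(sim, "mutant", degradationRate = degradationRate,
                       seed = seed)
  list(genome = sim$genome, truth = sim$truth, wildtype = wt, mutant = mut)
}
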