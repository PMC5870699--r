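test_that("median-scaled RPM normalization follows its formula", {
  m <- matrix(c(10, 20, 30, 40), nrow = 2,
              dimnames = list(NULL, c("a", "b")))
  # equal library sizes: unchanged
  expect_equal(normalizeRpmMedian(m, c(1e6, 1e6)), m)

  # count 10 in a 2M library with median 1M scales to 5
  m2 <- matrix(c(10, 0), nrow = 1, dimnames = list(NULL, c("a", "b")))
  norm <- normalizeRpmMedian(m2, c(2e6, 5e5))
  expect_equal(unname(norm[1, "a"]), 10 / 2e6 * median(c(2e6, 5e5)))

  expect_error(normalizeRpmMedian(m, c(0, 1e6)), "zero library")

  # idempotence once library sizes are recomputed from normalized data
  libs <- c(2e6, 1e6, 5e5)
  m3 <- matrix(runif(9, 1, 100) * rep(libs / 1e6, each = 3), nrow = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  n1 <- normalizeRpmMedian(m3, libs)
  # after normalization every column was scaled by median/lib; rescaling
  # with the implied new library sizes is a no-op
  newLibs <- libs * (median(libs) / libs)
  expect_equal(normalizeRpmMedian(n1, newLibs), n1)
})

test_that("log2 fold changes handle zeros through the pseudo-count", {
  expect_equal(log2FoldChange(5, 5), 0)
  expect_equal(log2FoldChange(20, 5, pseudo = 0), 2)
  expect_equal(log2FoldChange(0, 0, pseudo = 1), 0)
  expect_error(log2FoldChange(-1, 5))
})

test_that("downregulated fraction treats the 2-fold boundary inclusively", {
  wt <- c(10, 20, 40)
  exactlyHalved <- (wt + 1) / 2 - 1   # log2FC exactly 1 with pseudo 1
  expect_equal(downregulatedFraction(wt, exactlyHalved)$fraction, 1)
  expect_equal(downregulatedFraction(wt, wt)$fraction, 0)
  expect_error(downregulatedFraction(numeric(0), numeric(0)), "empty")

  r <- downregulatedFraction(c(40, 10), c(4, 10))
  expect_equal(r$fraction, 0.5)
  expect_equal(r$sortedLfc, sort(r$lfc))
})

test_that("quantification sums same-strand overlapping read abundance", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120),
                                 strand = "+")
  reads <- makeReads(data.frame(start = c(100, 110, 300),
                                end = c(120, 130, 320),
                                abundance = c(50L, 5L, 99L),
                                sequence = c("A", "B", "C")))
  se <- quantifyLoci(loci, list(s1 = reads))
  expect_equal(unname(SummarizedExperiment::assay(se, "counts")[1, 1]), 55)
  expect_equal(unname(SummarizedExperiment::colData(se)$librarySize), 154)

  minusReads <- makeReads(data.frame(start = 100, end = 120,
                                     abundance = 7L, strand = "-",
                                     sequence = "D"))
  se2 <- quantifyLoci(loci, list(s1 = minusReads))
  expect_equal(unname(SummarizedExperiment::assay(se2, "counts")[1, 1]), 0)
})

test_that("annotation comparison counts match a hand-worked toy", {
  # 5 annotated precursors (all expressed), matching mature entries;
  # 4 predictions of which 2 overlap annotated matures
  annPrec <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 300, 500, 700, 900), width = 80),
    strand = "+", type = "miRNA_primary_transcript")
  annMat <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110, 310, 510, 710, 910), width = 21),
    strand = "+", type = "miRNA")
  ann <- c(annPrec, annMat)
  ann$confidence <- NA_character_
  preds <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110, 310, 2000, 3000), width = 21),
    strand = "+")
  reads <- makeReads(data.frame(
    start = c(110, 310, 510, 710, 910), end = c(130, 330, 530, 730, 930),
    abundance = 1L, sequence = paste0("s", 1:5)))
  res <- evaluateAgainstAnnotation(preds, ann, reads)
  expect_equal(res$specificity, 50)
  expect_equal(res$sensitivity, 40)
  expect_equal(res$nExpressed, 5L)
  expect_equal(res$nDetected, 2L)
  expect_equal(res$nNovel, 2L)

  # zero predictions: specificity undefined, sensitivity zero
  res0 <- evaluateAgainstAnnotation(preds[0], ann, reads)
  expect_true(is.na(res0$specificity))
  expect_equal(res0$sensitivity, 0)

  # all predictions matching
  res1 <- evaluateAgainstAnnotation(preds[1:2], ann, reads)
  expect_equal(res1$specificity, 100)
})
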