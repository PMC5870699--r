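fp <- filterParams(animalParams())

candAt <- function(start, end, abundance = 100L, genomeHits = 1L,
                   seqChar = "A") {
  makeReads(data.frame(start = start, end = end, abundance = abundance,
                       genomeHits = genomeHits,
                       sequence = strrep(seqChar, end - start + 1L)))
}

test_that("repeat filter reads 'more than repeats times' literally", {
  expect_true(repeatFilter(candAt(10, 30, genomeHits = 1L), fp)$keep)
  expect_true(repeatFilter(candAt(10, 30, genomeHits = 20L), fp)$keep)
  v <- repeatFilter(candAt(10, 30, genomeHits = 21L), fp)
  expect_false(v$keep)
  expect_match(v$reason, "repetitive")
})

test_that("size-class filter requires a dominant miRNA-length class", {
  cand <- candAt(100, 120)
  # all incident reads 21 nt: spiked histogram, dominant class 21
  all21 <- makeReads(data.frame(start = c(100, 100, 130),
                                end = c(120, 120, 150),
                                abundance = c(50L, 30L, 20L)))
  v <- sizeClassFilter(cand, all21, fp)
  expect_true(v$keep)
  expect_gt(v$kld, fp@rudVal)
  expect_equal(v$dominantLength, 21L)

  # equal abundance in every length class: divergence 0, discard
  lens <- 16:28
  uni <- makeReads(data.frame(start = 100, end = 100 + lens - 1,
                              abundance = 10L))
  v2 <- sizeClassFilter(cand, uni, fp)
  expect_false(v2$keep)
  expect_equal(v2$kld, 0)
  expect_match(v2$reason, "uniform")

  # dominant class 24 nt: high divergence but outside the miRNA range
  long24 <- makeReads(data.frame(start = c(100, 140), end = c(123, 163),
                                 abundance = c(80L, 40L)))
  v3 <- sizeClassFilter(cand, long24, fp)
  expect_false(v3$keep)
  expect_match(v3$reason, "outside")

  expect_false(sizeClassFilter(cand, all21[0], fp)$keep)
  expect_equal(sizeClassFilter(cand, all21[0], fp)$reason, "no reads")
})

test_that("cluster construction groups coordinate variants greedily", {
  one <- makeReads(data.frame(start = 50, end = 70, abundance = 12L))
  cl <- buildClusters(one, fp)
  expect_length(cl, 1L)
  expect_equal(attr(cl[[1]], "totalAbundance"), 12L)

  # starts differing by exactly clearCut with the same end shift: joined
  pair <- makeReads(data.frame(start = c(50, 53), end = c(70, 73),
                               abundance = c(10L, 5L)))
  expect_length(buildClusters(pair, fp), 1L)

  far <- makeReads(data.frame(start = c(50, 150), end = c(70, 170),
                              abundance = 1L))
  expect_length(buildClusters(far, fp), 2L)
})

test_that("cluster construction partitions its input", {
  withr::with_seed(3, {
    for (i in 1:10) {
      starts <- sort(sample(1:500, 30, replace = TRUE))
      reads <- makeReads(data.frame(start = starts,
                                    end = starts + sample(18:24, 30, TRUE),
                                    abundance = sample(1:50, 30, TRUE)))
      cl <- buildClusters(reads, fp)
      expect_equal(sum(lengths(cl)), length(reads))
      expect_equal(sum(vapply(cl, function(x)
        attr(x, "totalAbundance"), numeric(1))),
        sum(reads$abundance))
    }
  })
})

test_that("precise-processing criteria follow the excision arithmetic", {
  # (a) all abundance exactly at the candidate's coordinates: keep
  cand <- candAt(100, 120, abundance = 60L)
  clean <- c(cand, candAt(100, 120, abundance = 40L, seqChar = "G"))
  v <- preciseProcessingFilter(cand[1], buildClusters(clean, fp), fp)
  expect_true(v$keep)
  expect_equal(v$variantFraction, 100)

  # (b) the candidate's coordinate variants hold 40 of the cluster's 100
  # with threshold 75%: ragged ends, discard. The third read sits within
  # clearCut of the cluster seed but > clearCut from the candidate's end.
  mixed <- makeReads(data.frame(start = c(100, 101, 102),
                                end = c(120, 123, 117),
                                abundance = c(10L, 30L, 60L),
                                sequence = c(strrep("A", 21),
                                             strrep("C", 23),
                                             strrep("G", 16))))
  clusters <- buildClusters(mixed, fp)
  expect_length(clusters, 1L)   # all within clearCut of the seed
  vb <- preciseProcessingFilter(mixed[2], clusters, fp)
  expect_false(vb$keep)
  expect_equal(vb$reason, "ragged 5'/3' ends")
  expect_equal(vb$variantFraction, 40)  # only 10+30 at +/-3 of (101,123)

  # (c) adjacent overlapping cluster with 60 of 100: smeared, discard
  s <- candAt(100, 120, abundance = 100L)
  adjacent <- candAt(110, 130, abundance = 60L, seqChar = "C")
  vc <- preciseProcessingFilter(s, buildClusters(c(s, adjacent), fp), fp)
  expect_false(vc$keep)
  expect_equal(vc$reason, "overlapping degradation")
})

test_that("clean stacks pass and uniform degradation fails, by design", {
  withr::with_seed(9, {
    for (i in 1:5) {
      # clean miRNA-like stack: every read within 1 nt of the mature
      jit <- sample(-1:1, 12, replace = TRUE)
      stack <- makeReads(data.frame(
        start = 200 + jit, end = 220 + sample(-1:1, 12, TRUE),
        abundance = c(80L, sample(1:10, 11, TRUE)),
        sequence = vapply(1:12, function(k)
          randomDnaString(21), character(1))))
      cand <- stack[1]
      expect_true(preciseProcessingFilter(
        cand, buildClusters(stack, fp), fp)$keep)

      # uniform degradation: reads smeared across the whole region
      smearStart <- seq(150, 260, by = 5)
      smear <- makeReads(data.frame(
        start = smearStart, end = smearStart + 20,
        abundance = 10L,
        sequence = vapply(seq_along(smearStart), function(k)
          randomDnaString(21), character(1))))
      candS <- smear[which(start(smear) == 200)]
      expect_false(preciseProcessingFilter(
        candS, buildClusters(smear, fp), fp)$keep)
    }
  })
})
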