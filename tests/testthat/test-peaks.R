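wp <- windowParams(animalParams())

test_that("absolute-log divergence matches its definition", {
  expect_identical(kld(rep(1 / 4, 4), rep(1 / 4, 4)), 0)
  # |ln(4/3)|*(2/3) + |ln(2/3)|*(1/3)
  expect_equal(kld(c(2 / 3, 1 / 3), c(1 / 2, 1 / 2)), 0.32694, tolerance = 1e-4)
  expect_error(kld(c(0.5, 0.5), rep(1 / 3, 3)), "length")
  expect_error(kld(c(0, 1), c(0.5, 0.5)), "positive")
})

test_that("divergence dominates standard KL on random distributions", {
  withr::with_seed(1, {
    for (i in 1:100) {
      n <- sample(2:20, 1)
      p <- randomDistribution(n)
      q <- randomDistribution(n)
      d <- kld(p, q)
      expect_gte(d, 0)
      expect_gte(d, kldStandard(p, q) - 1e-12)
      expect_equal(d, kldOracle(p, q), tolerance = 1e-12)
    }
  })
})

test_that("window tiling advances by lW - lO and clips chromosome ends", {
  cfg <- new("WindowParams", lW = 100L, lO = 50L, lSw = 25L, rudVal = 0.35,
             plateauRange = 75L, offset = 1)
  w <- tileWindows(c(chr1 = 250L), cfg)
  plus <- w[w$strand == "+", ]
  expect_equal(plus$start, c(1L, 51L, 101L, 151L, 201L))
  expect_equal(plus$end[5], 250L)
  expect_equal(nrow(w), 2L * nrow(plus))

  short <- tileWindows(c(chr1 = 80L), cfg)
  expect_equal(nrow(short[short$strand == "+", ]), 1L)
  expect_equal(short$end[1], 80L)
})

test_that("window distributions follow the offset probability formula", {
  empty <- windowDistribution(makeReads(data.frame(start = 1, end = 21,
                                                   abundance = 1))[0],
                              "chr1", "+", 1L, 100L, wp)
  expect_equal(empty$P, rep(1 / 4, 4))
  expect_equal(kld(empty$P, rep(empty$Q, empty$nSub)), 0)

  reads <- makeReads(data.frame(start = 30, end = 50, abundance = 10))
  d <- windowDistribution(reads, "chr1", "+", 1L, 100L, wp)
  expect_equal(d$rSw, c(0, 10, 0, 0))
  expect_equal(d$P, c(1, 11, 1, 1) / 14)

  # a read straddling a subwindow boundary counts once, in its 5' subwindow
  strad <- makeReads(data.frame(start = 24, end = 44, abundance = 5))
  d2 <- windowDistribution(strad, "chr1", "+", 1L, 100L, wp)
  expect_equal(d2$rSw, c(5, 0, 0, 0))
  # on the minus strand the 5' end is the right coordinate
  stradM <- makeReads(data.frame(start = 24, end = 44, abundance = 5,
                                 strand = "-"))
  d3 <- windowDistribution(stradM, "chr1", "-", 1L, 100L, wp)
  expect_equal(d3$rSw, c(0, 5, 0, 0))
})

test_that("peak extraction emits spikes and rejects uniform windows", {
  uniform <- makeReads(data.frame(start = seq(1, 176, by = 25),
                                  end = seq(21, 196, by = 25),
                                  abundance = 10))
  d <- windowDistribution(uniform, "chr1", "+", 1L, 200L, wp)
  expect_length(extractCandidates(d, uniform, wp), 0L)

  spike <- makeReads(data.frame(
    start = c(60, seq(1, 176, by = 25)),
    end = c(80, seq(21, 196, by = 25)),
    abundance = c(100L, rep(1L, 8))))
  d2 <- windowDistribution(spike, "chr1", "+", 1L, 200L, wp)
  got <- extractCandidates(d2, spike, wp)
  expect_gte(length(got), 1L)
  expect_equal(start(got)[1], 60L)
  expect_equal(got$abundance[1], 100L)
})

test_that("two sharp stacks are both emitted in descending peak order", {
  stacks <- makeReads(data.frame(start = c(20, 60), end = c(40, 80),
                                 abundance = c(100L, 80L)))
  d <- windowDistribution(stacks, "chr1", "+", 1L, 200L, wp)
  got <- extractCandidates(d, stacks, wp)
  expect_equal(length(got), 2L)
  expect_equal(got$abundance, c(100L, 80L))
  expect_equal(got$extractionOrder, 1:2)
})

test_that("wide plateaus are rejected by the local divergence test", {
  # six adjacent subwindows all highly and equally expressed: the window
  # is close to uniform overall, so nothing is extracted from the region
  plateau <- makeReads(data.frame(start = seq(1, 126, by = 25) + 2,
                                  end = seq(21, 146, by = 25) + 2,
                                  abundance = 100L))
  d <- windowDistribution(plateau, "chr1", "+", 1L, 200L, wp)
  expect_length(extractCandidates(d, plateau, wp), 0L)

  # a three-subwindow plateau whose centre holds the highest stack: the
  # local re-test around the centre read sees a flat profile and rejects
  # it, so the plateau centre is never reported as a peak
  centre <- makeReads(data.frame(start = c(28, 53, 78),
                                 end = c(48, 73, 98),
                                 abundance = c(100L, 101L, 100L)))
  d2 <- windowDistribution(centre, "chr1", "+", 1L, 200L, wp)
  got <- extractCandidates(d2, centre, wp)
  expect_false(any(got$abundance == 101L))
})

test_that("reads at the pseudo-count background level are never peaks", {
  # two identical-position reads of abundance 1 make the window
  # non-uniform, but abundance does not exceed the offset
  low <- makeReads(data.frame(start = c(30, 32), end = c(50, 52),
                              abundance = 1L))
  d <- windowDistribution(low, "chr1", "+", 1L, 200L, wp)
  expect_length(extractCandidates(d, low, wp), 0L)
})

test_that("implanted stacks are recovered from random background", {
  hits <- 0L
  for (seed in 1:20) {
    res <- withr::with_seed(seed, {
      bgStart <- sample(1:1979, 40)
      reads <- makeReads(data.frame(
        start = bgStart, end = bgStart + sample(18:24, 40, TRUE),
        abundance = sample(1:2, 40, TRUE)))
      pos <- sample(1:1900, 1)
      stack <- makeReads(data.frame(start = pos, end = pos + 20,
                                    abundance = 80L))
      all <- c(reads, stack)
      cand <- collectCandidates(all, c(chr1 = 2000L), wp)
      any(start(cand) == pos & cand$abundance == 80L)
    })
    hits <- hits + res
  }
  expect_equal(hits, 20L)
})

test_that("candidates emitted by overlapping windows are deduplicated", {
  # a stack near a window boundary is seen by two overlapping windows
  stack <- makeReads(data.frame(start = 95, end = 115, abundance = 50L))
  cand <- collectCandidates(stack, c(chr1 = 400L), wp)
  expect_equal(length(cand), 1L)
})
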