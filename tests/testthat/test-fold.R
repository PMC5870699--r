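sp <- structureParams(animalParams())

test_that("folding finds the expected toy structures", {
  df <- foldSequence("GGGGAAAACCCC")
  expect_gt(nrow(df), 0)
  expect_equal(df$structure[1], "((((....))))")
  expect_lt(df$mfe[1], 0)

  expect_equal(nrow(foldSequence("AAAAAAAAAAAA")), 0L)
  expect_error(foldSequence("ACGX"), "alphabet")
})

test_that("every reported structure is balanced and within the input", {
  withr::with_seed(5, {
    for (i in 1:10) {
      seq <- randomDnaString(120)
      df <- foldSequence(seq)
      for (j in seq_len(nrow(df))) {
        expect_gte(df$start[j], 1L)
        expect_lte(df$end[j], 120L)
        expect_equal(nchar(df$structure[j]), df$end[j] - df$start[j] + 1L)
        expect_silent(pairTable(df$structure[j]))
      }
    }
  })
})

test_that("aMFE follows its definition exactly", {
  expect_identical(computeAmfe(-30, 100), -30)
  expect_identical(computeAmfe(-30, 150), -20)
  expect_identical(computeAmfe(0, 73), 0)
  expect_error(computeAmfe(-10, 0), "foldLength")
})

test_that("pair tables and loop counts parse dot-bracket structures", {
  pt <- pairTable("((..((...))..))")
  expect_equal(pt[1], 15L)
  expect_equal(pt[2], 14L)
  expect_equal(pt[5], 11L)
  expect_true(is.na(pt[3]))
  expect_error(pairTable("(()"), "unbalanced")

  expect_equal(countHairpinLoops("((((....))))"), 1L)
  expect_equal(countHairpinLoops("((..))..((...))"), 2L)
  expect_equal(countHairpinLoops("(((..((..))((..))..)))"), 2L)
})

test_that("structural filters report each violation independently", {
  # perfect 21-bp duplex hairpin with 4 nt loop, mature = 5' arm
  hp <- paste0(strrep("(", 21), "....", strrep(")", 21))
  pass <- structuralFilters(hp, -50, 1, 21,
                            new("StructureParams", maxFoldLen = 100L,
                                minHairpinLen = 44L, maxAmfe = -20,
                                minPairedInMature = 14L,
                                maxUnpairedRun = 5L, maxLoops = 1L,
                                requireMatureNotInLoop = TRUE,
                                starOverhang = 2L))
  expect_true(pass$pass)

  # mature straddling the terminal loop
  straddle <- structuralFilters(hp, -50, 15, 35, sp)
  expect_false(straddle$pass)
  expect_true("mature spans terminal loop" %in% straddle$reasons)

  # too-short hairpin
  short <- paste0(strrep("(", 18), "....", strrep(")", 18))
  v <- structuralFilters(short, -40, 1, 18, sp)  # length 40 < 50
  expect_false(v$pass)
  expect_true("hairpin too short" %in% v$reasons)

  # weak structure fails the aMFE bound
  weak <- structuralFilters(paste0(strrep("(", 25), strrep(".", 10),
                                   strrep(")", 25)), -3, 1, 21, sp)
  expect_true("aMFE above maximum" %in% weak$reasons)
})

test_that("precursor selection minimizes aMFE with deterministic ties", {
  cands <- data.frame(start = c(1L, 10L), end = c(100L, 109L),
                      mfe = c(-25, -30),
                      structure = c(strrep(".", 100), strrep(".", 100)),
                      stringsAsFactors = FALSE)
  expect_equal(selectPrecursor(cands)$mfe, -30)

  one <- cands[1, ]
  expect_equal(selectPrecursor(one)$start, 1L)
  expect_null(selectPrecursor(cands[0, ]))

  # exact aMFE tie at different lengths: shorter wins
  tie <- data.frame(start = c(1L, 1L), end = c(90L, 120L),
                    mfe = c(-27, -36),  # both aMFE -30
                    structure = c(strrep(".", 90), strrep(".", 120)),
                    stringsAsFactors = FALSE)
  expect_equal(selectPrecursor(tie)$end, 90L)

  # invariant under permutation of the input
  withr::with_seed(2, {
    many <- data.frame(start = 1L, end = sample(60:120, 20),
                       mfe = -runif(20, 10, 50))
    many$structure <- strrep(".", many$end)
    picked <- selectPrecursor(many)
    for (i in 1:5) {
      perm <- many[sample(nrow(many)), ]
      expect_equal(selectPrecursor(perm), picked,
                   ignore_attr = "row.names")
    }
  })
})

test_that("star inference follows the 2 nt 3' overhang duplex geometry", {
  # perfect 30-bp stem, 6 nt loop; mature at 3..23 (5' arm)
  hp <- paste0(strrep("(", 30), "......", strrep(")", 30))
  L <- nchar(hp)  # 66
  star <- inferStar(hp, 3, 23, overhang = 2)
  # manual pair-table trace: partner of 3 is 64, partner of 23 is 44;
  # shifting by the overhang gives [46, 66]
  expect_equal(star$start, 46L)
  expect_equal(star$end, 66L)
  expect_false(star$clipped)
  expect_equal(star$end - star$start, 23L - 3L)  # star length = mature length

  # mature with most bases unpaired: no credible duplex
  mostlyOpen <- paste0(strrep("(", 8), strrep(".", 30), strrep(")", 8))
  expect_null(inferStar(mostlyOpen, 3, 23, overhang = 2))

  # mature at the very 5' end: the star would run past the hairpin and
  # is clipped
  starClip <- inferStar(hp, 1, 21, overhang = 2)
  expect_true(starClip$clipped)
  expect_equal(starClip$end, L)
})

test_that("an implanted hairpin is recovered from shuffled flanks", {
  ok <- 0L
  for (seed in 1:10) {
    sim <- simulateGenome(hairpinSpec(position = 151L, strand = "+"),
                          backgroundLen = 400L, seed = seed)
    tr <- sim$truth
    cand <- makeReads(data.frame(start = tr$matureStart,
                                 end = tr$matureEnd, abundance = 100L))
    prec <- foldCandidateWindow(cand, sim$genome, sp, backend = "internal")
    if (!is.null(prec) &&
        prec$start <= tr$matureStart && prec$end >= tr$matureEnd &&
        prec$start >= tr$precStart - 25 && prec$end <= tr$precEnd + 25) {
      ok <- ok + 1L
    }
  }
  expect_equal(ok, 10L)
})
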