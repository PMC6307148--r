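# Edit distance, anchor artifact distances and junction pre-filters.

test_that("edit distance handles the documented base cases", {
  expect_equal(editDistance("GATTACA", "GATTACA"), 0L)
  expect_equal(editDistance("GATTACA", "GACTACA"), 1L)
  expect_equal(editDistance("", "ACGT"), 4L)
  expect_equal(editDistance("ACGT", ""), 4L)
  expect_equal(editDistance("N", "A"), 1L)  # N mismatches definite bases
  expect_equal(editDistance("N", "N"), 0L)
  expect_equal(editDistance("ACGT", "AGT"), 1L)   # deletion
  expect_equal(editDistance("AGT", "ACGT"), 1L)   # insertion
})

test_that("dynamic programming agrees with the exhaustive recursion", {
  set.seed(21)
  for (rep in 1:60) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), TRUE),
               collapse = "")
    expect_identical(editDistance(a, b), edOracle(a, b))
  }
  # the batch path (equal widths) agrees with the scalar path
  s <- randomDna(50, 8); t <- randomDna(50, 8)
  batch <- editDistance(s, t)
  scalar <- vapply(1:50, function(i) editDistance(s[i], t[i]), integer(1))
  expect_identical(batch, scalar)
})

test_that("edit distance satisfies the metric axioms", {
  set.seed(22)
  for (rep in 1:40) {
    a <- randomDna(1, sample(1:8, 1))
    b <- randomDna(1, sample(1:8, 1))
    c <- randomDna(1, sample(1:8, 1))
    dab <- editDistance(a, b)
    expect_identical(dab, editDistance(b, a))           # symmetry
    expect_identical(editDistance(a, a), 0L)            # identity
    expect_identical(dab == 0L, a == b)
    expect_lte(dab, editDistance(a, c) + editDistance(c, b))  # triangle
  }
})

test_that("local alignment score is exposed as the optional similarity", {
  expect_equal(localAlignmentScore("ACGTACGT", "ACGTACGT"), 8)
  expect_gte(localAlignmentScore("AAAATTTT", "CCCCTTTT"), 4)
})

test_that("anchor distances follow the window formulas on a planted repeat", {
  # donor anchor (4 nt before the donor) copied verbatim just before the
  # acceptor: E_d must be 0
  anchor <- "TGCA"
  g <- c(chr1 = paste0("AAAAAA", anchor, "GT", "TTTTTTTTT", anchor,
                       "CCCCCCCC"))
  jd <- 10L  # last base of the anchor (exon | GT intron)
  ja <- 26L  # first exonic C; G[22..25] is the copied anchor
  j <- junctionTable("chr1", jd, ja)
  d <- artifactDistances(g, j, anchorDonor = 4, anchorAcceptor = 4)
  expect_identical(d$E_d, 0L)
  expect_gt(d$E_a, 0L)
})

test_that("anchor distances match independent window extraction", {
  set.seed(31)
  g <- c(chrZ = randomDna(1, 3000))
  j <- junctionTable("chrZ", donor = c(200, 900), acceptor = c(500, 1500),
                     strand = c("+", "-"))
  d <- artifactDistances(g, j, anchorDonor = 16, anchorAcceptor = 16)
  cs <- g[["chrZ"]]
  # strand +: spec formulas verbatim
  expect_identical(d$E_d[1], editDistance(substr(cs, 200 - 15, 200),
                                          substr(cs, 500 - 16, 499)))
  expect_identical(d$E_a[1], editDistance(substr(cs, 500, 515),
                                          substr(cs, 201, 216)))
  # strand -: same formulas on the reverse complement coordinate frame
  expect_identical(d$E_d[2], editDistance(substr(cs, 1500, 1515),
                                          substr(cs, 901, 916)))
  expect_identical(d$E_a[2], editDistance(substr(cs, 900 - 15, 900),
                                          substr(cs, 1500 - 16, 1499)))
  # random 16-mer anchors are never near-identical
  expect_true(all(pmin(d$E_d, d$E_a) >= 1))
  # single-base anchors by direct lookup
  d1 <- artifactDistances(g, j[1, ], anchorDonor = 1, anchorAcceptor = 1)
  expect_identical(d1$E_d,
                   as.integer(substr(cs, 200, 200) != substr(cs, 499, 499)))
})

test_that("the repeat filter drops exactly the planted repeat junction", {
  set.seed(32)
  backbone <- randomDna(1, 400)
  anchor <- substr(backbone, 85, 100)
  # copy the donor anchor into the 16 nt preceding the acceptor
  copied <- backbone
  substr(copied, 284, 299) <- anchor
  g <- c(chr1 = copied)
  j <- junctionTable("chr1", donor = c(100, 150), acceptor = c(300, 360),
                     id = c("repeat", "clean"))
  res <- filterRepetitive(g, j, maxDistance = 1)
  expect_identical(res$dropped$id, "repeat")
  expect_identical(res$kept$id, "clean")
  expect_match(res$dropped$reason, "repeat artifact")
  expect_identical(res$dropped$E_d, 0L)
  # sentinel disables the filter entirely
  off <- filterRepetitive(g, j, maxDistance = -1)
  expect_identical(off$kept$id, j$id)
  expect_identical(nrow(off$dropped), 0L)
})

test_that("the repeat filter partitions its input and ignores support", {
  b <- smallBench()
  sim <- b$sim
  j <- head(sim$junctions, 60)
  res <- filterRepetitive(sim$genome, j)
  expect_setequal(c(res$kept$id, res$dropped$id), j$id)
  expect_length(intersect(res$kept$id, res$dropped$id), 0L)
  # order independence: membership is stable under permutation
  set.seed(33)
  resPerm <- filterRepetitive(sim$genome, j[sample(nrow(j)), ])
  expect_setequal(resPerm$kept$id, res$kept$id)
  # coverage independence: support columns never influence the decision
  j2 <- j
  j2$reads <- 0L
  j2$samples <- 0L
  res2 <- filterRepetitive(sim$genome, j2)
  expect_identical(res2$kept$id, res$kept$id)
})

test_that("planted artifacts are recovered exactly from the generator", {
  cfg <- generatorConfig(nTrue = 80, nFalse = 120, repeatFraction = 0.4,
                         seed = 44)
  sim <- generateGenome(cfg)
  res <- filterRepetitive(sim$genome, sim$junctions, maxDistance = 3)
  truthArtifact <- sim$junctions$id[sim$junctions$class == "artifact"]
  expect_setequal(res$dropped$id, truthArtifact)
})

test_that("support filtering retains junctions seen in enough samples", {
  j <- junctionTable("chr1", c(10, 40, 70, 100), c(30, 60, 90, 130),
                     samples = c(1, 2, 10, 1000))
  kept <- filterBySupport(j)
  expect_identical(kept$samples, c(2L, 10L, 1000L))
  expect_identical(filterBySupport(j, 1), j)
  noCol <- j[, setdiff(names(j), "samples")]
  expect_error(filterBySupport(noCol), "samples")
  expect_identical(filterBySupport(noCol, 1), noCol)
})
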