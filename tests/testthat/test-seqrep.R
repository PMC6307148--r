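# Sequence representation: one-hot encoding, window assembly, splitting.

test_that("base encoding is the documented orthonormal scheme", {
  expect_equal(unname(encodeBase("A")), c(0, 0, 0, 1))
  expect_equal(unname(encodeBase("C")), c(0, 0, 1, 0))
  expect_equal(unname(encodeBase("G")), c(0, 1, 0, 0))
  expect_equal(unname(encodeBase("T")), c(1, 0, 0, 0))
  expect_equal(unname(encodeBase("N")), rep(0.25, 4))
  expect_equal(encodeBase("a"), encodeBase("A"))
  # the four definite vectors are mutually orthogonal basis vectors
  M <- rbind(encodeBase("A"), encodeBase("C"), encodeBase("G"), encodeBase("T"))
  expect_equal(unname(M %*% t(M)), diag(4))
  # ambiguity codes collapse to N; junk is rejected with the character named
  expect_equal(encodeBase("R"), encodeBase("N"))
  expect_error(encodeBase("X"), "X")
})

test_that("sequence encoding normalises, maps N, and is invertible", {
  x <- encodeSequences(c("ACGT", "NNNN"))
  expect_equal(dim(x), c(2L, 4L, 4L))
  expect_equal(rowSums(x[1, , ]), rep(1, 4))
  expect_true(all(x[2, , ] == 0.25))
  expect_equal(decodeSequences(x), c("ACGT", "NNNN"))
  # 120-nt junction sequence -> width-120 tensor, every position sums to 1
  s120 <- randomDna(1, 120)
  t120 <- encodeSequences(s120)
  expect_equal(dim(t120), c(1L, 120L, 4L))
  expect_equal(rowSums(t120[1, , ]), rep(1, 120))
  expect_error(encodeSequences(c("ACGT", "AC-T")), "position 3")
  expect_error(encodeSequences(character(0)))
  expect_error(encodeSequences(c("ACG", "ACGT")), "same length")
})

test_that("junction assembly produces the documented window order", {
  g <- c(chr1 = "AAAAGTTTTTAGCCCC")
  j <- junctionTable("chr1", donor = 4, acceptor = 13)
  s <- assembleJunctionSequence(g, j, flank = 2)
  expect_equal(unname(s[1]), "AAGTAGCC")
  expect_equal(substr(s[[1]], 3, 4), "GT")
  expect_equal(substr(s[[1]], 5, 6), "AG")
  expect_error(assembleJunctionSequence(g, j, flank = 1), "flank")
  expect_error(
    assembleJunctionSequence(g, junctionTable("chr1", 2, 13), flank = 4),
    "boundary")
  expect_error(
    assembleJunctionSequence(g, junctionTable("chrX", 4, 13), flank = 2),
    "chrX")
})

test_that("minus-strand assembly is the reverse complement with roles swapped", {
  set.seed(42)
  g <- c(chrR = randomDna(1, 400))
  j <- junctionTable("chrR", donor = 100, acceptor = 300, strand = "+")
  jm <- junctionTable("chrR", donor = 100, acceptor = 300, strand = "-")
  plus <- assembleJunctionSequence(g, j, flank = 30)
  minus <- assembleJunctionSequence(g, jm, flank = 30)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(plus))))
  expect_equal(unname(minus[1]), rc)
  # donor windows of the minus assembly are acceptor windows of the plus one
  sp <- splitJunctionIntoSites(plus)
  sm <- splitJunctionIntoSites(minus)
  expect_equal(unname(sm$donor[1]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(unname(sp$acceptor)))))
})

test_that("assembly failures can be reported per junction", {
  g <- c(chr1 = randomDna(1, 200))
  j <- junctionTable("chr1", donor = c(10, 80), acceptor = c(150, 140))
  s <- assembleJunctionSequence(g, j, flank = 30, onError = "report")
  expect_true(is.na(s[1]))  # donor window out of bounds
  expect_false(is.na(s[2]))
  expect_match(attr(s, "note")[1], "boundary")
})

test_that("splitting partitions a junction sequence and round-trips", {
  g <- c(chr1 = "AAAAGTTTTTAGCCCC")
  s <- assembleJunctionSequence(g, junctionTable("chr1", 4, 13), flank = 2)
  sites <- splitJunctionIntoSites(s)
  expect_equal(unname(sites$donor[1]), "AAGT")
  expect_equal(unname(sites$acceptor[1]), "AGCC")
  expect_equal(paste0(sites$donor, sites$acceptor), unname(s[1]))
  seqs <- randomDna(5, 120)
  sp <- splitJunctionIntoSites(seqs)
  expect_equal(unname(paste0(sp$donor, sp$acceptor)), seqs)
  expect_error(splitJunctionIntoSites(sp$donor, flank = 30), "invalid-mode")
})

test_that("generator-planted true junctions always show canonical GT/AG", {
  b <- smallBench()
  sim <- b$sim
  tj <- sim$junctions[sim$junctions$class == "true", ]
  seqs <- assembleJunctionSequence(sim$genome, tj, flank = 30)
  f <- 30
  expect_true(all(substr(seqs, f + 1, f + 2) == "GT"))
  expect_true(all(substr(seqs, 3 * f - 1, 3 * f) == "AG"))
  # and the windows back-project onto the recorded coordinates
  g <- sim$genome[["chrS"]]
  i <- 1
  expect_equal(substr(g, tj$donor[i] - f + 1, tj$donor[i]),
               substr(seqs[[i]], 1, f))
  expect_equal(substr(g, tj$acceptor[i], tj$acceptor[i] + f - 1),
               substr(seqs[[i]], 3 * f + 1, 4 * f))
})

test_that("window layouts partition the sequence without gaps", {
  for (mode in c("junction", "donor_site", "acceptor_site")) {
    lay <- windowLayout(30, mode)
    expect_equal(lay$start[1], 1L)
    expect_equal(lay$start[-1], head(lay$end, -1) + 1L)
  }
  expect_equal(windowLayout(30, "junction")$end[4], 120L)
})
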