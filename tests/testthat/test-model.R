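# The convolutional classifier: construction, training, inference.

test_that("parameter count matches the closed-form sum over layers", {
  cfg <- spliceModelConfig(inputWidth = 120)
  m <- buildSpliceModel(cfg)
  # conv1: 3*4*8+8; conv2: 3*8*16+16; fc: 120*16*32+32; out: 32*2+2
  expected <- (3 * 4 * 8 + 8) + (3 * 8 * 16 + 16) +
    (120 * 16 * 32 + 32) + (32 * 2 + 2)
  expect_equal(nParameters(m), expected)
  expect_equal(expected, 62042)
  cfg60 <- spliceModelConfig(inputWidth = 60)
  expect_equal(nParameters(buildSpliceModel(cfg60)),
               (3 * 4 * 8 + 8) + (3 * 8 * 16 + 16) +
                 (60 * 16 * 32 + 32) + (32 * 2 + 2))
})

test_that("builds are deterministic under the config seed", {
  a <- buildSpliceModel(spliceModelConfig(seed = 7))
  b <- buildSpliceModel(spliceModelConfig(seed = 7))
  c <- buildSpliceModel(spliceModelConfig(seed = 8))
  expect_identical(modelWeights(a), modelWeights(b))
  expect_false(identical(modelWeights(a), modelWeights(c)))
})

test_that("inference is deterministic, normalised, and shape-checked", {
  m <- smallModel()
  x <- smallBench()$test$sequences[1:5]
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # class probabilities sum to 1 within numeric tolerance
  z <- predict(m, x, type = "logits")
  P <- exp(z) / rowSums(exp(z))
  expect_equal(P[, 2], p1, tolerance = 1e-6)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  # an all-N sequence is a valid degenerate input
  pn <- predict(m, strrep("N", 120))
  expect_true(pn > 0 && pn < 1)
  expect_error(predict(m, randomDna(1, 60)), "shape")
})

test_that("training rejects empty and single-class sets", {
  m <- buildSpliceModel(spliceModelConfig(inputWidth = 12, maxEpochs = 1))
  x <- encodeSequences(randomDna(6, 12))
  expect_error(trainSpliceModel(m, x[0, , , drop = FALSE], integer(0)),
               "empty")
  expect_error(trainSpliceModel(m, x, rep(1L, 6)), "class 0")
  expect_error(trainSpliceModel(m, x, rep(0L, 6)), "class 1")
})

test_that("a linearly separable motif set is learned to perfect accuracy", {
  set.seed(5)
  n <- 100
  motif <- "GTAAGT"
  make <- function(withMotif) {
    vapply(seq_len(n), function(i) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
        if (withMotif) substr(s, 8, 13) <- motif
        if (withMotif == grepl(motif, substr(s, 8, 13), fixed = TRUE)) {
          return(s)
        }
      }
    }, character(1))
  }
  xs <- c(make(TRUE), make(FALSE))
  y <- rep(c(1L, 0L), each = n)
  # the count-based rule separates the classes perfectly by construction
  ruleAcc <- mean(grepl(motif, substr(xs, 8, 13), fixed = TRUE) == (y == 1))
  expect_identical(ruleAcc, 1)
  cfg <- spliceModelConfig(inputWidth = 20, maxEpochs = 50, patience = 50,
                           batchSize = 32, seed = 2)
  m <- trainSpliceModel(buildSpliceModel(cfg), xs, y)
  expect_equal(mean(predict(m, xs, type = "class") == y), 1)
  expect_lte(nrow(trainingLog(m)), 50)
})

test_that("label-permuted data is classified at chance level", {
  b <- smallBench()
  set.seed(9)
  n <- length(b$train$labels)
  yPerm <- sample(b$train$labels)
  cfg <- spliceModelConfig(maxEpochs = 6, patience = 6, seed = 3)
  m <- trainSpliceModel(buildSpliceModel(cfg), b$train$sequences, yPerm,
                        b$valid$sequences, sample(b$valid$labels))
  acc <- mean(predict(m, b$test$sequences, type = "class") ==
                sample(b$test$labels))
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("training is reproducible given the seed", {
  b <- smallBench()
  cfg <- spliceModelConfig(maxEpochs = 3, seed = 11)
  idx <- c(which(b$train$labels == 1)[1:60], which(b$train$labels == 0)[1:60])
  run <- function() {
    trainSpliceModel(buildSpliceModel(cfg),
                     b$train$sequences[idx], b$train$labels[idx],
                     b$valid$sequences[1:60], b$valid$labels[1:60])
  }
  m1 <- run(); m2 <- run()
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(modelWeights(m1), modelWeights(m2))
})

test_that("a 1x1-filter degenerate config still builds and trains", {
  cfg <- spliceModelConfig(inputWidth = 12, filterWidth = 1,
                           maxEpochs = 3, batchSize = 16, seed = 1)
  xs <- randomDna(40, 12)
  y <- rep(c(0L, 1L), 20)
  m <- trainSpliceModel(buildSpliceModel(cfg), xs, y)
  expect_true(isTrained(m))
  expect_length(predict(m, xs), 40)
})

test_that("site probabilities combine by the product rule", {
  expect_equal(combineSiteProbabilities(1, 1), 1)
  expect_equal(combineSiteProbabilities(0.5, 0.5), 0.25)
  expect_equal(combineSiteProbabilities(c(0.1, 0.9, 1), 0), c(0, 0, 0))
  expect_error(combineSiteProbabilities(1.2, 0.5), "domain")
  expect_error(combineSiteProbabilities(0.5, -0.1), "domain")
})

test_that("classifyJunctions respects thresholds, modes, and reports failures", {
  b <- smallBench()
  sim <- b$sim
  m <- smallModel()
  j <- head(sim$junctions[sim$junctions$class != "artifact", ], 20)
  scored <- classifyJunctions(sim$genome, j, model = m, mode = "junction")
  expect_true(all(scored$p_true >= 0 & scored$p_true <= 1))
  allPos <- classifyJunctions(sim$genome, j, model = m, threshold = 0)
  expect_true(all(allPos$call))
  allNeg <- classifyJunctions(sim$genome, j, model = m, threshold = 1.01)
  expect_false(any(allNeg$call))
  # a junction whose windows fall off the chromosome is reported, not fatal
  core <- c("id", "chrom", "donor", "acceptor", "strand")
  jBad <- rbind(j[, core], junctionTable("chrS", 3, 80, id = "edge")[, core])
  scored2 <- classifyJunctions(sim$genome, jBad, model = m)
  expect_true(is.na(scored2$p_true[nrow(scored2)]))
  expect_false(anyNA(scored2$p_true[-nrow(scored2)]))
  # mode fields are checked
  expect_error(classifyJunctions(sim$genome, j, model = m,
                                 donorModel = m, acceptorModel = m,
                                 mode = "site_pair"), "site_pair")
})

test_that("checkpoints round-trip and validate on load", {
  m <- smallModel()
  f <- tempfile(fileext = ".ckpt")
  saveSpliceModel(m, f)
  m2 <- loadSpliceModel(f)
  expect_identical(modelWeights(m2), modelWeights(m))
  expect_identical(modelConfig(m2)$inputWidth, 120L)
  x <- smallBench()$test$sequences[1:3]
  expect_identical(predict(m2, x), predict(m, x))
  saveRDS(list(format = "other"), f)
  expect_error(loadSpliceModel(f), "checkpoint")
})
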