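# Deep Taylor decomposition: redistribution rules, conservation,
# aggregation and export.

# A hand-built all-positive linear chain: conv1/conv2 are 1-wide identity
# passes and the fully connected layer applies weights w, so the network
# computes y = sum_i w_i x_i with zero biases.
linearChainModel <- function(w) {
  W <- length(w)
  cfg <- spliceModelConfig(inputWidth = W, conv1Features = 1,
                           conv2Features = 1, filterWidth = 1, fcUnits = 1)
  m <- buildSpliceModel(cfg)
  wt <- modelWeights(m)
  wt$K1 <- matrix(c(0.25, 0.25, 0.25, 0.25), 4, 1)  # channel sum = x "on"
  wt$b1 <- 0
  wt$K2 <- matrix(1, 1, 1); wt$b2 <- 0
  wt$W3 <- matrix(w, W, 1); wt$b3 <- 0
  wt$W4 <- matrix(c(0, 1), 1, 2); wt$b4 <- c(0, 0)
  m@weights <- wt
  m@trained <- TRUE
  m
}

test_that("a positive linear neuron redistributes relevance as w_i * x_i", {
  w <- c(0.5, 1.5, 2, 0.25)
  m <- linearChainModel(w)
  x <- "ACGT"  # every position contributes activation 0.25 * 1 ... = 0.25
  map <- deepTaylorDecompose(m, x)
  act <- rep(0.25, 4)  # channel sum after the 0.25 input kernel
  expected <- w * act
  expect_equal(perBase(map), expected, tolerance = 1e-12)
  expect_equal(decomposedOutput(map), sum(expected), tolerance = 1e-12)
  expect_equal(sum(taylorResiduals(map)), 0)
})

test_that("inputs with no positively contributing path get an all-zero map", {
  m <- linearChainModel(c(1, 1, 1, 1))
  wt <- modelWeights(m)
  wt$W4 <- matrix(c(1, -1), 1, 2)  # negative score for the true class
  m@weights <- wt
  map <- deepTaylorDecompose(m, "ACGT")
  expect_equal(decomposedOutput(map), 0)
  expect_true(all(perBase(map) == 0))
})

test_that("relevance is conserved for bias-free networks and never NaN", {
  m <- smallModel()
  w <- modelWeights(m)
  for (nm in c("b1", "b2", "b3", "b4")) w[[nm]] <- w[[nm]] * 0
  m0 <- m
  m0@weights <- w
  xs <- smallBench()$test$sequences[1:20]
  for (i in seq_along(xs)) {
    map <- deepTaylorDecompose(m0, xs[i])
    expect_false(anyNA(perBase(map)))
    expect_true(all(perBase(map) >= 0))
    out <- decomposedOutput(map)
    if (out > 0) {
      expect_lt(abs(sum(perBase(map)) + sum(taylorResiduals(map)) - out),
                1e-4 * out)
    }
  }
})

test_that("general networks at most sub-conserve the output score", {
  m <- smallModel()
  xs <- smallBench()$test$sequences[1:10]
  for (i in seq_along(xs)) {
    map <- deepTaylorDecompose(m, xs[i])
    expect_true(all(perBase(map) >= 0))
    expect_lte(sum(perBase(map)),
               decomposedOutput(map) + sum(taylorResiduals(map)) + 1e-8)
  }
})

test_that("zero redistribution denominators drop to residuals, not NaN", {
  cfg <- spliceModelConfig(inputWidth = 4, conv1Features = 1,
                           conv2Features = 1, filterWidth = 1, fcUnits = 2)
  m <- buildSpliceModel(cfg)
  wt <- modelWeights(m)
  wt$K1 <- matrix(0.25, 4, 1); wt$b1 <- 0
  wt$K2 <- matrix(1, 1, 1); wt$b2 <- 0
  # unit 1 is purely bias-driven: all its incoming weights are negative,
  # so its z+ denominator is 0 while its relevance is positive
  wt$W3 <- cbind(rep(-1, 4), rep(1, 4)); wt$b3 <- c(5, 0)
  wt$W4 <- matrix(c(0, 0, 1, 1), 2, 2); wt$b4 <- c(0, 0)
  m@weights <- wt; m@trained <- TRUE
  map <- deepTaylorDecompose(m, "ACGT")
  expect_false(anyNA(perBase(map)))
  expect_gt(taylorResiduals(map)[["fc1"]], 0)
  expect_equal(sum(perBase(map)) + sum(taylorResiduals(map)),
               decomposedOutput(map), tolerance = 1e-10)
})

test_that("aggregation averages maps and annotates windows", {
  m <- smallModel()
  x <- smallBench()$test$sequences[1:3]
  maps <- deepTaylorDecomposeSet(m, x)
  one <- aggregatePositions(maps[[1]], windowLayout(30, "junction"))
  expect_equal(one$mean, perBase(maps[[1]]))
  expect_equal(one$sd, rep(0, 120))
  expect_equal(unique(one$window[1:30]), "donor_exon")
  expect_equal(unique(one$window[31:60]), "donor_intron")
  prof <- aggregatePositions(maps, windowLayout(30, "junction"))
  expect_equal(prof$mean, colMeans(do.call(rbind, lapply(maps, perBase))))
  short <- deepTaylorDecompose(
    linearChainModel(rep(1, 4)), "ACGT")
  expect_error(aggregatePositions(c(maps, list(short))), "mixed widths")
})

test_that("site-adjacent positions out-contribute the rest on synthetic data", {
  m <- smallModel()
  b <- smallBench()
  p <- predict(m, b$test$sequences)
  keep <- which(b$test$labels == 1 & p >= 0.5)
  maps <- deepTaylorDecomposeSet(m, b$test$sequences[head(keep, 40)])
  prof <- aggregatePositions(maps, b$layout)
  f <- 30
  near <- c((f - 5):(f + 6), (3 * f - 5):(3 * f + 6))
  expect_gt(mean(prof$mean[near]), mean(prof$mean[-near]))
})

test_that("profiles export, plot, and round-trip through the reader", {
  m <- smallModel()
  prof <- explainPredictions(m, smallBench()$test$sequences[1:10],
                             labels = smallBench()$test$labels[1:10])
  expect_equal(nrow(prof), 120L)
  f <- tempfile(fileext = ".tsv")
  png <- tempfile(fileext = ".png")
  exportProfile(prof, f, plot = png)
  expect_true(file.exists(png))
  back <- readProfile(f)
  expect_equal(back$mean, prof$mean, tolerance = 1e-12)
  expect_equal(back$window, prof$window)
  empty <- prof[0, , drop = FALSE]
  exportProfile(empty, f)
  expect_equal(nrow(readProfile(f)), 0L)
  expect_equal(readLines(f)[1], "position\twindow\tmean\tsd")
})
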