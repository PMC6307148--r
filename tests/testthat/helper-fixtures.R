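# Shared fixtures, built once per test run and cached in-process.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE)) {
    assign(name, maker(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# A small default-strength benchmark: enough signal to train a competent
# model in a few seconds, used by the model/taylor module tests.
smallBench <- function() fixture("smallBench", function() {
  makeBenchmark(generatorConfig(nTrue = 300, nFalse = 300, seed = 101))
})

smallModel <- function() fixture("smallModel", function() {
  b <- smallBench()
  cfg <- spliceModelConfig(maxEpochs = 25, patience = 6, seed = 101)
  trainSpliceModel(buildSpliceModel(cfg),
                   b$train$sequences, b$train$labels,
                   b$valid$sequences, b$valid$labels)
})

# The study-condition benchmark runs shared by the learnability and
# relevance acceptance checks: default generator (2000 true / 2000 decoy,
# default motif strength), three seeds.
defaultBenchRuns <- function() fixture("defaultBenchRuns", function() {
  lapply(1:3, function(s) {
    bench <- makeBenchmark(generatorConfig(seed = 200 + s))
    model <- trainSpliceModel(
      buildSpliceModel(spliceModelConfig(seed = s)),
      bench$train$sequences, bench$train$labels,
      bench$valid$sequences, bench$valid$labels)
    p <- predict(model, bench$test$sequences)
    list(bench = bench, model = model, scores = p,
         auROC = curveMetrics(p, bench$test$labels)$auROC,
         oracleAuROC = curveMetrics(
           pwmBayesScore(bench$test$sequences, bench$sim$config),
           bench$test$labels)$auROC)
  })
})

# Memo-free recursive edit-distance oracle (exhaustive enumeration).
edOracle <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  sub <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(edOracle(substr(a, 2L, nchar(a)), b) + 1L,
      edOracle(a, substr(b, 2L, nchar(b))) + 1L,
      edOracle(substr(a, 2L, nchar(a)), substr(b, 2L, nchar(b))) + sub)
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

# Exhaustive pair-counting auROC: P(pos > neg) + 0.5 P(tie).
auROCOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Independent step-summed auPRC over distinct thresholds.
auPRCOracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevRec <- 0; area <- 0
  for (t in th) {
    call <- scores >= t
    tp <- sum(call & labels == 1)
    prec <- tp / sum(call)
    rec <- tp / sum(labels == 1)
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}
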