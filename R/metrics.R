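# Evaluation measures for splice site / junction classifiers.

#' Thresholded confusion counts
#'
#' @param scores Numeric scores (probabilities of the positive class).
#' @param labels Binary 0/1 truth labels.
#' @param threshold Call threshold; scores equal to the threshold count as
#'   positive calls.
#' @return A list of class `confusionCounts` with integer fields `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("empty input")
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  call <- scores >= threshold
  out <- list(TP = sum(call & labels == 1L),
              FP = sum(call & labels == 0L),
              TN = sum(!call & labels == 0L),
              FN = sum(!call & labels == 1L))
  structure(lapply(out, as.integer), class = "confusionCounts")
}

#' Q9 global accuracy measure
#'
#' Q9 is a class-distribution-independent accuracy summary,
#' `Q9 = (1 + q9) / 2`, with
#' \deqn{q9 = 1 - \sqrt{2}\sqrt{(FN/(TP+FN))^2 + (FP/(TN+FP))^2}}
#' when both classes are present, and the degenerate one-class forms
#' `q9 = (TN - FP)/(TN + FP)` when `TP + FN = 0` and
#' `q9 = (TP - FN)/(TP + FN)` when `TN + FP = 0`. Q9 equals 1 iff
#' `FP = FN = 0`, lies in `[0, 1]` when computed from attainable rate
#' pairs, and is invariant to scaling all counts by a positive integer.
#'
#' @param counts A `confusionCounts` list (or any list with TP/FP/TN/FN),
#'   or a single TP count if the remaining three are given.
#' @param FP,TN,FN Individual counts when `counts` is given as TP.
#' @return Q9 as a number in `[0, 1]`.
#' @export
#' @examples
#' q9Score(list(TP = 9571, FN = 429, TN = 9376, FP = 624))  # 0.9465
q9Score <- function(counts, FP = NULL, TN = NULL, FN = NULL) {
  if (is.numeric(counts) && length(counts) == 1L && !is.null(FP)) {
    counts <- list(TP = counts, FP = FP, TN = TN, FN = FN)
  }
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (TP + FN == 0 && TN + FP == 0) stop("undefined: all four counts are zero")
  q9 <- if (TP + FN == 0) {
    (TN - FP) / (TN + FP)
  } else if (TN + FP == 0) {
    (TP - FN) / (TP + FN)
  } else {
    1 - sqrt(2) * sqrt((FN / (TP + FN))^2 + (FP / (TN + FP))^2)
  }
  (1 + q9) / 2
}

#' Standard rate metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and F1 (harmonic mean of precision and recall). A rate
#' whose denominator is zero is returned as `NA` (undefined-metric
#' marker), never `NaN`.
#'
#' @param counts A `confusionCounts` list.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`,
#'   `F1`.
#' @export
rateMetrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = rate(TP, TP + FN),
       specificity = rate(TN, TN + FP),
       accuracy = rate(TP + TN, TP + FP + TN + FN),
       F1 = rate(2 * TP, 2 * TP + FP + FN))
}

#' Area under the ROC and precision-recall curves
#'
#' auROC by the rank (trapezoidal) method with tied scores averaged -
#' equivalently the probability that a random positive outscores a random
#' negative, plus half the tie probability. auPRC by interpolation-free
#' step summation over distinct score thresholds.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return Named list with `auROC` and `auPRC`, both in `[0, 1]`.
#' @export
curveMetrics <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # ties averaged
  auROC <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # step-summed precision-recall over distinct thresholds, high to low
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  cumTP <- cumsum(y); cumAll <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
  tp <- cumTP[last]; all <- cumAll[last]
  prec <- tp / all
  rec <- tp / n1
  dRec <- diff(c(0, rec))
  auPRC <- sum(dRec * prec)
  list(auROC = auROC, auPRC = auPRC)
}

#' Confidence interval for a classification error proportion
#'
#' Normal-approximation binomial interval for the error rate
#' `errors / n`, clipped to `[0, 1]`; an exact Clopper-Pearson interval is
#' available via `method = "exact"`.
#'
#' @param errors Number of misclassified items, `0 <= errors <= n`.
#' @param n Number of items tested, `> 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"normal"` (default) or `"exact"`.
#' @return Numeric `c(lo, hi)`.
#' @export
errorConfidenceInterval <- function(errors, n, level = 0.95,
                                    method = c("normal", "exact")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  stopifnot(errors >= 0, errors <= n)
  alpha <- 1 - level
  if (method == "normal") {
    p <- errors / n
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  } else {
    lo <- if (errors == 0) 0 else qbeta(alpha / 2, errors, n - errors + 1)
    hi <- if (errors == n) 1 else qbeta(1 - alpha / 2, errors + 1, n - errors)
    c(lo, hi)
  }
}

#' Stratified k-fold cross-validation of a splice model
#'
#' Assigns items of each class round-robin to `k` seeded folds (fold sizes
#' differ by at most one and preserve the class ratio within one item),
#' trains one model per fold on the remaining data - a stratified tenth of
#' which is held out internally for checkpoint selection - and evaluates
#' on the fold. Pooled metrics are computed on the concatenated held-out
#' predictions.
#'
#' @param x Encoded array `[n, width, 4]`, sequences, or DNAStringSet.
#' @param y Binary labels; each class needs at least `k` members.
#' @param config A [spliceModelConfig()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment (default 1).
#' @param mode Model mode, as in [buildSpliceModel()].
#' @return A list with `folds` (per-fold metric data.frame), `pooled`
#'   (metrics on concatenated predictions), `assignments` (fold index per
#'   item) and `scores` (pooled out-of-fold scores).
#' @export
crossValidate <- function(x, y, config = spliceModelConfig(), k = 10L,
                          seed = 1L, mode = "junction") {
  b <- .asBatch(x, config$inputWidth)
  y <- as.integer(y)
  stopifnot(length(y) == b$n)
  if (k < 2L) stop("k must be >= 2")
  for (cls in c(0L, 1L)) {
    if (sum(y == cls) < k) {
      stop("class ", cls, " has fewer than k = ", k, " members")
    }
  }
  arr <- array(b$Xm, c(b$n, b$W, 4L))
  fold <- integer(b$n)
  .withSeed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  scores <- rep(NA_real_, b$n)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    tr <- which(!test)
    # stratified internal validation split for checkpointing
    va <- .withSeed(seed + f, {
      unlist(lapply(c(0L, 1L), function(cls) {
        cand <- tr[y[tr] == cls]
        sample(cand, max(1L, length(cand) %/% 10L))
      }))
    })
    tr2 <- setdiff(tr, va)
    model <- buildSpliceModel(config, mode = mode)
    model <- trainSpliceModel(model,
                              arr[tr2, , , drop = FALSE], y[tr2],
                              arr[va, , , drop = FALSE], y[va])
    p <- predict(model, arr[test, , , drop = FALSE])
    scores[test] <- p
    cm <- confusionCounts(p, y[test])
    rm_ <- rateMetrics(cm)
    cv <- tryCatch(curveMetrics(p, y[test]),
                   error = function(e) list(auROC = NA_real_, auPRC = NA_real_))
    rows[[f]] <- data.frame(fold = f, n = sum(test),
                            auROC = cv$auROC, auPRC = cv$auPRC,
                            sensitivity = rm_$sensitivity,
                            specificity = rm_$specificity,
                            accuracy = rm_$accuracy, F1 = rm_$F1,
                            Q9 = q9Score(cm))
  }
  cmAll <- confusionCounts(scores, y)
  pooled <- c(rateMetrics(cmAll), curveMetrics(scores, y),
              list(Q9 = q9Score(cmAll)))
  list(folds = do.call(rbind, rows), pooled = pooled,
       assignments = fold, scores = scores)
}
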