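# Deep Taylor decomposition of the trained network.
#
# The pre-normalisation positive-class score (clamped at 0) is
# redistributed backwards layer by layer via first-order Taylor expansions
# at layer-specific root points:
#   * hidden rectifier layers (output, fully-connected, conv2) use the
#     positive-weight z+ rule: C_i = sum_j x_i w+_ij / (sum_i' x_i' w+_i'j) C_j
#   * the input layer, whose values live in the box [0,1] per channel,
#     uses the bounded-domain rule with l = 0, h = 1:
#     C_i = sum_j (x_i w_ij - h w-_ij) / (sum_i' x_i' w_i'j - h w-_i'j) C_j
# Convolutions are treated as their unrolled linear maps (the same im2col
# product as the forward pass), so a base's score automatically pools the
# contribution of every filter window covering it. Neurons whose
# redistribution denominator is zero have their relevance dropped to a
# per-layer residual - never propagated as NaN. Both rules redistribute
# ignoring biases, so for a bias-free network total relevance is conserved
# exactly; relevance is nonnegative by construction.

# z+ redistribution through a linear map X [n, I] %*% K [I, J] given
# output relevance R [n, J]; returns list(Rin = [n, I], residual).
.zplusBackward <- function(X, K, R) {
  Kp <- pmax(K, 0)
  Z <- X %*% Kp
  ok <- Z > 1e-12
  S <- matrix(0, nrow(R), ncol(R))
  S[ok] <- R[ok] / Z[ok]
  list(Rin = X * tcrossprod(S, Kp),
       residual = sum(R[!ok]))
}

# Bounded-box rule (l = 0, h = 1) through X %*% K. `mask` flags which
# kernel taps read a real input position (vs. boundary zero padding):
# padded taps are fixed at 0, not free in the box, so they receive no
# relevance and contribute nothing to the denominator.
.zBoxBackward <- function(X, K, R, mask = NULL) {
  Kn <- pmin(K, 0)
  negTerm <- if (is.null(mask)) {
    matrix(colSums(Kn), nrow(X), ncol(K), byrow = TRUE)
  } else {
    mask %*% Kn
  }
  Z <- X %*% K - negTerm
  ok <- Z > 1e-12
  S <- matrix(0, nrow(R), ncol(R))
  S[ok] <- R[ok] / Z[ok]
  Rin <- X * tcrossprod(S, K) - if (is.null(mask)) {
    tcrossprod(S, Kn)
  } else {
    mask * tcrossprod(S, Kn)
  }
  list(Rin = Rin, residual = sum(R[!ok]))
}

#' Deep Taylor decomposition of a prediction
#'
#' Redistributes the model's pre-normalisation "true" score (clamped at 0
#' if negative) onto every (position, channel) of the input tensor, then
#' sums channels to a per-nucleotide contribution score. Hidden rectifier
#' layers use the z+ rule; the `[0,1]`-valued input layer uses the
#' bounded-box rule. Dropout is inactive. All contributions are
#' nonnegative, and for a bias-free network they sum to the decomposed
#' output.
#'
#' @param model A trained [SpliceModel-class] (rectifier activations are a
#'   structural property of the package's models).
#' @param x A single input: sequence string, DNAStringSet of length 1,
#'   encoded matrix `[width, 4]` or array `[1, width, 4]`.
#' @return A [RelevanceMap-class].
#' @export
deepTaylorDecompose <- function(model, x) {
  stopifnot(is(model, "SpliceModel"))
  cfg <- model@config
  w <- model@weights
  b <- .asBatch(x, cfg$inputWidth)
  if (b$n != 1L) stop("deepTaylorDecompose explains one input at a time")
  W <- cfg$inputWidth
  F1 <- cfg$conv1Features; F2 <- cfg$conv2Features
  fw <- cfg$filterWidth

  f <- .forward(w, cfg, b$Xm, 1L, keep = TRUE)
  out <- max(f$Z4[1L, 2L], 0)
  residuals <- c(output = 0, fc1 = 0, conv2 = 0, input = 0)

  if (out == 0) {
    pc <- matrix(0, W, 4L, dimnames = list(NULL, spliceChannels()))
    return(new("RelevanceMap", perChannel = pc, perBase = numeric(W),
               output = 0, residuals = residuals,
               rules = c(hidden = "z+", input = "zB[0,1]")))
  }

  # output layer: H3 [1, fc] -> true-class score
  r <- .zplusBackward(matrix(f$H3, 1L), w$W4[, 2L, drop = FALSE],
                      matrix(out, 1L, 1L))
  residuals["output"] <- r$residual
  Rh3 <- r$Rin                                   # [1, fc]

  # fully connected layer: Fl [1, W*F2] -> H3
  r <- .zplusBackward(f$Fl, w$W3, Rh3)
  residuals["fc1"] <- r$residual
  # un-flatten to position-major [W, F2]
  Rh2 <- matrix(aperm(array(r$Rin, c(1L, F2, W)), c(1L, 3L, 2L)), W, F2)

  # conv2: Xc2 [W, fw*F1] -> H2; then pool col2im onto H1
  r <- .zplusBackward(f$Xc2, w$K2, Rh2)
  residuals["conv2"] <- r$residual
  Rh1 <- .col2im(r$Rin, 1L, W, F1, fw)           # [W, F1]

  # conv1 = input layer: bounded box on the one-hot channels
  mask <- .im2col(matrix(1, W, 4L), 1L, W, 4L, fw)
  r <- .zBoxBackward(f$Xc1, w$K1, Rh1, mask = mask)
  residuals["input"] <- r$residual
  Rx <- .col2im(r$Rin, 1L, W, 4L, fw)            # [W, 4]
  Rx[Rx < 0 & Rx > -1e-12] <- 0                  # clip numeric dust
  colnames(Rx) <- spliceChannels()

  new("RelevanceMap", perChannel = Rx, perBase = rowSums(Rx),
      output = out, residuals = residuals,
      rules = c(hidden = "z+", input = "zB[0,1]"))
}

#' Decompose a set of inputs
#'
#' @param model A trained [SpliceModel-class].
#' @param xs Sequences (character/DNAStringSet) or encoded array
#'   `[n, width, 4]`.
#' @return A list of [RelevanceMap-class] objects.
#' @export
deepTaylorDecomposeSet <- function(model, xs) {
  b <- .asBatch(xs, model@config$inputWidth)
  n <- b$n; W <- b$W
  arr <- array(b$Xm, c(n, W, 4L))
  lapply(seq_len(n), function(i) {
    deepTaylorDecompose(model, matrix(arr[i, , ], W, 4L))
  })
}

#' Aggregate relevance maps into a positional contribution profile
#'
#' Computes the positionwise mean (and standard deviation) of per-base
#' contributions across a set of relevance maps and annotates each
#' position with its exon/intron window from a [windowLayout()].
#'
#' @param maps A [RelevanceMap-class] or list of them, all of one width.
#' @param layout Optional layout data.frame ([windowLayout()]); positions
#'   outside any window (or with `layout = NULL`) are labelled `"all"`.
#' @return A data.frame with columns `position`, `window`, `mean`, `sd`.
#' @export
aggregatePositions <- function(maps, layout = NULL) {
  if (is(maps, "RelevanceMap")) maps <- list(maps)
  stopifnot(length(maps) > 0L)
  widths <- vapply(maps, function(m) length(perBase(m)), integer(1L))
  if (length(unique(widths)) != 1L) {
    stop("relevance maps have mixed widths: ",
         paste(unique(widths), collapse = ", "))
  }
  M <- do.call(rbind, lapply(maps, perBase))
  wlab <- rep("all", widths[1L])
  if (!is.null(layout)) {
    for (k in seq_len(nrow(layout))) {
      wlab[layout$start[k]:layout$end[k]] <- layout$window[k]
    }
  }
  data.frame(position = seq_len(widths[1L]), window = wlab,
             mean = colMeans(M),
             sd = if (nrow(M) > 1L) apply(M, 2L, sd) else rep(0, ncol(M)),
             stringsAsFactors = FALSE)
}

#' Explain a trained model on a sequence set
#'
#' Convenience wrapper: decomposes (by default) only the sequences the
#' model calls positive - and, when labels are given, only the true
#' positives, matching how positional importance profiles are usually
#' drawn - then aggregates them into a profile.
#'
#' @param model A trained [SpliceModel-class].
#' @param xs Sequences or encoded array.
#' @param labels Optional 0/1 truth labels.
#' @param positiveOnly Restrict to predicted positives (and true
#'   positives if `labels` given); default `TRUE`. If nothing qualifies,
#'   all sequences are used with a warning.
#' @param threshold Call threshold (default 0.5).
#' @param layout Layout for window annotation; defaults to the junction
#'   or site layout implied by the model's mode and width.
#' @return A profile data.frame as from [aggregatePositions()].
#' @export
explainPredictions <- function(model, xs, labels = NULL, positiveOnly = TRUE,
                               threshold = 0.5, layout = NULL) {
  b <- .asBatch(xs, model@config$inputWidth)
  arr <- array(b$Xm, c(b$n, b$W, 4L))
  keep <- rep(TRUE, b$n)
  if (positiveOnly) {
    p <- predict(model, arr)
    keep <- p >= threshold
    if (!is.null(labels)) keep <- keep & (as.integer(labels) == 1L)
    if (!any(keep)) {
      warning("no (true) positive predictions; explaining all inputs")
      keep <- rep(TRUE, b$n)
    }
  }
  if (is.null(layout)) {
    layout <- switch(modelMode(model),
                     junction = windowLayout(b$W %/% 4L, "junction"),
                     donor_site = windowLayout(b$W %/% 2L, "donor_site"),
                     acceptor_site = windowLayout(b$W %/% 2L, "acceptor_site"))
  }
  maps <- deepTaylorDecomposeSet(model, arr[keep, , , drop = FALSE])
  aggregatePositions(maps, layout)
}

#' Export / read a positional contribution profile
#'
#' Writes the profile as TSV (`position`, `window`, `mean`, `sd`) and
#' optionally draws it to a PNG. The TSV round-trips through
#' [readProfile()].
#'
#' @param profile Profile data.frame from [aggregatePositions()].
#' @param path Output TSV path.
#' @param plot Optional PNG path for a positional bar plot.
#' @return The TSV path, invisibly.
#' @export
exportProfile <- function(profile, path, plot = NULL) {
  stopifnot(all(c("position", "window", "mean", "sd") %in% names(profile)))
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot)) {
    png(plot, width = 900, height = 420)
    on.exit(dev.off())
    plotProfile(profile)
  }
  invisible(path)
}

#' @rdname exportProfile
#' @export
readProfile <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Plot a positional contribution profile
#'
#' @param profile Profile data.frame.
#' @param ... Passed to [plot()].
#' @export
plotProfile <- function(profile, ...) {
  if (!nrow(profile)) {
    plot.new()
    return(invisible(NULL))
  }
  plot(profile$position, profile$mean, type = "h",
       xlab = "position (nt)", ylab = "mean contribution", ...)
  bounds <- cumsum(rle(profile$window)$lengths)
  abline(v = head(bounds, -1L) + 0.5, lty = 2, col = "grey50")
  invisible(NULL)
}
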