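# The convolutional classifier.
#
# Architecture (fixed by design): input [1, W, 4] -> conv(8 filters, 3x1,
# stride 1, length-preserving zero padding, rectifier) -> conv(16 filters,
# 3x1, rectifier) -> flatten -> fully connected (32, rectifier, dropout) ->
# fully connected (2) -> softmax. Convolutions are implemented as im2col
# matrix products; a batch of sequences is held as a [n*W, channels] matrix
# whose rows are ordered position-major (all samples at position 1, then
# position 2, ...), so a shift by one position is a shift by n rows.

#' Hyperparameter configuration for a splice model
#'
#' @param inputWidth Sequence width in nt: 120 for junction mode, 60 for
#'   site mode (always `4*flank` or `2*flank`).
#' @param conv1Features,conv2Features Feature maps in the two convolutional
#'   layers (defaults 8 and 16).
#' @param filterWidth Convolution filter width (default 3; filters are
#'   `filterWidth x 1`).
#' @param fcUnits Fully-connected layer width (default 32).
#' @param dropoutRate Dropout probability on the fully-connected layer
#'   during training (default 0.5).
#' @param l2 L2 penalty coefficient on weights, biases excluded
#'   (default 1e-4).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize Mini-batch size (default 64).
#' @param maxEpochs Training epoch cap (default 100).
#' @param patience Early-stopping patience: stop after this many epochs
#'   without validation-loss improvement (default 10; `Inf` disables).
#' @param classWeights If `TRUE`, weight the loss by inverse class
#'   frequency (for imbalanced sets such as 1:10 benchmarks); default off.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; identical (config, data) pairs reproduce identical training
#'   logs.
#' @return A validated config list of class `spliceModelConfig`.
#' @export
spliceModelConfig <- function(inputWidth = 120L, conv1Features = 8L,
                              conv2Features = 16L, filterWidth = 3L,
                              fcUnits = 32L, dropoutRate = 0.5,
                              l2 = 1e-4, learningRate = 1e-3,
                              batchSize = 64L, maxEpochs = 100L,
                              patience = 10L, classWeights = FALSE,
                              seed = 1L) {
  cfg <- list(inputWidth = as.integer(inputWidth),
              conv1Features = as.integer(conv1Features),
              conv2Features = as.integer(conv2Features),
              filterWidth = as.integer(filterWidth),
              fcUnits = as.integer(fcUnits),
              dropoutRate = dropoutRate, l2 = l2,
              learningRate = learningRate,
              batchSize = as.integer(batchSize),
              maxEpochs = as.integer(maxEpochs),
              patience = patience,
              classWeights = isTRUE(classWeights),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(inputWidth >= 1L, conv1Features >= 1L, conv2Features >= 1L,
              fcUnits >= 1L, batchSize >= 1L, maxEpochs >= 1L,
              dropoutRate >= 0, dropoutRate < 1, l2 >= 0, learningRate > 0)
    if (filterWidth < 1L || filterWidth > inputWidth) {
      stop("filterWidth must be in [1, inputWidth]")
    }
  })
  class(cfg) <- "spliceModelConfig"
  cfg
}

# Run `expr` under a private RNG stream without disturbing the caller's.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Build an (untrained) splice model
#'
#' Allocates all layer parameters with seeded He-scaled normal
#' initialisation (biases zero). Two builds with the same config are
#' bitwise identical.
#'
#' @param config A [spliceModelConfig()].
#' @param mode Classification mode the model is intended for:
#'   `"junction"`, `"donor_site"` or `"acceptor_site"`.
#' @return An untrained [SpliceModel-class].
#' @export
buildSpliceModel <- function(config = spliceModelConfig(),
                             mode = c("junction", "donor_site", "acceptor_site")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "spliceModelConfig"))
  w <- .withSeed(config$seed, {
    fw <- config$filterWidth
    he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    list(K1 = he(fw * 4L, config$conv1Features),
         b1 = numeric(config$conv1Features),
         K2 = he(fw * config$conv1Features, config$conv2Features),
         b2 = numeric(config$conv2Features),
         W3 = he(config$inputWidth * config$conv2Features, config$fcUnits),
         b3 = numeric(config$fcUnits),
         W4 = he(config$fcUnits, 2L),
         b4 = numeric(2L))
  })
  new("SpliceModel", config = config, weights = w,
      log = data.frame(epoch = integer(), trainLoss = numeric(),
                       validLoss = numeric(), validAccuracy = numeric()),
      mode = mode, trained = FALSE)
}

# ---- internal numeric core -------------------------------------------------

# Position-major im2col for a batch matrix Xm [n*W, C] with length-
# preserving zero padding; returns [n*W, fw*C], offset-major columns.
.im2col <- function(Xm, n, W, C, fw) {
  if (fw == 1L) return(Xm)
  padL <- (fw - 1L) %/% 2L
  padR <- fw - 1L - padL
  Xp <- rbind(matrix(0, n * padL, C), Xm, matrix(0, n * padR, C))
  out <- matrix(0, n * W, fw * C)
  for (d in 0:(fw - 1L)) {
    out[, (d * C + 1L):((d + 1L) * C)] <-
      Xp[(d * n + 1L):(d * n + n * W), , drop = FALSE]
  }
  out
}

# Adjoint of .im2col: scatter-add column blocks back to input rows.
.col2im <- function(dXc, n, W, C, fw) {
  if (fw == 1L) return(dXc)
  padL <- (fw - 1L) %/% 2L
  padR <- fw - 1L - padL
  acc <- matrix(0, n * (W + padL + padR), C)
  for (d in 0:(fw - 1L)) {
    rng <- (d * n + 1L):(d * n + n * W)
    acc[rng, ] <- acc[rng, ] + dXc[, (d * C + 1L):((d + 1L) * C), drop = FALSE]
  }
  acc[(padL * n + 1L):(padL * n + n * W), , drop = FALSE]
}

.relu <- function(x) { x[x < 0] <- 0; x }

.softmax <- function(z) {
  p <- exp(z - apply(z, 1L, max))
  p / rowSums(p)
}

# Coerce inputs (character/DNAStringSet/array) to the internal batch
# matrix [n*W, 4] (position-major) and return with n, W.
.asBatch <- function(x, inputWidth = NULL) {
  if (is.character(x) || inherits(x, "XStringSet")) x <- encodeSequences(x)
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3L] == 4L)
  n <- dim(x)[1L]; W <- dim(x)[2L]
  if (!is.null(inputWidth) && W != inputWidth) {
    stop("shape error: input width ", W, " does not match model input width ",
         inputWidth)
  }
  list(Xm = matrix(x, n * W, 4L), n = n, W = W)
}

# Forward pass on a batch matrix; returns all intermediates when keep=TRUE.
.forward <- function(w, cfg, Xm, n, keep = FALSE, dropMask = NULL) {
  W <- cfg$inputWidth; fw <- cfg$filterWidth
  F1 <- cfg$conv1Features; F2 <- cfg$conv2Features
  Xc1 <- .im2col(Xm, n, W, 4L, fw)
  Z1 <- sweep(Xc1 %*% w$K1, 2L, w$b1, "+")
  H1 <- .relu(Z1)
  Xc2 <- .im2col(H1, n, W, F1, fw)
  Z2 <- sweep(Xc2 %*% w$K2, 2L, w$b2, "+")
  H2 <- .relu(Z2)
  Fl <- matrix(aperm(array(H2, c(n, W, F2)), c(1L, 3L, 2L)), n, F2 * W)
  Z3 <- sweep(Fl %*% w$W3, 2L, w$b3, "+")
  H3 <- .relu(Z3)
  H3d <- if (is.null(dropMask)) H3 else H3 * dropMask
  Z4 <- sweep(H3d %*% w$W4, 2L, w$b4, "+")
  P <- .softmax(Z4)
  if (!keep) return(list(P = P, Z4 = Z4))
  list(Xc1 = Xc1, Z1 = Z1, H1 = H1, Xc2 = Xc2, Z2 = Z2, H2 = H2,
       Fl = Fl, Z3 = Z3, H3 = H3, H3d = H3d, Z4 = Z4, P = P)
}

# Gradients of mean (weighted) cross-entropy + l2 * sum(weights^2).
.backward <- function(w, cfg, fw, n, fwd, Y, sampleWeight) {
  W <- cfg$inputWidth; F1 <- cfg$conv1Features; F2 <- cfg$conv2Features
  kw <- cfg$filterWidth
  dZ4 <- (fwd$P - Y) * (sampleWeight / sum(sampleWeight))
  dW4 <- crossprod(fwd$H3d, dZ4) + 2 * cfg$l2 * w$W4
  db4 <- colSums(dZ4)
  dH3 <- tcrossprod(dZ4, w$W4)
  if (!is.null(fwd$dropMask)) dH3 <- dH3 * fwd$dropMask
  dZ3 <- dH3 * (fwd$Z3 > 0)
  dW3 <- crossprod(fwd$Fl, dZ3) + 2 * cfg$l2 * w$W3
  db3 <- colSums(dZ3)
  dFl <- tcrossprod(dZ3, w$W3)
  dH2 <- matrix(aperm(array(dFl, c(n, F2, W)), c(1L, 3L, 2L)), n * W, F2)
  dZ2 <- dH2 * (fwd$Z2 > 0)
  dK2 <- crossprod(fwd$Xc2, dZ2) + 2 * cfg$l2 * w$K2
  db2 <- colSums(dZ2)
  dH1 <- .col2im(tcrossprod(dZ2, w$K2), n, W, F1, kw)
  dZ1 <- dH1 * (fwd$Z1 > 0)
  dK1 <- crossprod(fwd$Xc1, dZ1) + 2 * cfg$l2 * w$K1
  db1 <- colSums(dZ1)
  list(K1 = dK1, b1 = db1, K2 = dK2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

.ceLoss <- function(P, Y, sampleWeight, l2, w) {
  eps <- 1e-12
  ll <- -rowSums(Y * log(P + eps))
  sum(ll * sampleWeight) / sum(sampleWeight) +
    l2 * (sum(w$K1^2) + sum(w$K2^2) + sum(w$W3^2) + sum(w$W4^2))
}

# ---- training --------------------------------------------------------------

#' Train a splice model
#'
#' Minimises 2-class cross-entropy plus an L2 weight penalty by Adam over
#' seeded mini-batches. Dropout is active only during training. The
#' returned model carries the parameter state of the epoch with the best
#' validation loss and a per-epoch training log; training is fully
#' reproducible given the config seed.
#'
#' @param model An untrained (or trained) [SpliceModel-class].
#' @param x Training inputs: encoded array `[n, width, 4]`, character
#'   vector of sequences, or DNAStringSet.
#' @param y Binary labels (0 = false, 1 = true junction/site).
#' @param xValid,yValid Validation set, disjoint from training, used for
#'   checkpoint selection and early stopping. If omitted, the training
#'   loss is used instead (documented fallback, not recommended).
#' @param verbose Print one line per epoch.
#' @return The trained [SpliceModel-class].
#' @export
trainSpliceModel <- function(model, x, y, xValid = NULL, yValid = NULL,
                             verbose = FALSE) {
  stopifnot(is(model, "SpliceModel"))
  cfg <- model@config
  b <- .asBatch(x, cfg$inputWidth)
  y <- as.integer(y)
  if (b$n == 0L) stop("empty training set")
  if (length(y) != b$n) stop("x and y lengths differ")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  for (cls in c(0L, 1L)) {
    if (!any(y == cls)) {
      stop("single-class training set: class ", cls, " is missing")
    }
  }
  hasValid <- !is.null(xValid)
  if (hasValid) {
    vb <- .asBatch(xValid, cfg$inputWidth)
    yv <- as.integer(yValid)
    stopifnot(length(yv) == vb$n)
  }
  n <- b$n; W <- cfg$inputWidth
  Y <- cbind(1 - y, y)  # column 2 = "true"
  classW <- if (cfg$classWeights) {
    cw <- n / (2 * c(sum(y == 0L), sum(y == 1L)))
    cw[y + 1L]
  } else rep(1, n)

  w <- model@weights
  adamM <- lapply(w, function(z) z * 0)
  adamV <- adamM
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  step <- 0L

  logRows <- vector("list", cfg$maxEpochs)
  best <- list(loss = Inf, weights = w, epoch = 0L)
  sinceBest <- 0L

  .withSeed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / cfg$batchSize)
      epochLoss <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * cfg$batchSize + 1L):min(bi * cfg$batchSize, n)]
        m <- length(idx)
        rows <- rep(idx, times = W) + rep((0:(W - 1L)) * n, each = m)
        Xb <- b$Xm[rows, , drop = FALSE]
        dropMask <- if (cfg$dropoutRate > 0) {
          matrix(rbinom(m * cfg$fcUnits, 1L, 1 - cfg$dropoutRate),
                 m, cfg$fcUnits) / (1 - cfg$dropoutRate)
        } else NULL
        fwd <- .forward(w, cfg, Xb, m, keep = TRUE, dropMask = dropMask)
        fwd$dropMask <- dropMask
        sw <- classW[idx]
        epochLoss <- epochLoss + .ceLoss(fwd$P, Y[idx, , drop = FALSE], sw,
                                         cfg$l2, w) * m
        grad <- .backward(w, cfg, cfg$filterWidth, m, fwd,
                          Y[idx, , drop = FALSE], sw)
        step <- step + 1L
        for (nm in names(w)) {
          adamM[[nm]] <- beta1 * adamM[[nm]] + (1 - beta1) * grad[[nm]]
          adamV[[nm]] <- beta2 * adamV[[nm]] + (1 - beta2) * grad[[nm]]^2
          mhat <- adamM[[nm]] / (1 - beta1^step)
          vhat <- adamV[[nm]] / (1 - beta2^step)
          w[[nm]] <- w[[nm]] - cfg$learningRate * mhat / (sqrt(vhat) + adamEps)
        }
      }
      trainLoss <- epochLoss / n
      if (hasValid) {
        vp <- .predictCore(w, cfg, vb$Xm, vb$n)
        validLoss <- .ceLoss(vp$P, cbind(1 - yv, yv), rep(1, vb$n), cfg$l2, w)
        validAcc <- mean((vp$P[, 2L] >= 0.5) == (yv == 1L))
      } else {
        validLoss <- trainLoss
        validAcc <- NA_real_
      }
      logRows[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                     validLoss = validLoss,
                                     validAccuracy = validAcc)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  valid %.4f  acc %.4f",
                        epoch, trainLoss, validLoss, validAcc))
      }
      if (validLoss < best$loss - 1e-9) {
        best <- list(loss = validLoss, weights = w, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$patience) break
      }
    }
  })

  model@weights <- best$weights
  model@log <- do.call(rbind, logRows[!vapply(logRows, is.null, logical(1L))])
  model@trained <- TRUE
  validObject(model)
  model
}

# Batched deterministic inference on an internal batch matrix.
.predictCore <- function(w, cfg, Xm, n, chunk = 512L) {
  W <- cfg$inputWidth
  P <- matrix(NA_real_, n, 2L)
  Z <- matrix(NA_real_, n, 2L)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    rows <- rep(idx, times = W) + rep((0:(W - 1L)) * n, each = length(idx))
    f <- .forward(w, cfg, Xm[rows, , drop = FALSE], length(idx))
    P[idx, ] <- f$P
    Z[idx, ] <- f$Z4
  }
  list(P = P, Z4 = Z)
}

#' Predict splice junction/site probabilities
#'
#' Deterministic batched inference (dropout disabled, order preserving).
#' Class probabilities are the softmax of the two output logits; `p_true`
#' is the probability of the "real junction/site" class.
#'
#' @param object A trained [SpliceModel-class].
#' @param x Encoded array `[n, width, 4]`, character sequences, or
#'   DNAStringSet; width must match the model's `inputWidth`.
#' @param type `"prob"` (default) returns `p_true`; `"logits"` the raw
#'   two-class scores; `"class"` thresholded 0/1 calls.
#' @param threshold Decision threshold for `type = "class"` (ties call
#'   positive).
#' @param ... Unused.
#' @return Numeric vector (`prob`, `class`) or two-column matrix
#'   (`logits`).
#' @export
setMethod("predict", "SpliceModel",
          function(object, x, type = c("prob", "logits", "class"),
                   threshold = 0.5, ...) {
  type <- match.arg(type)
  cfg <- object@config
  b <- .asBatch(x, cfg$inputWidth)
  out <- .predictCore(object@weights, cfg, b$Xm, b$n)
  switch(type,
         prob = out$P[, 2L],
         logits = out$Z4,
         class = as.integer(out$P[, 2L] >= threshold))
})

#' Combine donor- and acceptor-site probabilities
#'
#' The probability that a junction is real in site-pair mode is the product
#' of the probabilities that its donor site and its acceptor site are real,
#' the two site classification events being treated as independent.
#'
#' @param pDonor,pAcceptor Probabilities in `[0, 1]` (recycled).
#' @return `pDonor * pAcceptor`.
#' @export
#' @examples
#' combineSiteProbabilities(0.5, 0.5)  # 0.25
combineSiteProbabilities <- function(pDonor, pAcceptor) {
  if (any(pDonor < 0 | pDonor > 1, na.rm = TRUE) ||
      any(pAcceptor < 0 | pAcceptor > 1, na.rm = TRUE)) {
    stop("domain error: probabilities must lie in [0, 1]")
  }
  pDonor * pAcceptor
}

#' Classify a junction table against a genome
#'
#' Assembles the paired-window sequence of every junction, encodes it and
#' scores it: in `"junction"` mode with a single junction model; in
#' `"site_pair"` mode by splitting into the 60-nt donor and acceptor
#' windows, scoring each with its site model and multiplying the
#' probabilities ([combineSiteProbabilities()]). Assembly failures are
#' reported per junction (NA score), never fatal for the batch.
#'
#' @param genome Genome as in [assembleJunctionSequence()].
#' @param junctions A junction table.
#' @param model Junction-mode [SpliceModel-class] (for `mode="junction"`).
#' @param donorModel,acceptorModel Site-mode models (for
#'   `mode="site_pair"`).
#' @param mode `"junction"` or `"site_pair"`.
#' @param threshold Decision threshold; scores at the threshold call
#'   positive.
#' @return The junction table with columns `p_true`, `call` (logical) and
#'   `note` (NA unless assembly failed).
#' @export
classifyJunctions <- function(genome, junctions, model = NULL,
                              donorModel = NULL, acceptorModel = NULL,
                              mode = c("junction", "site_pair"),
                              threshold = 0.5) {
  mode <- match.arg(mode)
  if (mode == "junction") {
    stopifnot(is(model, "SpliceModel"))
    if (modelMode(model) != "junction") {
      stop("model mode '", modelMode(model), "' does not match 'junction'")
    }
    flank <- model@config$inputWidth %/% 4L
  } else {
    stopifnot(is(donorModel, "SpliceModel"), is(acceptorModel, "SpliceModel"))
    if (modelMode(donorModel) != "donor_site" ||
        modelMode(acceptorModel) != "acceptor_site") {
      stop("site_pair mode needs a donor_site and an acceptor_site model")
    }
    flank <- donorModel@config$inputWidth %/% 2L
  }
  seqs <- assembleJunctionSequence(genome, junctions, flank = flank,
                                   onError = "report")
  note <- attr(seqs, "note")
  ok <- !is.na(seqs)
  p <- rep(NA_real_, length(seqs))
  if (any(ok)) {
    if (mode == "junction") {
      p[ok] <- predict(model, seqs[ok])
    } else {
      sites <- splitJunctionIntoSites(seqs[ok], flank = flank)
      p[ok] <- combineSiteProbabilities(
        predict(donorModel, sites$donor),
        predict(acceptorModel, sites$acceptor))
    }
  }
  out <- junctions
  out$p_true <- p
  out$call <- p >= threshold
  out$note <- if (is.null(note)) NA_character_ else note
  out
}

#' Save / load a splice model checkpoint
#'
#' The checkpoint is a self-describing list (format version, config,
#' weights, mode, training log, channel order) serialised with `saveRDS`.
#' Loading validates the stored shapes against the config (including
#' `inputWidth`) and the channel order against the package constant.
#'
#' @param model A [SpliceModel-class].
#' @param path Checkpoint file path.
#' @return `saveSpliceModel`: the path, invisibly. `loadSpliceModel`: the
#'   restored model.
#' @export
saveSpliceModel <- function(model, path) {
  stopifnot(is(model, "SpliceModel"))
  saveRDS(list(format = "SpliceJudge-checkpoint-1",
               channels = spliceChannels(),
               config = model@config, mode = model@mode,
               weights = model@weights, log = model@log,
               trained = model@trained),
          path)
  invisible(path)
}

#' @rdname saveSpliceModel
#' @export
loadSpliceModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "SpliceJudge-checkpoint-1")) {
    stop("not a SpliceJudge checkpoint: ", path)
  }
  if (!identical(ck$channels, spliceChannels())) {
    stop("checkpoint channel order ", paste(ck$channels, collapse = ""),
         " does not match this package's ",
         paste(spliceChannels(), collapse = ""))
  }
  m <- new("SpliceModel", config = ck$config, weights = ck$weights,
           log = ck$log, mode = ck$mode, trained = ck$trained)
  validObject(m)  # validates all shapes against inputWidth/config
  m
}
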