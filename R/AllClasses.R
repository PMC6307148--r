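# S4 classes for the trained classifier and per-nucleotide relevance maps.

# configs are classed S3 lists; register them so they can live in S4 slots
setOldClass(c("spliceModelConfig", "list"))
setOldClass(c("generatorConfig", "list"))

#' SpliceModel: a convolutional splice junction/site classifier
#'
#' Holds the architecture hyperparameters, all layer weights, the
#' per-epoch training log and the classification mode. Build with
#' [buildSpliceModel()], fit with [trainSpliceModel()], apply with
#' [predict()].
#'
#' @slot config List of hyperparameters from [spliceModelConfig()].
#' @slot weights Named list of weight matrices/vectors (`K1`, `b1`, `K2`,
#'   `b2`, `W3`, `b3`, `W4`, `b4`); shapes are fully determined by the
#'   config.
#' @slot log Per-epoch data.frame (`epoch`, `trainLoss`, `validLoss`,
#'   `validAccuracy`).
#' @slot mode One of `"junction"`, `"donor_site"`, `"acceptor_site"`.
#' @slot trained Logical scalar.
#' @exportClass SpliceModel
setClass("SpliceModel",
         representation(config = "list", weights = "list",
                        log = "data.frame", mode = "character",
                        trained = "logical"))

setValidity("SpliceModel", function(object) {
  cfg <- object@config
  if (!object@mode %in% c("junction", "donor_site", "acceptor_site")) {
    return("mode must be junction, donor_site or acceptor_site")
  }
  w <- object@weights
  need <- c("K1", "b1", "K2", "b2", "W3", "b3", "W4", "b4")
  if (!all(need %in% names(w))) {
    return(paste("weights must contain", paste(need, collapse = ", ")))
  }
  fw <- cfg$filterWidth
  exp <- list(K1 = c(fw * 4L, cfg$conv1Features),
              K2 = c(fw * cfg$conv1Features, cfg$conv2Features),
              W3 = c(cfg$inputWidth * cfg$conv2Features, cfg$fcUnits),
              W4 = c(cfg$fcUnits, 2L))
  for (nm in names(exp)) {
    if (!identical(dim(w[[nm]]), as.integer(exp[[nm]]))) {
      return(paste0("weight ", nm, " has wrong shape for the config"))
    }
  }
  if (length(w$b1) != cfg$conv1Features || length(w$b2) != cfg$conv2Features ||
      length(w$b3) != cfg$fcUnits || length(w$b4) != 2L) {
    return("bias length inconsistent with config")
  }
  TRUE
})

#' @describeIn SpliceModel Compact summary.
#' @param object A `SpliceModel`.
#' @export
setMethod("show", "SpliceModel", function(object) {
  cfg <- object@config
  cat("SpliceModel (", object@mode, " mode, ",
      if (object@trained) "trained" else "untrained", ")\n", sep = "")
  cat("  input width: ", cfg$inputWidth, " nt x 4 channels (",
      paste(spliceChannels(), collapse = ""), ")\n", sep = "")
  cat("  conv ", cfg$conv1Features, " -> conv ", cfg$conv2Features,
      " (filters ", cfg$filterWidth, "x1) -> fc ", cfg$fcUnits,
      " -> 2\n", sep = "")
  cat("  parameters: ", nParameters(object), "\n", sep = "")
  if (nrow(object@log)) {
    best <- which.min(object@log$validLoss)
    cat("  best epoch ", object@log$epoch[best], ": valid loss ",
        signif(object@log$validLoss[best], 4L), ", valid accuracy ",
        signif(object@log$validAccuracy[best], 4L), "\n", sep = "")
  }
  invisible(object)
})

#' Accessors for SpliceModel
#'
#' @param model A [SpliceModel-class] object.
#' @return `modelConfig`: the hyperparameter list; `modelWeights`: the
#'   weight list; `trainingLog`: per-epoch data.frame; `modelMode`: the
#'   mode string; `isTrained`: logical; `nParameters`: total parameter
#'   count.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
modelConfig <- function(model) model@config

#' @rdname model-accessors
#' @export
modelWeights <- function(model) model@weights

#' @rdname model-accessors
#' @export
trainingLog <- function(model) model@log

#' @rdname model-accessors
#' @export
modelMode <- function(model) model@mode

#' @rdname model-accessors
#' @export
isTrained <- function(model) model@trained

#' @rdname model-accessors
#' @export
nParameters <- function(model) {
  sum(vapply(model@weights, length, integer(1L)))
}

#' RelevanceMap: per-nucleotide contribution scores
#'
#' Result of [deepTaylorDecompose()]: the model's positive-class score
#' redistributed onto every (position, channel) of the input tensor.
#'
#' @slot perChannel Numeric matrix `[width, 4]` of nonnegative
#'   contributions in the package channel order.
#' @slot perBase Numeric vector of per-position contributions
#'   (`rowSums(perChannel)`).
#' @slot output The decomposed output quantity (pre-normalisation
#'   positive-class score, clamped at 0).
#' @slot residuals Named numeric: relevance dropped per layer where a
#'   redistribution denominator vanished.
#' @slot rules Character: the redistribution rule used per layer.
#' @exportClass RelevanceMap
setClass("RelevanceMap",
         representation(perChannel = "matrix", perBase = "numeric",
                        output = "numeric", residuals = "numeric",
                        rules = "character"))

setValidity("RelevanceMap", function(object) {
  if (ncol(object@perChannel) != 4L) return("perChannel must have 4 columns")
  if (length(object@perBase) != nrow(object@perChannel)) {
    return("perBase length must match perChannel rows")
  }
  if (max(abs(object@perBase - rowSums(object@perChannel))) > 1e-8) {
    return("perBase must be the channel sum of perChannel")
  }
  if (any(object@perBase < -1e-9)) return("relevance must be nonnegative")
  TRUE
})

#' @describeIn RelevanceMap Compact summary.
#' @param object A `RelevanceMap`.
#' @export
setMethod("show", "RelevanceMap", function(object) {
  cat("RelevanceMap over ", length(object@perBase), " positions\n", sep = "")
  cat("  decomposed output: ", signif(object@output, 5L),
      "; total relevance: ", signif(sum(object@perBase), 5L), "\n", sep = "")
  cat("  rules: ", paste(object@rules, collapse = ", "), "\n", sep = "")
  if (any(object@residuals != 0)) {
    cat("  residuals: ", paste(names(object@residuals), "=",
                               signif(object@residuals, 3L), collapse = ", "),
        "\n", sep = "")
  }
  invisible(object)
})

#' Accessors for RelevanceMap
#'
#' @param map A [RelevanceMap-class] object.
#' @return `perBase`: per-position contribution vector; `perChannel`:
#'   position-by-channel matrix; `decomposedOutput`: the redistributed
#'   score; `taylorResiduals`: per-layer dropped relevance.
#' @name relevance-accessors
NULL

#' @rdname relevance-accessors
#' @export
perBase <- function(map) map@perBase

#' @rdname relevance-accessors
#' @export
perChannel <- function(map) map@perChannel

#' @rdname relevance-accessors
#' @export
decomposedOutput <- function(map) map@output

#' @rdname relevance-accessors
#' @export
taylorResiduals <- function(map) map@residuals
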