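# One-hot sequence encoding.
#
# Channel order is fixed package-wide: channel 1 = T, 2 = G, 3 = C, 4 = A,
# so that A -> [0,0,0,1], C -> [0,0,1,0], G -> [0,1,0,0], T -> [1,0,0,0] and
# the ambiguous base N -> [0.25,0.25,0.25,0.25]. Every encoded position sums
# to exactly 1; definite bases are orthonormal basis vectors.

.CHANNELS <- c("T", "G", "C", "A")

# IUPAC ambiguity codes (everything definite-but-ambiguous) collapse to N;
# reference genomes contain them and N already encodes uncertainty.
.IUPAC_TO_N <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.ENCODE_LOOKUP <- local({
  m <- rbind(
    A = c(0, 0, 0, 1),
    C = c(0, 0, 1, 0),
    G = c(0, 1, 0, 0),
    T = c(1, 0, 0, 0),
    U = c(1, 0, 0, 0),
    N = rep(0.25, 4)
  )
  extra <- matrix(0.25, length(.IUPAC_TO_N), 4,
                  dimnames = list(.IUPAC_TO_N, NULL))
  m <- rbind(m, extra[setdiff(.IUPAC_TO_N, rownames(m)), , drop = FALSE])
  colnames(m) <- .CHANNELS
  m
})

#' Channel order of the one-hot encoding
#'
#' Returns the fixed channel order used by every encoder, model and
#' relevance map in the package. Channel `k` of an encoded tensor carries
#' the indicator for base `spliceChannels()[k]`.
#'
#' @return Character vector of length 4, `c("T","G","C","A")`.
#' @export
#' @examples
#' spliceChannels()
spliceChannels <- function() .CHANNELS

#' Encode a single base as a 4-channel probability vector
#'
#' Definite bases map to orthonormal basis vectors in the package channel
#' order ([spliceChannels()]); `N` and every other IUPAC ambiguity code map
#' to the uniform vector `c(0.25, 0.25, 0.25, 0.25)`. `U` is treated as `T`.
#'
#' @param base A single character (case-insensitive).
#' @return Numeric vector of length 4 summing to 1, named by channel.
#' @export
#' @examples
#' encodeBase("A")  # c(0, 0, 0, 1)
#' encodeBase("n")  # uniform
encodeBase <- function(base) {
  stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
  b <- toupper(base)
  if (!b %in% rownames(.ENCODE_LOOKUP)) {
    stop("invalid-input: '", base, "' at position 1 is not an IUPAC nucleotide code")
  }
  .ENCODE_LOOKUP[b, ]
}

#' One-hot encode a set of equal-length sequences
#'
#' Converts sequences over `{A,C,G,T,N}` (other IUPAC ambiguity codes are
#' collapsed to `N`) into a rank-3 numeric array of shape
#' `[n, width, 4]` in the fixed channel order [spliceChannels()]. Each
#' per-position channel vector sums to 1 and the encoding is invertible for
#' definite bases.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of sequences,
#'   all of the same length.
#' @return Numeric array of dimension `c(length(seqs), width, 4)`.
#' @export
#' @examples
#' x <- encodeSequences(c("ACGT", "NNNN"))
#' dim(x)                 # 2 4 4
#' rowSums(x[1, , ])      # all 1
encodeSequences <- function(seqs) {
  seqs <- .asSequenceCharacter(seqs)
  if (length(seqs) == 0L) stop("no sequences to encode")
  widths <- nchar(seqs)
  if (any(widths == 0L)) stop("sequence length must be > 0")
  if (length(unique(widths)) != 1L) {
    stop("sequences must all have the same length; got widths ",
         paste(unique(widths), collapse = ", "))
  }
  w <- widths[1L]
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = n, ncol = w, byrow = TRUE)
  idx <- match(chars, rownames(.ENCODE_LOOKUP))
  dim(idx) <- dim(chars)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1L, ]
    stop("invalid-input: '", chars[bad[1L], bad[2L]], "' in sequence ",
         bad[1L], " at position ", bad[2L],
         " is not an IUPAC nucleotide code")
  }
  enc <- .ENCODE_LOOKUP[idx, , drop = FALSE]     # (n*w) x 4, n fastest
  array(enc, dim = c(n, w, 4L),
        dimnames = list(NULL, NULL, .CHANNELS))
}

#' Decode an encoded tensor back to sequences
#'
#' Inverse of [encodeSequences()] for definite bases; uniform positions
#' decode to `N`.
#'
#' @param x Array of dimension `[n, width, 4]`.
#' @return Character vector of length `n`.
#' @export
decodeSequences <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3L] == 4L)
  n <- dim(x)[1L]; w <- dim(x)[2L]
  out <- character(n)
  for (i in seq_len(n)) {
    m <- x[i, , , drop = TRUE]
    if (w == 1L) m <- matrix(m, 1L, 4L)
    hit <- max.col(m)
    base <- ifelse(m[cbind(seq_len(w), hit)] >= 0.999, .CHANNELS[hit], "N")
    out[i] <- paste(base, collapse = "")
  }
  out
}

.asSequenceCharacter <- function(seqs) {
  if (inherits(seqs, "XStringSet") || inherits(seqs, "XString")) {
    seqs <- as.character(seqs)
  }
  if (!is.character(seqs)) stop("sequences must be character or DNAStringSet")
  unname(seqs)
}
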