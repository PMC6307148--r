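# Assembly of fixed-length paired-window junction sequences from a genome.
#
# A junction-mode sequence is the concatenation of four flank-length
# windows, always emitted donor-to-acceptor in transcript orientation:
#   [donor exon | donor intron | acceptor intron | acceptor exon]
# For a canonical junction the intron starts with GT (positions flank+1,
# flank+2 of the emitted string) and ends with AG (positions 3*flank-1,
# 3*flank).

#' Read a genome FASTA
#'
#' Loads a (small) reference genome for random access by the assembly and
#' filtering functions. Sequence names are trimmed to the first whitespace
#' token.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Normalise a genome to a named character vector chrom -> sequence.
.genomeAsCharacter <- function(genome) {
  if (inherits(genome, "XStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- genome
  } else if (is.list(genome)) {
    g <- vapply(genome, .asSequenceCharacter, character(1L))
  } else {
    stop("genome must be a DNAStringSet or named character vector")
  }
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    if (length(g) == 1L) names(g) <- "chr1" else stop("genome sequences must be named")
  }
  toupper(g)
}

.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Vectorised window extraction with bounds checking.
.extractWindows <- function(chromSeq, start, end, what = "window") {
  len <- nchar(chromSeq)
  if (any(start < 1L) || any(end > len)) {
    bad <- which(start < 1L | end > len)[1L]
    stop("boundary error: ", what, " [", start[bad], ", ", end[bad],
         "] outside chromosome of length ", len)
  }
  substring(chromSeq, start, end)
}

#' Window layout of a junction or site sequence
#'
#' Describes how the emitted sequence partitions into exonic/intronic
#' sub-windows (no gaps, no overlap).
#'
#' @param flank Sub-window length in nt (default 30).
#' @param mode `"junction"` (four windows, width `4*flank`),
#'   `"donor_site"` or `"acceptor_site"` (two windows, width `2*flank`).
#' @return A data.frame with columns `window`, `start`, `end` (1-based
#'   inclusive offsets into the emitted sequence).
#' @export
#' @examples
#' windowLayout(30, "junction")
windowLayout <- function(flank = 30L,
                         mode = c("junction", "donor_site", "acceptor_site")) {
  mode <- match.arg(mode)
  f <- as.integer(flank)
  if (mode == "junction") {
    data.frame(
      window = c("donor_exon", "donor_intron", "acceptor_intron", "acceptor_exon"),
      start = c(1L, f + 1L, 2L * f + 1L, 3L * f + 1L),
      end = c(f, 2L * f, 3L * f, 4L * f),
      stringsAsFactors = FALSE
    )
  } else if (mode == "donor_site") {
    data.frame(window = c("donor_exon", "donor_intron"),
               start = c(1L, f + 1L), end = c(f, 2L * f),
               stringsAsFactors = FALSE)
  } else {
    data.frame(window = c("acceptor_intron", "acceptor_exon"),
               start = c(1L, f + 1L), end = c(f, 2L * f),
               stringsAsFactors = FALSE)
  }
}

#' Assemble paired-window junction sequences from a genome
#'
#' For a junction on strand `+` the emitted sequence is
#' `G[donor-flank+1..donor] G[donor+1..donor+flank]
#'  G[acceptor-flank..acceptor-1] G[acceptor..acceptor+flank-1]`,
#' uppercased. For strand `-` the same genomic windows are taken and the
#' whole construct is reverse-complemented, so that the sequence always
#' reads donor-to-acceptor in transcript orientation (the model must see
#' donor context first). For a canonical junction, positions
#' `flank+1..flank+2` read `GT` and positions `3*flank-1..3*flank` read
#' `AG`.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [readGenome()]) or named
#'   character vector.
#' @param junctions A junction table (see [junctionTable()]).
#' @param flank Sub-window length, >= 2 (default 30).
#' @param onError `"stop"` (default) aborts on the first out-of-bounds
#'   window or unknown chromosome; `"report"` emits `NA` for the failing
#'   junctions and records the reason in the `note` attribute column.
#' @return A character vector of sequences of width `4*flank`, named by
#'   junction id, with attributes `flank` and `layout`
#'   (see [windowLayout()]). Under `onError = "report"` failed entries are
#'   `NA` and a `note` attribute holds per-junction messages.
#' @export
#' @examples
#' g <- c(chr1 = "AAAAGTTTTTAGCCCC")
#' j <- junctionTable("chr1", donor = 4, acceptor = 13)
#' assembleJunctionSequence(g, j, flank = 2)  # "AAGTAGCC"
assembleJunctionSequence <- function(genome, junctions, flank = 30L,
                                     onError = c("stop", "report")) {
  onError <- match.arg(onError)
  flank <- as.integer(flank)
  if (flank < 2L) stop("flank must be >= 2")
  junctions <- validateJunctions(junctions)
  g <- .genomeAsCharacter(genome)
  n <- nrow(junctions)
  out <- rep(NA_character_, n)
  note <- rep(NA_character_, n)
  for (ch in unique(junctions$chrom)) {
    sel <- which(junctions$chrom == ch)
    if (!ch %in% names(g)) {
      msg <- paste0("lookup error: chromosome '", ch, "' absent from genome")
      if (onError == "stop") stop(msg)
      note[sel] <- msg
      next
    }
    cs <- g[[ch]]
    len <- nchar(cs)
    jd <- junctions$donor[sel]
    ja <- junctions$acceptor[sel]
    lo <- jd - flank + 1L
    hi <- ja + flank - 1L
    ok <- lo >= 1L & hi <= len
    if (any(!ok)) {
      msg <- paste0("boundary error: windows [", lo[!ok][1L], ", ",
                    hi[!ok][1L], "] outside chromosome '", ch,
                    "' of length ", len)
      if (onError == "stop") stop(msg)
      note[sel[!ok]] <- paste0("boundary error: windows outside chromosome '",
                               ch, "'")
    }
    if (any(ok)) {
      i <- sel[ok]
      jd <- junctions$donor[i]; ja <- junctions$acceptor[i]
      seq <- paste0(
        substring(cs, jd - flank + 1L, jd),        # donor exon
        substring(cs, jd + 1L, jd + flank),        # donor intron
        substring(cs, ja - flank, ja - 1L),        # acceptor intron
        substring(cs, ja, ja + flank - 1L)         # acceptor exon
      )
      minus <- junctions$strand[i] == "-"
      if (any(minus)) seq[minus] <- .revComp(seq[minus])
      out[i] <- seq
    }
  }
  names(out) <- if ("id" %in% names(junctions)) junctions$id else NULL
  attr(out, "flank") <- flank
  attr(out, "layout") <- windowLayout(flank, "junction")
  if (any(!is.na(note))) attr(out, "note") <- note
  out
}

#' Split a junction sequence into donor- and acceptor-site windows
#'
#' Partitions each `4*flank`-wide junction sequence into its first
#' `2*flank` characters (the donor-site window) and its last `2*flank`
#' characters (the acceptor-site window); their concatenation is the input.
#'
#' @param seqs Character vector (or DNAStringSet) of junction-mode
#'   sequences, width divisible by 4.
#' @param flank Sub-window length; defaults to the `flank` attribute if
#'   present, else `width/4`.
#' @return A list with character vectors `donor` and `acceptor`, each of
#'   width `2*flank`, carrying their own `layout` attributes.
#' @export
splitJunctionIntoSites <- function(seqs, flank = NULL) {
  a <- attr(seqs, "flank")
  s <- .asSequenceCharacter(seqs)
  w <- unique(nchar(s))
  if (length(w) != 1L) stop("sequences must share one width")
  if (is.null(flank)) flank <- if (!is.null(a)) a else w %/% 4L
  flank <- as.integer(flank)
  if (w != 4L * flank) {
    stop("invalid-mode: expected a 4-window junction sequence of width ",
         4L * flank, ", got width ", w)
  }
  donor <- substring(s, 1L, 2L * flank)
  acceptor <- substring(s, 2L * flank + 1L, 4L * flank)
  names(donor) <- names(acceptor) <- names(seqs)
  attr(donor, "flank") <- attr(acceptor, "flank") <- flank
  attr(donor, "layout") <- windowLayout(flank, "donor_site")
  attr(acceptor, "layout") <- windowLayout(flank, "acceptor_site")
  list(donor = donor, acceptor = acceptor)
}
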