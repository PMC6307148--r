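# Junction coordinate tables.
#
# A junction table is a data.frame with columns:
#   chrom    chromosome name
#   donor    1-based position of the LAST exonic base of the upstream exon
#   acceptor 1-based position of the FIRST exonic base of the downstream exon
#   strand   "+" or "-" (coordinates are always genomic: donor < acceptor)
#   reads    optional nonnegative read support
#   samples  optional nonnegative sample reoccurrence
# The intron occupies [donor + 1, acceptor - 1] and must be nonempty.

#' Construct and validate a junction table
#'
#' @param chrom Character vector of chromosome names.
#' @param donor,acceptor Integer vectors, 1-based inclusive coordinates of
#'   the last exonic base before the intron and the first exonic base after
#'   it. `acceptor > donor + 1` is required (nonempty intron).
#' @param strand `"+"` or `"-"`.
#' @param reads,samples Optional nonnegative integer support columns.
#' @param id Optional junction identifiers (default `j1, j2, ...`).
#' @return A validated `data.frame` junction table.
#' @export
#' @examples
#' junctionTable("chr1", 100, 200, "+")
junctionTable <- function(chrom, donor, acceptor, strand = "+",
                          reads = NULL, samples = NULL, id = NULL) {
  n <- max(length(chrom), length(donor), length(acceptor))
  df <- data.frame(
    id = if (is.null(id)) paste0("j", seq_len(n)) else as.character(id),
    chrom = as.character(rep_len(chrom, n)),
    donor = as.integer(rep_len(donor, n)),
    acceptor = as.integer(rep_len(acceptor, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  if (!is.null(reads)) df$reads <- as.integer(rep_len(reads, n))
  if (!is.null(samples)) df$samples <- as.integer(rep_len(samples, n))
  validateJunctions(df)
}

#' Validate a junction table
#'
#' Checks the column contract and the coordinate invariants: strand in
#' `{+,-}`, `acceptor > donor + 1` (the intron is nonempty), nonnegative
#' support counts.
#'
#' @param junctions A data.frame with at least columns `chrom`, `donor`,
#'   `acceptor`, `strand`.
#' @return The table, invisibly unchanged, or an error.
#' @export
validateJunctions <- function(junctions) {
  need <- c("chrom", "donor", "acceptor", "strand")
  miss <- setdiff(need, names(junctions))
  if (length(miss)) stop("junction table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(junctions$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  bad <- which(!(junctions$acceptor > junctions$donor + 1L))
  if (length(bad)) {
    stop("junction(s) ", paste(head(bad, 5L), collapse = ", "),
         ": acceptor must exceed donor + 1 (nonempty intron)")
  }
  for (col in c("reads", "samples")) {
    if (col %in% names(junctions) && any(junctions[[col]] < 0L, na.rm = TRUE)) {
      stop("negative values in column '", col, "'")
    }
  }
  junctions
}

#' Read a junction list from TSV
#'
#' Expects a header line with columns `chrom donor_pos acceptor_pos strand`
#' and optionally `reads` and `samples`. Coordinates are 1-based inclusive
#' by default (`donor_pos` = last exonic base, `acceptor_pos` = first exonic
#' base). With `dialect = "bed"` the two coordinate columns are interpreted
#' as a 0-based half-open intron interval `[start, end)`, i.e.
#' `donor = start` and `acceptor = end + 1` in 1-based terms.
#'
#' @param path TSV file path.
#' @param dialect `"onebased"` (default) or `"bed"`.
#' @return A validated junction table.
#' @export
readJunctions <- function(path, dialect = c("onebased", "bed")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, stringsAsFactors = FALSE)
  cn <- tolower(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      hit <- which(cn == cand)
      if (length(hit)) return(df[[hit[1L]]])
    }
    NULL
  }
  chrom <- pick("chrom", "chr", "chromosome")
  donor <- pick("donor_pos", "donor")
  acceptor <- pick("acceptor_pos", "acceptor")
  strand <- pick("strand")
  if (is.null(chrom) || is.null(donor) || is.null(acceptor)) {
    stop("TSV must have columns chrom, donor_pos, acceptor_pos (strand optional)")
  }
  donor <- as.integer(donor); acceptor <- as.integer(acceptor)
  if (dialect == "bed") {
    acceptor <- acceptor + 1L
  }
  junctionTable(chrom, donor, acceptor,
                strand = if (is.null(strand)) "+" else strand,
                reads = pick("reads", "read_support"),
                samples = pick("samples", "sample_count"),
                id = pick("id"))
}

#' Write a junction table as TSV
#'
#' Writes 1-based inclusive coordinates with the canonical header
#' understood by [readJunctions()]. Extra columns (e.g. `p_true`, `call`)
#' are preserved.
#'
#' @param junctions Junction table.
#' @param path Output path.
#' @param header Optional character vector of `# `-prefixed comment lines.
#' @export
writeJunctions <- function(junctions, path, header = NULL) {
  df <- junctions
  names(df)[names(df) == "donor"] <- "donor_pos"
  names(df)[names(df) == "acceptor"] <- "acceptor_pos"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import junctions from a BED12 file
#'
#' Each BED12 record's block structure defines one junction per adjacent
#' block pair: `donor` is the last base of block `k`, `acceptor` the first
#' base of block `k + 1`. Requires the rtracklayer package.
#'
#' @param path BED12 file path.
#' @return A junction table.
#' @export
readJunctionsBed12 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("readJunctionsBed12 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  if (is.null(blocks)) stop("BED file has no block structure (need BED12)")
  out <- list()
  for (i in seq_along(gr)) {
    bl <- blocks[[i]]
    if (length(bl) < 2L) next
    abs <- IRanges::shift(bl, BiocGenerics::start(gr[i]) - 1L)
    ends <- BiocGenerics::end(abs)[-length(abs)]
    starts <- BiocGenerics::start(abs)[-1L]
    out[[length(out) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      donor = ends, acceptor = starts,
      strand = as.character(BiocGenerics::strand(gr[i])),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop("no multi-block records in ", path)
  df <- do.call(rbind, out)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  junctionTable(df$chrom, df$donor, df$acceptor, df$strand)
}

#' Read a labeled FASTA sequence set
#'
#' Reads fixed-length windows whose description lines carry a binary label
#' as `label=1` or `label=0`. Supports center-anchored trimming of longer
#' windows (e.g. 140-nt windows trimmed to 60) with a configurable offset.
#'
#' @param path FASTA path.
#' @param trim Optional target width; sequences longer than `trim` are cut
#'   to `trim` consecutive bases.
#' @param offset Shift (in nt) of the trim window relative to the centered
#'   position; positive moves it rightward.
#' @return A list with `sequences` ([Biostrings::DNAStringSet]) and
#'   `labels` (integer 0/1, `NA` where no label tag is present).
#' @export
readLabeledFasta <- function(path, trim = NULL, offset = 0L) {
  ss <- Biostrings::readDNAStringSet(path)
  lab <- rep(NA_integer_, length(ss))
  m <- regmatches(names(ss), regexpr("label=[01]", names(ss)))
  has <- grepl("label=[01]", names(ss))
  lab[has] <- as.integer(sub("label=", "", m))
  if (!is.null(trim)) {
    w <- Biostrings::width(ss)
    if (any(w < trim)) stop("sequences shorter than trim width")
    start <- pmax(1L, (w - trim) %/% 2L + 1L + as.integer(offset))
    start <- pmin(start, w - trim + 1L)
    ss <- Biostrings::subseq(ss, start = start, width = trim)
  }
  list(sequences = ss, labels = lab)
}

#' Write a labeled FASTA sequence set
#'
#' @param sequences Character vector or DNAStringSet.
#' @param labels Integer 0/1 labels, encoded as `label=` tags in the
#'   description lines.
#' @param path Output path.
#' @param prefix Record name prefix.
#' @export
writeLabeledFasta <- function(sequences, labels, path, prefix = "seq") {
  seqs <- Biostrings::DNAStringSet(.asSequenceCharacter(sequences))
  stopifnot(length(labels) == length(seqs))
  names(seqs) <- sprintf("%s%d label=%d", prefix, seq_along(seqs),
                         as.integer(labels))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
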