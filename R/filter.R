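# Pre-filters for junction lists: repeat-artifact removal by anchor edit
# distance, and support-based retention.
#
# An alignment artifact arises when the exonic anchor on one side of a
# candidate junction also matches the sequence immediately inside the
# other side, so a spliced alignment is indistinguishable from a
# contiguous one. Two distances are computed per junction (donor anchor
# length A_d, acceptor anchor length A_a, genome G, donor position J_d,
# acceptor position J_a):
#   E_d = dist( G[J_d-A_d+1 .. J_d] , G[J_a-A_a .. J_a-1] )
#   E_a = dist( G[J_a .. J_a+A_a-1] , G[J_d+1 .. J_d+A_d] )
# and the junction is discarded iff min(E_d, E_a) <= maxDistance. The
# decision never reads read-support fields: the filter is independent of
# coverage by design.

#' Unit-cost edit (Levenshtein) distance
#'
#' Dynamic-programming edit distance with unit-cost substitutions,
#' insertions and deletions, vectorised over pairs. Symmetric; zero iff
#' the strings are equal; `N` mismatches every base except `N` itself.
#' Empty strings are allowed (distance = other's length).
#'
#' @param s,t Character vectors over `{A,C,G,T,N}` (recycled to a common
#'   length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' editDistance("GATTACA", "GACTACA")  # 1
editDistance <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(toupper(s), n); t <- rep_len(toupper(t), n)
  ws <- nchar(s); wt <- nchar(t)
  if (length(unique(ws)) == 1L && length(unique(wt)) == 1L && n > 1L) {
    return(.editDistanceBatch(s, t))
  }
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- .editDistance1(s[i], t[i])
  out
}

.editDistance1 <- function(s, t) {
  a <- strsplit(s, "", fixed = TRUE)[[1L]]
  b <- strsplit(t, "", fixed = TRUE)[[1L]]
  la <- length(a); lb <- length(b)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[lb + 1L]
}

# All s share one width and all t share one width: run the DP over every
# pair simultaneously (columns of the DP table vectorised across pairs).
.editDistanceBatch <- function(s, t) {
  n <- length(s)
  la <- nchar(s[1L]); lb <- nchar(t[1L])
  if (la == 0L) return(rep.int(lb, n))
  if (lb == 0L) return(rep.int(la, n))
  A <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
              n, la, byrow = TRUE)
  B <- matrix(unlist(strsplit(t, "", fixed = TRUE), use.names = FALSE),
              n, lb, byrow = TRUE)
  prev <- matrix(rep(0:lb, each = n), n, lb + 1L)
  for (i in seq_len(la)) {
    cur <- matrix(0L, n, lb + 1L)
    cur[, 1L] <- i
    ai <- A[, i]
    for (j in seq_len(lb)) {
      cur[, j + 1L] <- pmin(prev[, j + 1L] + 1L, cur[, j] + 1L,
                            prev[, j] + (ai != B[, j]))
    }
    prev <- cur
  }
  as.integer(prev[, lb + 1L])
}

#' Local-alignment similarity score (Smith-Waterman)
#'
#' Optional companion to [editDistance()]: the best local alignment score
#' between two anchor windows (match +1, mismatch -1, gap open/extend
#' -1), computed via [Biostrings::pairwiseAlignment()]. Exposed for users
#' who want a literal local-alignment similarity instead of the global
#' unit-cost distance the filter uses by default.
#'
#' @param s,t Character vectors (recycled).
#' @return Numeric vector of local alignment scores.
#' @export
localAlignmentScore <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(s, n); t <- rep_len(t, n)
  vapply(seq_len(n), function(i) {
    Biostrings::pairwiseAlignment(
      s[i], t[i], type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
  }, numeric(1L))
}

#' Anchor edit distances of candidate junctions
#'
#' Computes the two repeat-artifact distances `E_d` and `E_a` (see the
#' file header formulas) for every junction. On strand `-` the windows
#' are taken in transcript orientation, i.e. the donor anchor sits on the
#' genomic right side; distances are invariant to the common reverse
#' complement.
#'
#' @param genome Genome as in [assembleJunctionSequence()].
#' @param junctions Junction table.
#' @param anchorDonor,anchorAcceptor Anchor lengths `A_d`, `A_a` in nt
#'   (default 16 each).
#' @param onError `"stop"` or `"report"` (NA distances for junctions whose
#'   windows fall outside the chromosome).
#' @return The junction table with integer columns `E_d` and `E_a`.
#' @export
artifactDistances <- function(genome, junctions, anchorDonor = 16L,
                              anchorAcceptor = 16L,
                              onError = c("stop", "report")) {
  onError <- match.arg(onError)
  Ad <- as.integer(anchorDonor); Aa <- as.integer(anchorAcceptor)
  if (Ad < 1L || Aa < 1L) stop("anchor lengths must be >= 1")
  junctions <- validateJunctions(junctions)
  g <- .genomeAsCharacter(genome)
  n <- nrow(junctions)
  Ed <- rep(NA_integer_, n); Ea <- rep(NA_integer_, n)
  Amax <- max(Ad, Aa)
  for (ch in unique(junctions$chrom)) {
    sel <- which(junctions$chrom == ch)
    if (!ch %in% names(g)) {
      if (onError == "stop") stop("lookup error: chromosome '", ch,
                                  "' absent from genome")
      next
    }
    cs <- g[[ch]]; len <- nchar(cs)
    ok <- junctions$donor[sel] - Amax + 1L >= 1L &
      junctions$acceptor[sel] + Amax - 1L <= len
    if (any(!ok) && onError == "stop") {
      stop("boundary error: anchor windows outside chromosome '", ch, "'")
    }
    for (str in c("+", "-")) {
      i <- sel[ok & junctions$strand[sel] == str]
      if (!length(i)) next
      jd <- junctions$donor[i]; ja <- junctions$acceptor[i]
      if (str == "+") {
        # donor at the genomic left boundary
        Ed[i] <- editDistance(substring(cs, jd - Ad + 1L, jd),
                              substring(cs, ja - Aa, ja - 1L))
        Ea[i] <- editDistance(substring(cs, ja, ja + Aa - 1L),
                              substring(cs, jd + 1L, jd + Ad))
      } else {
        # donor at the genomic right boundary; both windows of each pair
        # share a reverse complement, which leaves the distance unchanged
        Ed[i] <- editDistance(substring(cs, ja, ja + Ad - 1L),
                              substring(cs, jd + 1L, jd + Aa))
        Ea[i] <- editDistance(substring(cs, jd - Aa + 1L, jd),
                              substring(cs, ja - Ad, ja - 1L))
      }
    }
  }
  junctions$E_d <- Ed
  junctions$E_a <- Ea
  junctions
}

#' Filter repeat-artifact junctions
#'
#' Drops every junction whose minimum anchor edit distance
#' `min(E_d, E_a)` is at or below `maxDistance`; all dropped records carry
#' their distances and a reason. The decision is purely sequence-based
#' and never reads the support columns. Junctions whose windows cannot be
#' extracted are retained with NA distances and a note (reported, not
#' fatal). `maxDistance = -1` disables the filter (identity).
#'
#' Optionally (`alternativeSites = TRUE`) a group-wise pass compares
#' junctions sharing a donor (resp. acceptor) at their variable ends with
#' the same distance rule, keeping the first junction of each similarity
#' group in input order.
#'
#' @param genome Genome as in [assembleJunctionSequence()].
#' @param junctions Junction table.
#' @param anchorDonor,anchorAcceptor Anchor lengths (default 16).
#' @param maxDistance Drop threshold (default 3, about 80 percent anchor
#'   identity at length 16); `-1` disables.
#' @param alternativeSites Enable the optional alternative-site pass
#'   (default off).
#' @return A list with `kept` and `dropped` junction tables (the union is
#'   the input, the intersection empty); `dropped` has columns `E_d`,
#'   `E_a` and `reason`.
#' @export
filterRepetitive <- function(genome, junctions, anchorDonor = 16L,
                             anchorAcceptor = 16L, maxDistance = 3L,
                             alternativeSites = FALSE) {
  junctions <- validateJunctions(junctions)
  if (maxDistance < 0) {
    return(list(kept = junctions,
                dropped = junctions[0L, , drop = FALSE]))
  }
  withD <- artifactDistances(genome, junctions, anchorDonor, anchorAcceptor,
                             onError = "report")
  minD <- pmin(withD$E_d, withD$E_a)
  drop <- !is.na(minD) & minD <= maxDistance
  reason <- rep(NA_character_, nrow(withD))
  reason[drop] <- sprintf("repeat artifact: min(E_d=%d, E_a=%d) <= %d",
                          withD$E_d[drop], withD$E_a[drop],
                          as.integer(maxDistance))
  if (alternativeSites && any(!drop)) {
    for (side in c("donor", "acceptor")) {
      keyCols <- c("chrom", side, "strand")
      key <- do.call(paste, c(withD[keyCols], sep = "\r"))
      varPos <- if (side == "donor") withD$acceptor else withD$donor
      A <- if (side == "donor") anchorAcceptor else anchorDonor
      g <- .genomeAsCharacter(genome)
      for (k in unique(key[duplicated(key)])) {
        grp <- which(key == k & !drop)
        if (length(grp) < 2L) next
        cs <- g[[withD$chrom[grp[1L]]]]
        win <- if (side == "donor") {
          substring(cs, varPos[grp] - A, varPos[grp] - 1L)
        } else {
          substring(cs, varPos[grp] + 1L, varPos[grp] + A)
        }
        for (u in seq_along(grp)[-1L]) {
          d <- editDistance(win[seq_len(u - 1L)], rep(win[u], u - 1L))
          if (any(d <= maxDistance)) {
            drop[grp[u]] <- TRUE
            reason[grp[u]] <- sprintf(
              "alternative %s site within distance %d of an earlier junction",
              if (side == "donor") "acceptor" else "donor",
              as.integer(maxDistance))
          }
        }
      }
    }
  }
  dropped <- withD[drop, , drop = FALSE]
  dropped$reason <- reason[drop]
  kept <- withD[!drop, , drop = FALSE]
  list(kept = kept, dropped = dropped)
}

#' Retain junctions by sample reoccurrence
#'
#' Keeps junctions observed in at least `minSamples` independent samples
#' (default 2, i.e. supported by more than one sample).
#'
#' @param junctions Junction table with a `samples` column (required
#'   unless `minSamples = 1`).
#' @param minSamples Minimum sample reoccurrence (default 2).
#' @return The kept junction table.
#' @export
filterBySupport <- function(junctions, minSamples = 2L) {
  if (minSamples < 1L) stop("minSamples must be >= 1")
  if (!"samples" %in% names(junctions)) {
    if (minSamples == 1L) return(junctions)
    stop("junction table has no 'samples' column")
  }
  junctions[junctions$samples >= minSamples, , drop = FALSE]
}
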