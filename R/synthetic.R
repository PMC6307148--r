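# Synthetic genomes, junction sets and labeled benchmarks with known
# ground truth.
#
# The generator plants three junction classes on an i.i.d. uniform
# background genome:
#   true     - PWM-sampled donor + acceptor motifs joined across an
#              intron, with the canonical GT / AG fixed;
#   decoy    - junctions anchored at GT..AG dinucleotide pairs that occur
#              by chance in the background, so decoys carry the consensus
#              but no motif structure;
#   artifact - false junctions created by copying the donor exonic anchor
#              (with a few substitutions) into the window just before the
#              acceptor, emulating spliced-alignment artifacts of
#              repetitive sequence.
# Per-junction donor/acceptor motif strength varies through a Gaussian
# copula whose correlation is configurable, so "site-pair" and "junction"
# classification modes can be contrasted. All generation is a pure
# function of (config, seed).

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- vapply(.BASES, function(b) charToRaw(b), raw(1L))

#' Default full-strength donor / acceptor position-probability matrices
#'
#' Synthetic motifs following the canonical mammalian consensus footprint:
#' the donor 9-mer spans 3 exonic + 6 intronic positions with consensus
#' `CAG|GTAAGT` (GT fixed); the acceptor 15-mer spans 14 intronic + 1
#' exonic position with a polypyrimidine tract and `...CAG|G` (AG fixed).
#' Columns are the full-strength (`motifStrength = 1`) distributions:
#' consensus-exact except the deliberately uninformative spacer column of
#' the acceptor, which stays uniform. [generatorConfig()] interpolates
#' every non-fixed column toward uniform as
#' `s * column + (1 - s) * 0.25`. These probabilities are package
#' constants, synthetic by design, not estimates from data.
#'
#' @return A 4 x width matrix (rows `A`, `C`, `G`, `T`; columns sum to 1)
#'   with attributes `consensus`, `fixed` (column indices whose
#'   distribution never interpolates) and `nExonic`/`nIntronic`.
#' @name default-pwms
NULL

.pwmFromConsensus <- function(consensus, fixed, uninformative = integer()) {
  L <- length(consensus)
  m <- matrix(0, 4L, L, dimnames = list(.BASES, NULL))
  m[cbind(match(consensus, .BASES), seq_len(L))] <- 1
  if (length(uninformative)) m[, uninformative] <- 0.25
  attr(m, "consensus") <- consensus
  attr(m, "fixed") <- as.integer(fixed)
  m
}

#' @rdname default-pwms
#' @export
defaultDonorPwm <- function() {
  m <- .pwmFromConsensus(strsplit("CAGGTAAGT", "")[[1L]], fixed = 4:5)
  attr(m, "nExonic") <- 3L; attr(m, "nIntronic") <- 6L
  m
}

#' @rdname default-pwms
#' @export
defaultAcceptorPwm <- function() {
  m <- .pwmFromConsensus(strsplit("TTTTTTTTTTNCAGG", "")[[1L]],
                         fixed = 13:14, uninformative = 11L)
  attr(m, "consensus")[11L] <- "N"
  attr(m, "nIntronic") <- 14L; attr(m, "nExonic") <- 1L
  m
}

#' Configuration of the synthetic junction generator
#'
#' @param nTrue,nFalse Number of true and false (decoy + artifact)
#'   junctions.
#' @param motifStrength Scalar in `[0, 1]` interpolating the full-strength
#'   PWM columns toward uniform (0 = no signal beyond the fixed GT/AG,
#'   1 = consensus-exact). Default 0.85.
#' @param repeatFraction Fraction of false junctions planted as repeat
#'   artifacts (default 0; the rest are GT..AG decoys).
#' @param siteCorrelation Correlation in `[0, 1]` of the per-junction
#'   donor and acceptor motif strengths of true junctions (default 0).
#' @param strengthRange Range of the per-junction strength multiplier the
#'   Gaussian copula maps into (default `c(0.6, 1)` of the nominal
#'   strength).
#' @param flank Sub-window length used downstream (default 30).
#' @param intronRange Intron length range in nt (default 70-140, long
#'   enough that the two intronic windows never collide).
#' @param anchorLength Anchor length copied for artifact junctions
#'   (default 16, matching the filter default).
#' @param repeatMutations Substitutions applied to the copied artifact
#'   anchor (default 1; the planted divergence).
#' @param donorPwm,acceptorPwm Full-strength PWMs (defaults
#'   [defaultDonorPwm()] / [defaultAcceptorPwm()]); custom matrices must
#'   have rows A,C,G,T, columns summing to 1, and `fixed`/`nExonic`
#'   attributes as produced by the defaults.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return A validated list of class `generatorConfig`.
#' @export
generatorConfig <- function(nTrue = 2000L, nFalse = 2000L,
                            motifStrength = 0.85, repeatFraction = 0,
                            siteCorrelation = 0,
                            strengthRange = c(0.6, 1),
                            flank = 30L, intronRange = c(70L, 140L),
                            anchorLength = 16L, repeatMutations = 1L,
                            donorPwm = defaultDonorPwm(),
                            acceptorPwm = defaultAcceptorPwm(),
                            seed = 1L) {
  cfg <- list(nTrue = as.integer(nTrue), nFalse = as.integer(nFalse),
              motifStrength = motifStrength,
              repeatFraction = repeatFraction,
              siteCorrelation = siteCorrelation,
              strengthRange = strengthRange,
              flank = as.integer(flank),
              intronRange = as.integer(intronRange),
              anchorLength = as.integer(anchorLength),
              repeatMutations = as.integer(repeatMutations),
              donorPwm = donorPwm, acceptorPwm = acceptorPwm,
              seed = as.integer(seed))
  stopifnot(cfg$nTrue >= 0L, cfg$nFalse >= 0L,
            motifStrength >= 0, motifStrength <= 1,
            repeatFraction >= 0, repeatFraction <= 1,
            siteCorrelation >= 0, siteCorrelation <= 1,
            length(strengthRange) == 2L, strengthRange[1L] <= strengthRange[2L],
            strengthRange[1L] >= 0, strengthRange[2L] <= 1,
            cfg$flank >= 2L, cfg$intronRange[1L] >= 2L * cfg$flank,
            cfg$anchorLength >= 3L)
  for (pwm in list(donorPwm, acceptorPwm)) {
    if (max(abs(colSums(pwm) - 1)) > 1e-9) stop("PWM columns must sum to 1")
    fx <- attr(pwm, "fixed")
    if (is.null(fx) || any(apply(pwm[, fx, drop = FALSE], 2L, max) < 1)) {
      stop("fixed consensus PWM columns must be degenerate (probability 1)")
    }
  }
  class(cfg) <- "generatorConfig"
  cfg
}

# Interpolated column distributions at effective strength s (non-fixed
# columns only): s * fullStrengthColumn + (1 - s) * uniform.
.pwmAtStrength <- function(pwm, s) {
  out <- pwm * s + (1 - s) * 0.25
  fx <- attr(pwm, "fixed")
  out[, fx] <- pwm[, fx]
  out
}

# Sample one motif instance per row of `strength`; returns an
# [n, L] integer matrix of base codes 1..4.
.sampleMotif <- function(pwm, strength) {
  n <- length(strength)
  L <- ncol(pwm)
  out <- matrix(0L, n, L)
  fx <- attr(pwm, "fixed")
  for (k in seq_len(L)) {
    fromPwm <- if (k %in% fx) rep(TRUE, n) else runif(n) < strength
    col <- sample.int(4L, n, replace = TRUE, prob = pwm[, k])
    unif <- sample.int(4L, n, replace = TRUE)
    out[, k] <- ifelse(fromPwm, col, unif)
  }
  out
}

# Per-junction (donor, acceptor) strength multipliers from a Gaussian
# copula with correlation rho, mapped into strengthRange.
.sampleStrengths <- function(n, cfg) {
  rho <- cfg$siteCorrelation
  zd <- rnorm(n)
  za <- rho * zd + sqrt(1 - rho^2) * rnorm(n)
  lo <- cfg$strengthRange[1L]; hi <- cfg$strengthRange[2L]
  list(donor = cfg$motifStrength * (lo + (hi - lo) * pnorm(zd)),
       acceptor = cfg$motifStrength * (lo + (hi - lo) * pnorm(za)))
}

#' Generate a synthetic genome with planted junctions
#'
#' Builds one chromosome (`chrS`) of i.i.d. uniform background hosting
#' `nTrue` motif-planted true junctions, decoy junctions anchored at
#' background GT..AG occurrences, and (if `repeatFraction > 0`)
#' repeat-artifact junctions. Support columns are simulated (true
#' junctions reoccur in more samples than false ones). Deterministic
#' under the config seed: equal configs give byte-identical genomes.
#'
#' @param cfg A [generatorConfig()].
#' @return A list with `genome` (named character, one chromosome),
#'   `junctions` (junction table with truth columns `class` in
#'   true/decoy/artifact and per-site strengths `sDonor`, `sAcceptor`)
#'   and `config`.
#' @export
generateGenome <- function(cfg = generatorConfig()) {
  stopifnot(inherits(cfg, "generatorConfig"))
  .withSeed(cfg$seed, .generateGenomeImpl(cfg))
}

.generateGenomeImpl <- function(cfg) {
  nArt <- as.integer(round(cfg$repeatFraction * cfg$nFalse))
  nDecoy <- cfg$nFalse - nArt
  classes <- c(rep("true", cfg$nTrue), rep("decoy", nDecoy),
               rep("artifact", nArt))
  nJ <- length(classes)
  pad <- max(cfg$flank, cfg$anchorLength) + 8L
  introns <- sample(cfg$intronRange[1L]:cfg$intronRange[2L], nJ,
                    replace = TRUE)
  # decoy loci get extra room for the GT / AG scan
  slack <- ifelse(classes == "decoy", 64L, 0L)
  lociLen <- 2L * pad + introns + slack
  offsets <- c(0L, cumsum(lociLen))[seq_len(nJ)]
  genomeLen <- sum(lociLen)
  g <- .BASE_RAW[sample.int(4L, genomeLen, replace = TRUE)]

  jd <- offsets + pad          # provisional: last exonic base of left exon
  ja <- jd + introns + 1L      # first exonic base of right exon

  isTrue <- classes == "true"
  strengths <- .sampleStrengths(sum(isTrue), cfg)
  sDonor <- sAcceptor <- rep(NA_real_, nJ)
  sDonor[isTrue] <- strengths$donor
  sAcceptor[isTrue] <- strengths$acceptor

  # --- true junctions: plant donor and acceptor motifs -------------------
  if (any(isTrue)) {
    dpwm <- cfg$donorPwm; apwm <- cfg$acceptorPwm
    dEx <- attr(dpwm, "nExonic")
    aIn <- attr(apwm, "nIntronic")
    dm <- .sampleMotif(dpwm, strengths$donor)
    am <- .sampleMotif(apwm, strengths$acceptor)
    ti <- which(isTrue)
    dStart <- jd[ti] - dEx + 1L
    aStart <- ja[ti] - aIn
    for (k in seq_len(ncol(dpwm))) g[dStart + k - 1L] <- .BASE_RAW[dm[, k]]
    for (k in seq_len(ncol(apwm))) g[aStart + k - 1L] <- .BASE_RAW[am[, k]]
  }

  # --- decoy junctions: anchor at background GT..AG pairs ----------------
  di <- which(classes == "decoy")
  for (i in di) {
    found <- FALSE
    for (try in 1:50) {
      locus <- rawToChar(g[(offsets[i] + 1L):(offsets[i] + lociLen[i])])
      gts <- gregexpr("GT", locus, fixed = TRUE)[[1L]]
      ags <- gregexpr("AG", locus, fixed = TRUE)[[1L]]
      ok <- FALSE
      if (gts[1L] != -1L && ags[1L] != -1L) {
        gts <- gts[gts >= pad + 1L & gts <= pad + 1L + slack[i]]
        for (p in gts) {
          # GT starts the intron at local donor p - 1
          lo <- p - 1L + cfg$intronRange[1L] - 1L
          hi <- p - 1L + cfg$intronRange[2L] - 1L
          cand <- ags[ags >= lo & ags <= hi &
                        ags + 2L + pad <= lociLen[i]]
          if (length(cand)) {
            q <- cand[1L]
            jd[i] <- offsets[i] + p - 1L
            ja[i] <- offsets[i] + q + 2L
            ok <- TRUE
            break
          }
        }
      }
      if (ok) { found <- TRUE; break }
      # resample this locus and scan again
      g[(offsets[i] + 1L):(offsets[i] + lociLen[i])] <-
        .BASE_RAW[sample.int(4L, lociLen[i], replace = TRUE)]
    }
    if (!found) stop("infeasible decoy placement after bounded retries")
  }

  # --- artifact junctions: copy the donor anchor across the intron -------
  ai <- which(classes == "artifact")
  if (length(ai)) {
    A <- cfg$anchorLength
    for (i in ai) {
      # canonical dinucleotides, with the exonic anchor ending in AG so
      # the copied anchor supplies the acceptor's AG
      g[(jd[i] - 1L):jd[i]] <- .BASE_RAW[c(1L, 3L)]        # ..AG]
      g[(jd[i] + 1L):(jd[i] + 2L)] <- .BASE_RAW[c(3L, 4L)] # [GT..
      anchor <- g[(jd[i] - A + 1L):jd[i]]
      if (cfg$repeatMutations > 0L) {
        pos <- sample.int(A - 2L, min(cfg$repeatMutations, A - 2L))
        for (p in pos) {
          cur <- which(.BASE_RAW == anchor[p])
          anchor[p] <- .BASE_RAW[sample(setdiff(1:4, cur), 1L)]
        }
      }
      g[(ja[i] - A):(ja[i] - 1L)] <- anchor
    }
  }

  # simulated support evidence: true junctions reoccur in more samples
  reads <- integer(nJ); samples <- integer(nJ)
  reads[isTrue] <- 1L + stats::rnbinom(sum(isTrue), mu = 30, size = 1.2)
  samples[isTrue] <- 1L + stats::rpois(sum(isTrue), 4)
  reads[!isTrue] <- 1L + stats::rnbinom(sum(!isTrue), mu = 2, size = 0.8)
  samples[!isTrue] <- 1L + stats::rpois(sum(!isTrue), 0.3)

  junctions <- junctionTable(chrom = "chrS", donor = jd, acceptor = ja,
                             strand = "+", reads = reads, samples = samples)
  junctions$class <- classes
  junctions$sDonor <- sDonor
  junctions$sAcceptor <- sAcceptor
  list(genome = c(chrS = rawToChar(g)), junctions = junctions, config = cfg)
}

#' Write a simulation to disk
#'
#' Writes `genome.fa`, `junctions.tsv` (coordinates + support) and
#' `truth.tsv` (with the class and strength columns) into a directory.
#'
#' @param sim Result of [generateGenome()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
  pub <- sim$junctions[, c("id", "chrom", "donor", "acceptor", "strand",
                           "reads", "samples")]
  writeJunctions(pub, file.path(dir, "junctions.tsv"))
  writeJunctions(sim$junctions, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Build labeled train/valid/test benchmarks from the generator
#'
#' Generates a genome, assembles the junction-mode (`4*flank` nt) and
#' site-mode (`2*flank` nt) sequence views of every true and decoy
#' junction, and splits them into disjoint train/valid/test sets,
#' stratified by class. Artifact junctions (if any) are excluded from the
#' classification benchmark - they are the filter module's ground truth.
#' Supports imbalanced designs: with `ratio = 10`, all `nTrue` positives
#' are kept and `10 * nTrue` decoys are selected (the config must provide
#' at least that many).
#'
#' @param cfg A [generatorConfig()].
#' @param ratio Negatives selected per positive (default 1).
#' @param split Named fractions for train/valid/test (default
#'   0.5/0.25/0.25).
#' @return A list with elements `train`, `valid`, `test` - each a list of
#'   `sequences` (junction mode), `donor`, `acceptor` (site views),
#'   `labels` (1 = true) and `junctions` (the truth rows) - plus `sim`
#'   (the full simulation) and `layout`.
#' @export
makeBenchmark <- function(cfg = generatorConfig(), ratio = 1,
                          split = c(train = 0.5, valid = 0.25, test = 0.25)) {
  stopifnot(inherits(cfg, "generatorConfig"))
  nNeg <- as.integer(round(ratio * cfg$nTrue))
  sim <- generateGenome(cfg)
  j <- sim$junctions
  pos <- which(j$class == "true")
  neg <- which(j$class == "decoy")
  if (length(neg) < nNeg) {
    stop("ratio infeasible: need ", nNeg, " decoys but the config provides ",
         length(neg))
  }
  neg <- .withSeed(cfg$seed + 7L, sample(neg, nNeg))
  seqs <- assembleJunctionSequence(sim$genome, j, flank = cfg$flank)
  assign1 <- function(idx) {
    shuffled <- sample(idx)
    cut <- cumsum(round(split * length(idx)))
    cut[length(cut)] <- length(idx)
    grp <- rep(names(split), times = diff(c(0L, cut)))
    split(shuffled, factor(grp, levels = names(split)))
  }
  parts <- .withSeed(cfg$seed + 11L, {
    p <- assign1(pos); n <- assign1(neg)
    lapply(setNames(names(split), names(split)),
           function(s) c(p[[s]], n[[s]]))
  })
  out <- lapply(parts, function(idx) {
    sq <- seqs[idx]
    attr(sq, "flank") <- cfg$flank
    sites <- splitJunctionIntoSites(sq, flank = cfg$flank)
    list(sequences = sq, donor = sites$donor, acceptor = sites$acceptor,
         labels = as.integer(j$class[idx] == "true"),
         junctions = j[idx, , drop = FALSE])
  })
  c(out, list(sim = sim, layout = windowLayout(cfg$flank, "junction")))
}

#' Exact Bayes log-odds score under the generative model
#'
#' The log-likelihood ratio of the "true junction" model against the
#' "decoy" model for junction-mode sequences from [makeBenchmark()]. The
#' per-junction latent strengths are integrated out by equal-probability
#' Gaussian quadrature over the copula, so the score is the Bayes-optimal
#' reference classifier for the generator (up to quadrature resolution).
#' Fixed GT/AG columns cancel between the models; at
#' `motifStrength = 0` the score is identically 0.
#'
#' @param seqs Junction-mode sequences (character or DNAStringSet) of
#'   width `4*flank`.
#' @param cfg The [generatorConfig()] that produced them.
#' @param gridSize Quadrature nodes per latent dimension (default 16).
#' @return Numeric vector of log-odds scores.
#' @export
pwmBayesScore <- function(seqs, cfg, gridSize = 16L) {
  stopifnot(inherits(cfg, "generatorConfig"))
  s <- .asSequenceCharacter(seqs)
  w <- unique(nchar(s))
  f <- cfg$flank
  if (length(w) != 1L || w != 4L * f) {
    stop("layout mismatch: expected junction-mode width ", 4L * f)
  }
  dpwm <- cfg$donorPwm; apwm <- cfg$acceptorPwm
  dEx <- attr(dpwm, "nExonic"); aIn <- attr(apwm, "nIntronic")
  # motif columns inside the emitted sequence (donor boundary at f|f+1,
  # acceptor boundary at 3f|3f+1)
  dPos <- (f - dEx + 1L):(f - dEx + ncol(dpwm))
  aPos <- (3L * f - aIn + 1L):(3L * f - aIn + ncol(apwm))
  n <- length(s)
  chars <- matrix(unlist(strsplit(toupper(s), "", fixed = TRUE),
                         use.names = FALSE), n, w, byrow = TRUE)
  codeD <- matrix(match(chars[, dPos], .BASES), n, length(dPos))
  codeA <- matrix(match(chars[, aPos], .BASES), n, length(aPos))
  if (anyNA(codeD) || anyNA(codeA)) {
    stop("sequences must be over {A,C,G,T} in the motif windows")
  }
  m <- as.integer(gridSize)
  zs <- qnorm((seq_len(m) - 0.5) / m)
  lo <- cfg$strengthRange[1L]; hi <- cfg$strengthRange[2L]
  sOf <- function(z) cfg$motifStrength * (lo + (hi - lo) * pnorm(z))
  logLik <- function(code, pwm, sEff) {
    # [n] log-likelihood of the motif columns at effective strength sEff
    P <- .pwmAtStrength(pwm, sEff)
    P <- pmax(P, 1e-12)
    lp <- log(P)
    ll <- numeric(nrow(code))
    for (k in seq_len(ncol(code))) ll <- ll + lp[cbind(code[, k], k)]
    ll
  }
  # donor log-lik at each node, acceptor at each node
  llD <- vapply(zs, function(z) logLik(codeD, dpwm, sOf(z)), numeric(n))
  rho <- cfg$siteCorrelation
  if (rho == 0) {
    lTrue <- .logMeanExp(llD) + .logMeanExp(
      vapply(zs, function(z) logLik(codeA, apwm, sOf(z)), numeric(n)))
  } else {
    # z_a = rho z_d + sqrt(1-rho^2) e over an m x m equal-probability grid
    acc <- matrix(-Inf, n, m * m)
    col <- 0L
    for (gi in seq_len(m)) {
      for (hi_ in seq_len(m)) {
        col <- col + 1L
        za <- rho * zs[gi] + sqrt(1 - rho^2) * zs[hi_]
        acc[, col] <- llD[, gi] + logLik(codeA, apwm, sOf(za))
      }
    }
    lTrue <- .logMeanExp(acc)
  }
  lNull <- logLik(codeD, dpwm, 0) + logLik(codeA, apwm, 0)
  lTrue - lNull
}

# Row-wise log(mean(exp(x))) for a matrix of log-likelihood columns.
.logMeanExp <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  mx <- apply(x, 1L, max)
  mx + log(rowMeans(exp(x - mx)))
}
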