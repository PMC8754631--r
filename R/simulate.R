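# Seeded generators for every input class the pipeline consumes, each with
# a recorded SimulationTruth so downstream stages can be tested against
# known ground truth without external data.
#
# Run structure is controlled by a two-state hidden process: state W emits
# A/T, state S emits G/C. The chain's stationary weight on W is the target
# composition and `runIntensity` scales state persistence, so homopolymer
# run length can be varied at fixed composition. After emission an exact
# count correction (random state flips) pins the realized A+T fraction to
# within 0.5/length of the target.

#' Generate a random DNA sequence at a target composition
#'
#' Two-state emitter (W = A/T, S = G/C) with stationary W weight
#' `atTarget`; `runIntensity` multiplies the expected state run length at
#' fixed composition (1 = independent bases), and also sets the
#' within-state base persistence `runIntensity / (runIntensity + 1)`, so
#' larger values lengthen A and T homopolymer runs. Realized A+T is pinned
#' to `round(length * atTarget) / length` by an exact-count correction.
#'
#' @param length Sequence length in bp (>= 1).
#' @param atTarget Target A+T fraction in `[0, 1]`.
#' @param runIntensity Run-structure intensity (> 0; default 1). Values
#'   small enough to push a state-exit probability above 1 are rejected.
#' @param seed Integer seed.
#' @param id Identifier for the output sequence.
#' @return An [AnnotatedSequence-class].
#' @examples
#' atFraction(genSequence(1e4, 0.778, seed = 1))
#' @export
genSequence <- function(length, atTarget, runIntensity = 1, seed = NULL,
                        id = "sim") {
  L <- as.integer(length)
  if (is.na(L) || L < 1L) stop("length must be >= 1")
  if (atTarget < 0 || atTarget > 1) stop("atTarget must lie in [0, 1]")
  if (runIntensity <= 0) stop("runIntensity must be positive")
  pWS <- (1 - atTarget) / runIntensity
  pSW <- atTarget / runIntensity
  if (pWS > 1 || pSW > 1)
    stop("runIntensity too small for this composition: ",
         "state-exit probability exceeds 1")
  rho <- runIntensity / (runIntensity + 1)
  chars <- withSeed(seed, {
    states <- simStates(L, atTarget, pWS, pSW)
    # exact-count correction: pin the W count to round(L * atTarget)
    m <- round(L * atTarget)
    nW <- sum(states)
    if (nW > m) {
      flip <- which(states)[sample.int(nW, nW - m)]
      states[flip] <- FALSE
    } else if (nW < m) {
      flip <- which(!states)[sample.int(L - nW, m - nW)]
      states[flip] <- TRUE
    }
    out <- character(L)
    out[states] <- emitLetters(which(states), rho, c("A", "T"))
    out[!states] <- emitLetters(which(!states), 0.5, c("G", "C"))
    out
  })
  AnnotatedSequence(id = id, residues = paste(chars, collapse = ""))
}

# Simulate the W/S state sequence as interleaved geometric runs.
simStates <- function(L, atTarget, pWS, pSW) {
  if (atTarget >= 1) return(rep(TRUE, L))
  if (atTarget <= 0) return(rep(FALSE, L))
  firstW <- stats::runif(1) < atTarget
  nr <- max(16L, as.integer(ceiling(L * (pWS * atTarget +
                                         pSW * (1 - atTarget)))) + 16L)
  repeat {
    lw <- stats::rgeom(nr, pWS) + 1L
    ls <- stats::rgeom(nr, pSW) + 1L
    lens <- if (firstW) as.vector(rbind(lw, ls)) else
      as.vector(rbind(ls, lw))
    if (sum(lens) >= L) break
    nr <- nr * 2L
  }
  vals <- rep(c(firstW, !firstW), nr)
  rep(vals, lens)[seq_len(L)]
}

# Assign letters to the positions of one state class with persistence
# `rho`: within a contiguous stretch the base repeats with probability
# rho; stretches start with a uniform base.
emitLetters <- function(idx, rho, alphabet) {
  n <- length(idx)
  if (n == 0L) return(character(0))
  isStart <- c(TRUE, diff(idx) != 1L)
  pSwitch <- ifelse(isStart, 0.5, 1 - rho)
  sw <- stats::runif(n) < pSwitch
  alphabet[(cumsum(sw) %% 2L) + 1L]
}

#' Draw a pool of fixed-width segments at a target composition
#'
#' Cuts `n` adjacent segments from one generated sequence of length
#' `n * width`, so the POOL MEAN composition hits the target (exactly,
#' when `n * width * atTarget` is integral) while individual segments vary
#' stochastically around it — the behaviour needed when the per-segment
#' target (e.g. 0.94 on 20 bp) is not attainable exactly.
#'
#' @param n Number of segments.
#' @param width Segment width in bp.
#' @param atTarget Target mean A+T fraction.
#' @param runIntensity,seed Passed to [genSequence()].
#' @return Character vector of `n` segments.
#' @export
genSegmentPool <- function(n, width, atTarget, runIntensity = 1,
                           seed = NULL) {
  n <- as.integer(n); width <- as.integer(width)
  s <- as.character(genSequence(n * width, atTarget, runIntensity, seed))
  substring(s, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width)
}

#' Simulate a marker-discriminated ChIP experiment
#'
#' Draws reads from an experimental (marked) sequence and, with mixture
#' weight `1 - mixture`, from its native counterpart. Read starts on the
#' experimental sequence follow the fold-enrichment `layout` (start
#' density proportional to local fold; fold 1 outside all intervals);
#' native reads start uniformly. Sequencing errors are i.i.d.
#' substitutions at `errorRate`.
#'
#' @param expSeq Experimental (marked) [AnnotatedSequence-class].
#' @param nativeSeq Native counterpart (e.g. the unmodified sequence);
#'   may be `NULL` when `mixture = 1`.
#' @param layout Optional data.frame with columns `start`, `end` (1-based,
#'   closed, experimental coordinates) and `fold` (>= 0).
#' @param depth Mean per-base coverage of the experimental reference.
#' @param readLen Read length in bp (<= both reference lengths).
#' @param errorRate Per-base substitution error probability.
#' @param mixture Fraction of reads drawn from the experimental sequence.
#' @param seed Integer seed.
#' @return A list with `placements` (data.frame: `reference`, `start`,
#'   `end` 0-based half-open, `sequence`, `origin`) and `truth` (the
#'   simulation record, including realized per-origin read counts).
#' @export
genChipExperiment <- function(expSeq, nativeSeq = NULL, layout = NULL,
                              depth = 30, readLen = 100L, errorRate = 0,
                              mixture = 1, seed = NULL) {
  expSeq <- asAnnSeq(expSeq)
  if (!is.null(nativeSeq)) nativeSeq <- asAnnSeq(nativeSeq)
  readLen <- as.integer(readLen)
  L <- length(expSeq)
  if (readLen > L || (!is.null(nativeSeq) && readLen > length(nativeSeq)))
    stop("readLen exceeds a reference length")
  if (depth < 0 || readLen < 1L) stop("depth and readLen must be positive")
  if (mixture < 0 || mixture > 1) stop("mixture must lie in [0, 1]")
  if (mixture < 1 && is.null(nativeSeq))
    stop("nativeSeq required when mixture < 1")
  if (!is.null(layout)) {
    stopifnot(all(c("start", "end", "fold") %in% names(layout)))
    if (any(layout$fold < 0)) stop("folds must be >= 0")
  }
  nReads <- as.integer(round(depth * L / readLen))
  res <- withSeed(seed, {
    nExp <- stats::rbinom(1L, nReads, mixture)
    nNat <- nReads - nExp
    w <- rep(1, L - readLen + 1L)
    if (!is.null(layout)) {
      for (i in seq_len(nrow(layout))) {
        lo <- max(1L, as.integer(layout$start[i]))
        hi <- min(L - readLen + 1L, as.integer(layout$end[i]))
        if (lo <= hi) w[lo:hi] <- layout$fold[i]
      }
    }
    expStarts <- if (nExp > 0L)
      sample.int(L - readLen + 1L, nExp, replace = TRUE, prob = w)
    else integer(0)
    natStarts <- if (nNat > 0L)
      sample.int(length(nativeSeq) - readLen + 1L, nNat, replace = TRUE)
    else integer(0)
    expReads <- substring(as.character(expSeq), expStarts,
                          expStarts + readLen - 1L)
    natReads <- if (nNat > 0L)
      substring(as.character(nativeSeq), natStarts,
                natStarts + readLen - 1L)
    else character(0)
    reads <- addSeqErrors(c(expReads, natReads), errorRate)
    list(placements = data.frame(
           reference = c(rep(seqId(expSeq), nExp),
                         rep(if (is.null(nativeSeq)) NA_character_ else
                           seqId(nativeSeq), nNat)),
           start = c(expStarts, natStarts) - 1L,
           end = c(expStarts, natStarts) - 1L + readLen,
           sequence = reads,
           origin = rep(c("experimental", "native"), c(nExp, nNat)),
           stringsAsFactors = FALSE),
         nExp = nExp, nNat = nNat)
  })
  truth <- list(
    scenario = "chip_experiment",
    params = list(depth = depth, readLen = readLen, errorRate = errorRate,
                  mixture = mixture, seed = seed,
                  layout = layout,
                  expLength = L,
                  nativeLength = if (is.null(nativeSeq)) NULL else
                    length(nativeSeq)),
    realized = list(nReads = nReads, nExperimental = res$nExp,
                    nNative = res$nNat))
  list(placements = res$placements, truth = truth)
}

# i.i.d. substitution errors at `rate` applied to a character vector of
# equal-length reads.
addSeqErrors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  readLen <- nchar(reads[1L])
  nErr <- stats::rbinom(length(reads), readLen, rate)
  hit <- which(nErr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(readLen, nErr[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a species table under the scaling law
#'
#' Log10 genome sizes are uniform over `sizeRange`; relative centromeric
#' A+T follows `slope * log10(size) + intercept` plus Gaussian noise.
#' Genome A+T is a fixed baseline and centromere A+T is derived (clamped
#' to the representable 0-100 range; clamps are counted in the truth
#' record and are vanishingly rare under the defaults).
#'
#' Defaults emulate the published 43-species study conditions: slope
#' -7.831, genome sizes spanning yeast to mammal (1e7 to 3e9 bp), and
#' noise sized so the regression explains roughly 30% of the variance.
#'
#' @param n Number of species (>= 3).
#' @param slope,intercept True regression line (percentage points per
#'   log10 bp).
#' @param sigma Gaussian noise standard deviation (percentage points).
#' @param sizeRange Genome size range in bp.
#' @param genomeAT Baseline genome A+T percentage.
#' @param seed Integer seed.
#' @param clade Clade label for all simulated species.
#' @return A list with `records` (species data.frame) and `truth`.
#' @export
genSpeciesTable <- function(n = 43L, slope = -7.831, intercept = 74,
                            sigma = 8.5, sizeRange = c(1e7, 3e9),
                            genomeAT = 55, seed = NULL,
                            clade = "SimClade") {
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(sizeRange) != 2L || any(sizeRange <= 0) ||
      sizeRange[2L] <= sizeRange[1L])
    stop("degenerate size range")
  rec <- withSeed(seed, {
    lsz <- stats::runif(n, log10(sizeRange[1L]), log10(sizeRange[2L]))
    rel <- slope * lsz + intercept + stats::rnorm(n, 0, sigma)
    cent <- pmin(100, pmax(0, genomeAT + rel))
    data.frame(species = sprintf("sim_species_%03d", seq_len(n)),
               clade = clade,
               genome_size_bp = 10^lsz,
               genome_at_pct = genomeAT,
               centromere_at_pct = cent,
               stringsAsFactors = FALSE)
  })
  truth <- list(
    scenario = "species_table",
    params = list(n = n, slope = slope, intercept = intercept,
                  sigma = sigma, sizeRange = sizeRange,
                  genomeAT = genomeAT, seed = seed, clade = clade),
    realized = list(
      nClamped = sum(rec$centromere_at_pct %in% c(0, 100)),
      meanRelativeAT = mean(relativeAT(rec))))
  list(records = rec, truth = truth)
}

#' Simulate one replacement-assay outcome pair
#'
#' The control (empty-vector) arm reports its viable count at expectation;
#' the test (integrase) arm draws viable cells Poisson and the uracil
#' auxotroph and confirmed-swap counts Binomial, scaled so that the
#' expected [recoveryEfficiency()] equals `trueRecovery` exactly —
#' including truths above 1, which the assay can produce.
#'
#' @param trueRecovery True recovery proportion (>= 0; may exceed 1).
#' @param controlCells Viable cells in the control arm.
#' @param pUra,pSwap Per-cell detection fractions used to spread the truth
#'   across the measured fractions.
#' @param seed Integer seed.
#' @return A list with `test` and `control` ([AssayCounts-class]) and
#'   `truth`.
#' @export
genAssayOutcome <- function(trueRecovery, controlCells = 1e6,
                            pUra = 0.9, pSwap = 0.9, seed = NULL) {
  if (trueRecovery < 0) stop("trueRecovery must be >= 0")
  lambda <- controlCells * trueRecovery / (pUra * pSwap)
  counts <- withSeed(seed, {
    viable <- stats::rpois(1L, lambda)
    ura <- stats::rbinom(1L, viable, pUra)
    sw <- stats::rbinom(1L, ura, pSwap)
    c(viable = viable, ura = ura, sw = sw)
  })
  test <- assayCounts(
    "integrase", coloniesPooled = 50, viableCells = counts["viable"],
    fracUraMinus = if (counts["viable"] > 0)
      counts["ura"] / counts["viable"] else 0,
    fracSwapped = if (counts["ura"] > 0)
      counts["sw"] / counts["ura"] else 0)
  control <- assayCounts("empty_vector", coloniesPooled = 50,
                         viableCells = controlCells)
  truth <- list(
    scenario = "assay_outcome",
    params = list(trueRecovery = trueRecovery,
                  controlCells = controlCells, pUra = pUra,
                  pSwap = pSwap, seed = seed),
    realized = as.list(counts))
  list(test = test, control = control, truth = truth)
}

#' Regenerate a simulation from its truth record
#'
#' Every generator is a pure function of its parameter record; feeding the
#' `truth` element back through this function reproduces the original
#' output bit for bit. Sequence inputs of the ChIP generator are not part
#' of its parameter record and must be resupplied.
#'
#' @param truth A `truth` record from one of the generators.
#' @param ... Additional arguments (e.g. `expSeq`/`nativeSeq` for
#'   `chip_experiment`).
#' @return The regenerated object.
#' @export
regenerateFromTruth <- function(truth, ...) {
  p <- truth$params
  switch(truth$scenario,
    species_table = genSpeciesTable(
      n = p$n, slope = p$slope, intercept = p$intercept, sigma = p$sigma,
      sizeRange = p$sizeRange, genomeAT = p$genomeAT, seed = p$seed,
      clade = p$clade),
    assay_outcome = genAssayOutcome(
      trueRecovery = p$trueRecovery, controlCells = p$controlCells,
      pUra = p$pUra, pSwap = p$pSwap, seed = p$seed),
    chip_experiment = genChipExperiment(
      ..., layout = p$layout, depth = p$depth, readLen = p$readLen,
      errorRate = p$errorRate, mixture = p$mixture, seed = p$seed),
    stop("unknown scenario: ", truth$scenario))
}

#' Serialize a simulation truth record as JSON
#'
#' @param truth A truth record.
#' @param file Output path.
#' @export
writeTruthJSON <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
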