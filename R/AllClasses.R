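#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors Rle
NULL

#' AnnotatedSequence: a named DNA sequence with interval features
#'
#' The central sequence container of the package: an upper-case DNA string
#' over the alphabet A/C/G/T together with an identifier and an optional set
#' of interval features (design segments, concatemer units, marker loci).
#' Features are held as an [IRanges::IRanges] (1-based, closed) with a
#' `kind` metadata column.
#'
#' @slot id Single character identifier.
#' @slot seq A [Biostrings::DNAString].
#' @slot features An [IRanges::IRanges] with a `kind` metadata column; every
#'   range lies within `[1, length(seq)]`.
#'
#' @seealso [AnnotatedSequence()] for the validating constructor,
#'   [atFraction()], [windowedAT()], [findATRuns()].
#' @export
setClass("AnnotatedSequence",
  representation(id = "character", seq = "DNAString", features = "IRanges"))

setValidity("AnnotatedSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "'id' must be a single non-NA string")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  freq <- Biostrings::alphabetFrequency(object@seq)
  nonACGT <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
  if (nonACGT > 0)
    msg <- c(msg, sprintf("%d residue(s) outside A/C/G/T", nonACGT))
  fr <- object@features
  if (length(fr)) {
    if (is.null(S4Vectors::mcols(fr)$kind))
      msg <- c(msg, "features must carry a 'kind' metadata column")
    if (any(IRanges::start(fr) < 1L) || any(IRanges::end(fr) > length(object@seq)))
      msg <- c(msg, "features must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' CompositionProfile: windowed A+T fractions over a sequence
#'
#' Result of [windowedAT()]: one A+T fraction per tiled (or stepped) window.
#' Window starts are 1-based; a trailing partial window is never emitted.
#'
#' @slot window Window width in bp.
#' @slot step Step between successive window starts in bp.
#' @slot starts Integer vector of 1-based window start positions, strictly
#'   increasing by `step`.
#' @slot values Numeric vector of A+T fractions in `[0, 1]`, parallel to
#'   `starts`.
#' @export
setClass("CompositionProfile",
  representation(window = "integer", step = "integer",
                 starts = "integer", values = "numeric"))

setValidity("CompositionProfile", function(object) {
  msg <- character()
  if (length(object@starts) != length(object@values))
    msg <- c(msg, "'starts' and 'values' must have equal length")
  if (length(object@starts) > 1L &&
      !all(diff(object@starts) == object@step))
    msg <- c(msg, "'starts' must increase by exactly 'step'")
  if (length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 1))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CompetenceCall: centromere-competence classification
#'
#' Vectorised classification of (A+T fraction, length) pairs against the
#' activity thresholds observed in centromere-replacement assays. Labels are
#' ordered `inactive < unstable < active`, with `too_short` for sequences
#' below the minimum functional length.
#'
#' @slot label Character vector over
#'   `c("active", "unstable", "inactive", "too_short")`.
#' @slot atFraction Numeric vector of A+T fractions.
#' @slot lengthBp Integer vector of sequence lengths.
#' @seealso [classifyCompetence()]
#' @export
setClass("CompetenceCall",
  representation(label = "character", atFraction = "numeric",
                 lengthBp = "integer"))

setValidity("CompetenceCall", function(object) {
  ok <- object@label %in% c("active", "unstable", "inactive", "too_short")
  if (!all(ok)) return("invalid label(s)")
  if (length(object@label) != length(object@atFraction) ||
      length(object@label) != length(object@lengthBp))
    return("slots must have equal length")
  TRUE
})

#' MarkerSet: discriminating deletion markers on a sequence
#'
#' Records the 4 bp (by default) deletions introduced into an engineered
#' sequence to distinguish it from its near-identical native counterpart.
#' Positions refer to the UNMODIFIED sequence, 1-based; `removed` holds the
#' deleted strings so the deletion is exactly revertible.
#'
#' @slot starts Integer vector of 1-based deletion start positions in the
#'   unmodified sequence, sorted, non-overlapping.
#' @slot removed Character vector of deleted substrings, parallel to
#'   `starts`.
#' @seealso [introduceMarkers()], [revertMarkers()], [markerIndex()]
#' @export
setClass("MarkerSet",
  representation(starts = "integer", removed = "character"))

setValidity("MarkerSet", function(object) {
  if (length(object@starts) != length(object@removed))
    return("'starts' and 'removed' must have equal length")
  if (length(object@starts) > 1L) {
    ends <- object@starts + nchar(object@removed) - 1L
    if (is.unsorted(object@starts, strictly = TRUE))
      return("deletions must be sorted by position")
    if (any(object@starts[-1L] <= ends[-length(ends)]))
      return("deletions must not overlap")
  }
  TRUE
})

#' MarkerIndex: junction words for read discrimination
#'
#' For each deletion marker, the fixed-length word spanning the deletion
#' junction in the experimental (marked) sequence and the corresponding
#' undeleted word of the native sequence. Reads containing an experimental
#' junction word and no native word derive from the marked construct, and
#' conversely.
#'
#' @slot expWords Character vector of junction words present only in the
#'   experimental sequence (width `2 * flank`).
#' @slot natWords Character vector of the matched native words (width
#'   `deletion + 2 * flank`).
#' @slot flank Integer flank width either side of the deletion.
#' @slot starts Integer vector of marker start positions (unmodified
#'   coordinates), for reporting.
#' @seealso [markerIndex()], [assignReads()]
#' @export
setClass("MarkerIndex",
  representation(expWords = "character", natWords = "character",
                 flank = "integer", starts = "integer"))

setValidity("MarkerIndex", function(object) {
  if (length(object@expWords) != length(object@natWords))
    return("word vectors must be parallel")
  if (any(object@expWords == object@natWords))
    return("experimental and native words must differ for every marker")
  if (any(duplicated(c(object@expWords, object@natWords))))
    return("colliding junction words")
  TRUE
})

#' CoverageTrack: per-base depth over a named reference
#'
#' Per-base read depth over one reference interval, stored run-length
#' encoded, plus a normalization factor. A fresh track from [coverageTrack()]
#' has `normFactor = 1`; [normalizeToReference()] sets it to the mean read
#' count of the two reference centromeres.
#'
#' @slot reference Reference name.
#' @slot depth Integer [S4Vectors::Rle] of raw per-base depth.
#' @slot normFactor Positive scalar; normalized depth is `depth / normFactor`.
#' @export
setClass("CoverageTrack",
  representation(reference = "character", depth = "Rle",
                 normFactor = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@reference) != 1L)
    msg <- c(msg, "'reference' must be a single name")
  if (length(object@normFactor) != 1L || object@normFactor <= 0)
    msg <- c(msg, "'normFactor' must be a positive scalar")
  if (length(object@depth) && min(object@depth) < 0)
    msg <- c(msg, "depth must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AssayCounts: one arm of the centromere-replacement recovery assay
#'
#' Counts and fractions measured for one arm (integrase or empty vector) of
#' the replacement assay: pooled colonies, viable cells on rich medium, the
#' fraction of uracil auxotrophs among recovered cells, and the fraction of
#' auxotrophs confirmed swapped by PCR.
#'
#' @slot arm `"integrase"` or `"empty_vector"`.
#' @slot coloniesPooled Number of pooled colonies.
#' @slot viableCells Viable cell count.
#' @slot fracUraMinus Fraction of uracil-auxotrophic cells, in `[0, 1]`.
#' @slot fracSwapped Fraction of auxotrophs with a confirmed swap, in
#'   `[0, 1]`.
#' @seealso [assayCounts()], [recoveryEfficiency()]
#' @export
setClass("AssayCounts",
  representation(arm = "character", coloniesPooled = "numeric",
                 viableCells = "numeric", fracUraMinus = "numeric",
                 fracSwapped = "numeric"))

setValidity("AssayCounts", function(object) {
  msg <- character()
  if (!object@arm %in% c("integrase", "empty_vector"))
    msg <- c(msg, "'arm' must be 'integrase' or 'empty_vector'")
  if (object@coloniesPooled < 0 || object@viableCells < 0)
    msg <- c(msg, "counts must be non-negative")
  if (object@fracUraMinus < 0 || object@fracUraMinus > 1 ||
      object@fracSwapped < 0 || object@fracSwapped > 1)
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RateBound: zero-event upper confidence bound on a per-trial probability
#'
#' Records a zero-event experiment (no events in `trials` trials) and the
#' resulting upper confidence bound on the per-trial event probability:
#' `bound = 1 - (1 - confidence)^(1/trials)`. Trials may be non-integer when
#' they count informative lineage divisions.
#'
#' @slot trials Effective trial count (> 0, possibly non-integer).
#' @slot events Observed event count (0 in all supported uses).
#' @slot confidence Confidence level in (0, 1).
#' @slot bound Upper bound on the per-trial probability.
#' @seealso [zeroEventUpperBound()], [movementRateBound()]
#' @export
setClass("RateBound",
  representation(trials = "numeric", events = "integer",
                 confidence = "numeric", bound = "numeric"))

setValidity("RateBound", function(object) {
  msg <- character()
  if (object@trials <= 0) msg <- c(msg, "'trials' must be positive")
  if (object@confidence <= 0 || object@confidence >= 1)
    msg <- c(msg, "'confidence' must lie in (0, 1)")
  if (object@events == 0L) {
    expect <- 1 - (1 - object@confidence)^(1 / object@trials)
    if (abs(object@bound - expect) > 1e-12)
      msg <- c(msg, "bound inconsistent with zero-event closed form")
  }
  if (object@bound <= 0 || object@bound >= 1)
    msg <- c(msg, "bound must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' LineageModel: mutation-accumulation lineage accounting
#'
#' Describes a serial single-colony passaging experiment: `lines` independent
#' lineages, each re-streaked for `rounds` rounds, each round growing a
#' colony of `colonySize` cells. The informative divisions per line per
#' round are `log2(colonySize)` (the founding lineage of the picked colony).
#'
#' @slot colonySize Cells per colony (>= 2).
#' @slot rounds Number of streak rounds (>= 1).
#' @slot lines Number of independent lineages (>= 1).
#' @seealso [lineageModel()], [lineageDivisions()], [movementRateBound()]
#' @export
setClass("LineageModel",
  representation(colonySize = "numeric", rounds = "integer",
                 lines = "integer"))

setValidity("LineageModel", function(object) {
  msg <- character()
  if (object@colonySize < 2) msg <- c(msg, "'colonySize' must be >= 2")
  if (object@rounds < 1L || object@lines < 1L)
    msg <- c(msg, "'rounds' and 'lines' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ScalingFit: relative centromeric A+T vs log genome size regression
#'
#' Full ordinary-least-squares summary of the mutation-selection-balance
#' scaling regression: relative centromeric A+T (centromere minus genome,
#' percentage points) on the logarithm of genome size.
#'
#' @slot slope,intercept OLS coefficients.
#' @slot slopeSE Standard error of the slope.
#' @slot tStatistic,pValue Two-sided t test of the slope.
#' @slot rSquared,adjRSquared Coefficient of determination and its adjusted
#'   form.
#' @slot fStatistic F statistic on `df` degrees of freedom.
#' @slot df Integer pair `(1, n - 2)`.
#' @slot n Number of species.
#' @slot logBase Base of the genome-size logarithm used as predictor.
#' @seealso [fitScaling()], [cladeSubsetFit()]
#' @export
setClass("ScalingFit",
  representation(slope = "numeric", intercept = "numeric",
                 slopeSE = "numeric", tStatistic = "numeric",
                 pValue = "numeric", rSquared = "numeric",
                 adjRSquared = "numeric", fStatistic = "numeric",
                 df = "integer", n = "integer", logBase = "numeric"))

setValidity("ScalingFit", function(object) {
  msg <- character()
  if (!identical(object@df, c(1L, object@n - 2L)))
    msg <- c(msg, "df must equal (1, n - 2)")
  if (object@adjRSquared > object@rSquared + 1e-12)
    msg <- c(msg, "adjusted R-squared cannot exceed R-squared")
  if (is.finite(object@fStatistic) && is.finite(object@tStatistic) &&
      object@fStatistic > 0 &&
      abs(object@fStatistic - object@tStatistic^2) >
        1e-6 * max(1, abs(object@fStatistic)))
    msg <- c(msg, "F must equal t^2 for simple regression")
  if (length(msg)) msg else TRUE
})
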