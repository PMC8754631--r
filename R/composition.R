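#' A+T fraction of a DNA sequence
#'
#' `(A + T) / length` computed from integer base counts, so the value is
#' exact up to the final division. Accepts an [AnnotatedSequence-class], a
#' [Biostrings::DNAString] or a plain character string.
#'
#' @param x The sequence.
#' @param ... Unused.
#' @return A+T fraction in `[0, 1]`.
#' @examples
#' atFraction("AATT")  # 1
#' atFraction("ACGT")  # 0.5
#' @export
setMethod("atFraction", "AnnotatedSequence", function(x, ...) {
  freq <- Biostrings::alphabetFrequency(x@seq)
  sum(freq[c("A", "T")]) / length(x@seq)
})

#' @rdname atFraction
#' @export
setMethod("atFraction", "DNAString", function(x, ...) {
  atFraction(asAnnSeq(x))
})

#' @rdname atFraction
#' @export
setMethod("atFraction", "character", function(x, ...) {
  atFraction(asAnnSeq(x))
})

#' G+C fraction, the complement of [atFraction()]
#' @inheritParams atFraction
#' @export
gcFraction <- function(x) 1 - atFraction(asAnnSeq(x))

#' Windowed A+T composition profile
#'
#' A+T fraction in windows of `window` bp starting at positions
#' 1, 1 + step, 1 + 2 step, ...; a trailing window that would extend past
#' the sequence end is dropped, so every value is computed over exactly
#' `window` bases.
#'
#' @param x The sequence (see [atFraction()]).
#' @param window Window width in bp (`1 <= window <= length`).
#' @param step Step between window starts in bp (default: `window`, i.e.
#'   tiled, non-overlapping windows).
#' @return A [CompositionProfile-class].
#' @examples
#' windowedAT(strrep("ACGT", 50), window = 4, step = 4)
#' @export
windowedAT <- function(x, window, step = window) {
  x <- asAnnSeq(x)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || window > length(x))
    stop(sprintf("window (%d) must lie in [1, sequence length %d]",
                 window, length(x)))
  if (step < 1L) stop("step must be >= 1")
  starts <- seq.int(1L, length(x) - window + 1L, by = step)
  v <- Biostrings::Views(residues(x), start = starts, width = window)
  counts <- Biostrings::letterFrequency(v, letters = "AT")
  new("CompositionProfile", window = window, step = step,
      starts = as.integer(starts), values = as.numeric(counts) / window)
}

#' @rdname CompositionProfile-class
#' @param x A `CompositionProfile`.
#' @param row.names,optional,... Passed through per the generic.
#' @return `as.data.frame`: columns `start` (1-based), `end`, `at`.
#' @export
as.data.frame.CompositionProfile <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(start = x@starts, end = x@starts + x@window - 1L,
             at = x@values)
}

setMethod("as.data.frame", "CompositionProfile",
          as.data.frame.CompositionProfile)

#' @rdname CompositionProfile-class
#' @export
setMethod("length", "CompositionProfile", function(x) length(x@values))

#' @rdname CompositionProfile-class
#' @param object A `CompositionProfile`.
#' @export
setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf(
    "CompositionProfile: %d window(s) of %d bp (step %d); A+T %s\n",
    length(object@values), object@window, object@step,
    if (length(object@values))
      sprintf("range [%.3f, %.3f]", min(object@values), max(object@values))
    else "(empty)"))
})

#' @rdname CompositionProfile-class
#' @export
profileValues <- function(x) x@values

#' @rdname CompositionProfile-class
#' @export
profileStarts <- function(x) x@starts

#' Export a composition profile
#'
#' `writeProfileBedGraph` writes the profile as a bedGraph track (0-based,
#' half-open intervals) via [rtracklayer::export()]; `writeProfileTSV`
#' writes a plain 1-based TSV.
#'
#' @param profile A [CompositionProfile-class].
#' @param seqname Chromosome/sequence name for the track.
#' @param file Output path.
#' @export
writeProfileBedGraph <- function(profile, seqname, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = profile@starts,
                              width = profile@window),
    score = profile@values)
  rtracklayer::export(gr, con = file, format = "bedGraph")
  invisible(file)
}

#' @rdname writeProfileBedGraph
#' @export
writeProfileTSV <- function(profile, file) {
  utils::write.table(as.data.frame(profile), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Locate A/T homopolymer runs
#'
#' Maximal runs of a single base (`AAA...` or `TTT...`) of at least
#' `minLen` bp, in coordinate order. With `mixed = TRUE` the A and T
#' alphabet letters are pooled first, so maximal mixed A/T tracts are
#' reported instead (a sensitivity-analysis mode; the default follows the
#' per-base homopolymer reading of run structure).
#'
#' @param x The sequence (see [atFraction()]).
#' @param minLen Minimum run length to report (default 3, i.e. runs longer
#'   than 2 bp).
#' @param mixed Pool A and T into one alphabet class before run detection.
#' @return An [IRanges::IRanges] (1-based, closed) with metadata column
#'   `base` (`"A"`/`"T"`, or `"W"` for mixed tracts).
#' @examples
#' findATRuns("AAATCG", minLen = 3)
#' @export
findATRuns <- function(x, minLen = 3L, mixed = FALSE) {
  x <- asAnnSeq(x)
  minLen <- as.integer(minLen)
  if (minLen < 1L) stop("minLen must be >= 1")
  chars <- seqChars(x)
  if (mixed) chars <- ifelse(chars %in% c("A", "T"), "W", chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("A", "T", "W") & r$lengths >= minLen
  fr <- IRanges::IRanges(start = starts[keep], end = ends[keep])
  S4Vectors::mcols(fr) <- S4Vectors::DataFrame(base = r$values[keep])
  fr
}

#' Default centromere-competence thresholds
#'
#' Thresholds observed in the replacement assay: sequences of at least
#' 0.747 A+T formed centromeres indistinguishable from native ones, a 0.71
#' A+T sequence formed unstable centromeres, and lower compositions were
#' inactive; activity additionally required roughly 4.2 kb of sequence (a
#' 4.17 kb construct was stable, 3.59 kb was not), so the default length
#' floor is the 4 kb midpoint band.
#'
#' @param active Minimum A+T fraction for the `active` call.
#' @param unstable Minimum A+T fraction for the `unstable` call.
#' @param minLength Minimum length (bp) below which the call is
#'   `too_short`.
#' @return A named list usable as `thresholds` in [classifyCompetence()].
#' @export
competenceThresholds <- function(active = 0.747, unstable = 0.71,
                                 minLength = 4000L) {
  out <- list(active = active, unstable = unstable,
              minLength = as.integer(minLength))
  if (!(out$unstable < out$active))
    stop("malformed thresholds: require unstable < active")
  if (out$active > 1 || out$unstable < 0)
    stop("malformed thresholds: fractions must lie in [0, 1]")
  if (out$minLength < 1L) stop("malformed thresholds: minLength >= 1")
  out
}

#' Classify centromere competence from composition and length
#'
#' Pure function of (A+T fraction, length) given the thresholds: below the
#' length floor the call is `too_short`; otherwise `active` at or above the
#' activity threshold, `unstable` in the intermediate band, `inactive`
#' below it. Vectorised over `at` and `lengthBp`.
#'
#' @param at A+T fraction(s) in `[0, 1]`.
#' @param lengthBp Sequence length(s) in bp.
#' @param thresholds See [competenceThresholds()].
#' @return A [CompetenceCall-class].
#' @examples
#' classifyCompetence(0.778, 6100)
#' classifyCompetence(c(0.71, 0.63), c(5100, 5700))
#' @export
classifyCompetence <- function(at, lengthBp,
                               thresholds = competenceThresholds()) {
  if (!all(c("active", "unstable", "minLength") %in% names(thresholds)))
    stop("thresholds must name 'active', 'unstable' and 'minLength'")
  if (!(thresholds$unstable < thresholds$active))
    stop("malformed thresholds: require unstable < active")
  stopifnot(length(at) == length(lengthBp))
  if (any(at < 0 | at > 1)) stop("'at' must lie in [0, 1]")
  if (any(lengthBp < 1)) stop("'lengthBp' must be >= 1")
  label <- ifelse(lengthBp < thresholds$minLength, "too_short",
           ifelse(at >= thresholds$active, "active",
           ifelse(at >= thresholds$unstable, "unstable", "inactive")))
  new("CompetenceCall", label = label, atFraction = as.numeric(at),
      lengthBp = as.integer(lengthBp))
}

#' @rdname CompetenceCall-class
#' @export
competenceLabel <- function(x) x@label

#' @rdname CompetenceCall-class
#' @param object A `CompetenceCall`.
#' @export
setMethod("show", "CompetenceCall", function(object) {
  cat("CompetenceCall:\n")
  for (i in seq_along(object@label))
    cat(sprintf("  A+T %.3f, %d bp -> %s\n", object@atFraction[i],
                object@lengthBp[i], object@label[i]))
})
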