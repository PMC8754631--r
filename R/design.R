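# Construction and mutagenesis of candidate centromere sequences: tandem
# concatemers, interleaved composition designs, discriminating deletion
# markers, and the two run-targeted mutagenesis schemes.

#' Concatemerize a sequence unit
#'
#' Tandemly repeats `unit` `n` times (no linker bases between units; five
#' copies of an 889 bp unit give 4445 bp and seven give 6223 bp). Each
#' unit's interval is annotated as a `unit` feature.
#'
#' @param unit The repeat unit (see [atFraction()] for accepted types).
#' @param n Number of copies (>= 1).
#' @return An [AnnotatedSequence-class] of length `n * length(unit)`.
#' @examples
#' length(concatemerize(strrep("ACGTA", 10), 5))
#' @export
concatemerize <- function(unit, n) {
  unit <- asAnnSeq(unit)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  w <- length(unit)
  starts <- (seq_len(n) - 1L) * w + 1L
  AnnotatedSequence(
    id = sprintf("%s_x%d", seqId(unit), n),
    residues = strrep(as.character(unit), n),
    features = makeFeatures(starts, starts + w - 1L, rep("unit", n)))
}

#' Build an interleaved two-pool concatemer
#'
#' Emits alternating fixed-length segments A, B, A, B, ... drawn (uniformly,
#' with replacement, seeded) from two segment pools until the last whole
#' segment at or below `totalLength`; the output is truncated to whole
#' segments rather than padded, so the overall A+T fraction is exactly the
#' length-weighted mean of the chosen segments' fractions. This is the
#' design used to embed ~0.94 A+T budding-yeast CDEII-like segments in
#' ~0.55 A+T gene backbone segments.
#'
#' @param poolA,poolB Character vectors of segments, all of width
#'   `unitLength`.
#' @param unitLength Segment width in bp (default 20).
#' @param totalLength Target total length in bp (default 5900).
#' @param seed Integer seed for segment sampling.
#' @param id Identifier for the output sequence.
#' @return An [AnnotatedSequence-class] with `segment_a` / `segment_b`
#'   features.
#' @seealso [genSegmentPool()] to draw synthetic pools at a target
#'   composition.
#' @export
buildInterleaved <- function(poolA, poolB, unitLength = 20L,
                             totalLength = 5900L, seed = NULL,
                             id = "interleaved") {
  unitLength <- as.integer(unitLength)
  totalLength <- as.integer(totalLength)
  if (!length(poolA) || !length(poolB)) stop("segment pools must be non-empty")
  if (totalLength < unitLength) stop("totalLength must be >= unitLength")
  if (any(nchar(c(poolA, poolB)) != unitLength))
    stop(sprintf("all pool segments must be %d bp", unitLength))
  nSeg <- totalLength %/% unitLength
  isA <- seq_len(nSeg) %% 2L == 1L
  segs <- withSeed(seed, {
    out <- character(nSeg)
    out[isA] <- sample(poolA, sum(isA), replace = TRUE)
    out[!isA] <- sample(poolB, sum(!isA), replace = TRUE)
    out
  })
  starts <- (seq_len(nSeg) - 1L) * unitLength + 1L
  AnnotatedSequence(
    id = id,
    residues = paste(segs, collapse = ""),
    features = makeFeatures(starts, starts + unitLength - 1L,
                            ifelse(isA, "segment_a", "segment_b")))
}

#' Introduce discriminating deletion markers
#'
#' Marks a sequence the way engineered constructs were marked to tell them
#' apart from near-identical native DNA: one short deletion (default 4 bp)
#' per full `spacing` block (default 1 kb), placed uniformly within
#' `jitter` bp of the block centre. Deletions never fall within `delLen`
#' of the sequence ends and never overlap. The returned [MarkerSet-class]
#' records position and deleted string in unmodified coordinates, so
#' [revertMarkers()] reconstructs the input exactly.
#'
#' @param x The sequence to mark.
#' @param delLen Deletion length in bp (0 is a no-op).
#' @param spacing Block size in bp; one deletion per full block.
#' @param jitter Maximum displacement from the block centre (default
#'   `spacing / 4`). Must satisfy `spacing - 2 * jitter >= delLen`.
#' @param seed Integer seed for placement.
#' @return A list with elements `seq` (the marked [AnnotatedSequence-class],
#'   shorter than the input by `delLen` per deletion) and `markers` (a
#'   [MarkerSet-class]).
#' @export
introduceMarkers <- function(x, delLen = 4L, spacing = 1000L,
                             jitter = spacing %/% 4L, seed = NULL) {
  x <- asAnnSeq(x)
  delLen <- as.integer(delLen); spacing <- as.integer(spacing)
  jitter <- as.integer(jitter)
  L <- length(x)
  if (delLen == 0L) {
    return(list(seq = x,
                markers = new("MarkerSet", starts = integer(0),
                              removed = character(0))))
  }
  if (spacing <= delLen) stop("spacing must exceed delLen")
  if (L < spacing) stop("sequence shorter than one spacing block")
  if (spacing - 2L * jitter < delLen)
    stop(sprintf(
      "jitter %d too large: deletions of %d bp at spacing %d could overlap",
      jitter, delLen, spacing))
  nDel <- L %/% spacing
  starts <- withSeed(seed, {
    centres <- (seq_len(nDel) - 1L) * spacing + spacing %/% 2L
    offs <- if (jitter > 0L)
      sample(seq.int(-jitter, jitter), nDel, replace = TRUE)
    else rep(0L, nDel)
    s <- centres + offs - delLen %/% 2L
    pmin(pmax(s, delLen + 1L), L - 2L * delLen + 1L)
  })
  removed <- substring(as.character(x), starts, starts + delLen - 1L)
  markers <- new("MarkerSet", starts = as.integer(starts),
                 removed = removed)
  list(seq = applyMarkers(x, markers), markers = markers)
}

#' Apply or revert a marker set
#'
#' `applyMarkers` deletes the marked substrings from the unmodified
#' sequence; `revertMarkers` re-inserts them into a marked sequence,
#' reconstructing the original byte-for-byte.
#'
#' @param x An [AnnotatedSequence-class] (unmodified for `applyMarkers`,
#'   marked for `revertMarkers`).
#' @param markers A [MarkerSet-class].
#' @return An [AnnotatedSequence-class].
#' @export
applyMarkers <- function(x, markers) {
  x <- asAnnSeq(x)
  if (!length(markers@starts)) return(x)
  s <- as.character(residues(x))
  ends <- markers@starts + nchar(markers@removed) - 1L
  if (any(ends > nchar(s)))
    stop("marker positions extend beyond the sequence")
  if (!all(substring(s, markers@starts, ends) == markers@removed))
    stop("marker 'removed' strings do not match the sequence")
  keepStart <- c(1L, ends + 1L)
  keepEnd <- c(markers@starts - 1L, nchar(s))
  pieces <- substring(s, keepStart, keepEnd)
  AnnotatedSequence(id = paste0(seqId(x), "_marked"),
                    residues = paste(pieces, collapse = ""))
}

#' @rdname applyMarkers
#' @export
revertMarkers <- function(x, markers) {
  x <- asAnnSeq(x)
  s <- as.character(residues(x))
  if (!length(markers@starts)) return(x)
  lens <- nchar(markers@removed)
  # offsets of the deletions in MODIFIED coordinates
  offs <- markers@starts - c(0L, cumsum(lens))[seq_along(lens)] - 1L
  pieces <- character(2L * length(lens) + 1L)
  prev <- 0L
  for (i in seq_along(lens)) {
    pieces[2L * i - 1L] <- substr(s, prev + 1L, offs[i])
    pieces[2L * i] <- markers@removed[i]
    prev <- offs[i]
  }
  pieces[length(pieces)] <- substr(s, prev + 1L, nchar(s))
  AnnotatedSequence(id = sub("_marked$", "", seqId(x)),
                    residues = paste(pieces, collapse = ""))
}

#' @rdname MarkerSet-class
#' @param x A `MarkerSet`.
#' @export
markerStarts <- function(x) x@starts

#' @rdname MarkerSet-class
#' @export
markerRemoved <- function(x) x@removed

#' @rdname MarkerSet-class
#' @param object A `MarkerSet`.
#' @export
setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet: %d deletion(s), %d bp total\n",
              length(object@starts), sum(nchar(object@removed))))
})

#' @rdname MarkerSet-class
#' @export
setMethod("length", "MarkerSet", function(x) length(x@starts))

#' Marker set serialization
#'
#' TSV columns are `position` (0-based, in the unmodified sequence),
#' `length` and `removed`; the BED export writes 0-based half-open
#' intervals over the unmodified coordinate system.
#'
#' @param markers A [MarkerSet-class].
#' @param file Output (or input) path.
#' @export
writeMarkerTSV <- function(markers, file) {
  utils::write.table(
    data.frame(position = markers@starts - 1L,
               length = nchar(markers@removed),
               removed = markers@removed),
    file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMarkerTSV
#' @export
readMarkerTSV <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "length", "removed") %in% names(df)))
  if (!all(nchar(df$removed) == df$length))
    stop("'removed' strings inconsistent with 'length' column")
  new("MarkerSet", starts = as.integer(df$position) + 1L,
      removed = as.character(df$removed))
}

#' @rdname writeMarkerTSV
#' @param seqname Sequence name for the BED chrom column.
#' @export
writeMarkerBed <- function(markers, seqname, file) {
  utils::write.table(
    data.frame(chrom = seqname,
               start = markers@starts - 1L,
               end = markers@starts - 1L + nchar(markers@removed),
               name = sprintf("del%03d", seq_along(markers@starts))),
    file = file, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Disrupt A/T homopolymer runs with G/C substitutions
#'
#' Breaks every A or T homopolymer run longer than `maxRun` by substituting
#' a G or C (chosen at random, seeded) at every `(maxRun + 1)`-th position
#' of the run — the greedy left-to-right scheme, which uses the minimal
#' number of substitutions, `floor(runLength / (maxRun + 1))` per run.
#' Length is unchanged and A+T content can only decrease.
#'
#' @param x The sequence.
#' @param maxRun Longest run allowed to survive (default 2 bp).
#' @param seed Integer seed for the G-vs-C choice.
#' @return An [AnnotatedSequence-class] with no A/T homopolymer run longer
#'   than `maxRun`.
#' @examples
#' as.character(disruptRuns("AAAA", seed = 1))  # e.g. "AAGA" or "AACA"
#' @export
disruptRuns <- function(x, maxRun = 2L, seed = NULL) {
  x <- asAnnSeq(x)
  maxRun <- as.integer(maxRun)
  if (maxRun < 1L) stop("maxRun must be >= 1")
  runs <- findATRuns(x, minLen = maxRun + 1L)
  if (!length(runs)) return(x)
  pos <- unlist(lapply(seq_along(runs), function(i) {
    s <- IRanges::start(runs)[i]; k <- IRanges::width(runs)[i]
    s + maxRun + (seq_len(k %/% (maxRun + 1L)) - 1L) * (maxRun + 1L)
  }))
  chars <- seqChars(x)
  chars[pos] <- withSeed(seed,
    sample(c("G", "C"), length(pos), replace = TRUE))
  AnnotatedSequence(id = paste0(seqId(x), "_runfree"),
                    residues = paste(chars, collapse = ""),
                    features = seqFeatures(x))
}

#' Reduce A+T content while preserving homopolymer runs
#'
#' Lowers the overall A+T fraction to `targetAT` by substituting G or C
#' (seeded) for A/T residues lying OUTSIDE every homopolymer run longer
#' than `maxRun`; those runs are left byte-identical, so run structure at
#' `minLen = maxRun + 1` is exactly conserved. The realized fraction is
#' within `1/length` of the target.
#'
#' @param x The sequence.
#' @param targetAT Target A+T fraction; must be at most the current
#'   fraction and at least the fraction held inside preserved runs.
#' @param maxRun Runs longer than this are preserved (default 2 bp).
#' @param seed Integer seed for site and G-vs-C choice.
#' @return An [AnnotatedSequence-class].
#' @export
reduceATPreservingRuns <- function(x, targetAT, maxRun = 2L, seed = NULL) {
  x <- asAnnSeq(x)
  maxRun <- as.integer(maxRun)
  if (targetAT < 0 || targetAT > 1) stop("targetAT must lie in [0, 1]")
  L <- length(x)
  chars <- seqChars(x)
  runs <- findATRuns(x, minLen = maxRun + 1L)
  protected <- if (length(runs))
    unlist(Map(seq.int, IRanges::start(runs), IRanges::end(runs)))
  else integer(0)
  atPos <- which(chars %in% c("A", "T"))
  outside <- setdiff(atPos, protected)
  cur <- length(atPos)
  targetCount <- round(targetAT * L)
  d <- cur - targetCount
  if (d < 0L)
    stop(sprintf(
      "targetAT (%.4f) above current A+T (%.4f); only reductions possible",
      targetAT, cur / L))
  if (d > length(outside))
    stop(sprintf(
      "targetAT %.4f unachievable with runs preserved; minimum achievable A+T is %.4f",
      targetAT, (cur - length(outside)) / L))
  if (d > 0L) {
    subs <- withSeed(seed, {
      p <- outside[sample.int(length(outside), d)]
      list(pos = p, base = sample(c("G", "C"), d, replace = TRUE))
    })
    chars[subs$pos] <- subs$base
  }
  AnnotatedSequence(id = paste0(seqId(x), "_reduced"),
                    residues = paste(chars, collapse = ""),
                    features = seqFeatures(x))
}

#' Select A+T-rich windows from a genome
#'
#' Scans tiled, non-overlapping windows and returns those with A+T at or
#' above `minAT`, ranked by A+T descending — the in-silico analogue of
#' picking A+T-rich stretches of a bacterial genome as candidate
#' centromeres.
#'
#' @param genome The genome sequence.
#' @param window Window width in bp.
#' @param minAT Minimum A+T fraction to report.
#' @return A data.frame with columns `start`, `end` (1-based, closed) and
#'   `at`, ordered by `at` descending.
#' @export
selectATWindows <- function(genome, window, minAT) {
  prof <- windowedAT(genome, window = window, step = window)
  df <- as.data.frame(prof)
  df <- df[df$at >= minAT, , drop = FALSE]
  df <- df[order(-df$at, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
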