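# CENP-A ChIP enrichment quantitation: read placements, coverage tracks,
# normalization to the reference centromeres, marker-based read
# discrimination, and the composition-vs-binding segment regression.
#
# Placement tables use the simple TSV dialect (reference, start, end[,
# sequence]) with 0-based half-open coordinates, matching the bedGraph
# convention; conversion to 1-based IRanges happens internally.

#' Read placements from TSV or SAM
#'
#' `readPlacements` reads the canonical tabular placement dialect: tab
#' separated with header columns `reference`, `start`, `end` (0-based,
#' half-open) and optionally `sequence`. `readPlacementsSam` reads a text
#' SAM file (converted through [Rsamtools::asBam()]), keeping only primary
#' mapped records, and returns the same table.
#'
#' @param file Input path.
#' @return A data.frame with columns `reference`, `start`, `end` and, when
#'   available, `sequence`.
#' @export
readPlacements <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("reference", "start", "end")
  if (!all(need %in% names(df)))
    stop("placement TSV must have columns reference, start, end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validatePlacements(df)
  df
}

#' @rdname readPlacements
#' @export
readPlacementsSam <- function(file) {
  bam <- Rsamtools::asBam(file, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "seq")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  data.frame(
    reference = as.character(GenomicAlignments::seqnames(aln)),
    start = GenomicAlignments::start(aln) - 1L,
    end = GenomicAlignments::end(aln),
    sequence = as.character(S4Vectors::mcols(aln)$seq),
    stringsAsFactors = FALSE)
}

#' @rdname readPlacements
#' @param placements A placement data.frame.
#' @export
writePlacements <- function(placements, file) {
  utils::write.table(placements, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

validatePlacements <- function(placements, referenceLength = NULL) {
  bad <- which(placements$start < 0L | placements$end <= placements$start)
  if (!is.null(referenceLength))
    bad <- union(bad, which(placements$end > referenceLength))
  if (length(bad))
    stop(sprintf(
      "%d invalid placement(s) (rows %s): need 0 <= start < end%s",
      length(bad), paste(utils::head(bad, 5L), collapse = ", "),
      if (is.null(referenceLength)) ""
      else sprintf(" <= %d", referenceLength)))
  invisible(TRUE)
}

#' Build a per-base coverage track from read placements
#'
#' Depth at base `i` is the number of placements whose interval contains
#' `i`; the integral of the raw track equals the summed read lengths. The
#' fresh track has `normFactor = 1`.
#'
#' @param placements Placement data.frame (0-based half-open `start`/`end`;
#'   see [readPlacements()]). If a `reference` column is present, only rows
#'   matching `reference` are used.
#' @param referenceLength Length of the reference interval in bp.
#' @param reference Reference name (default: the single name present).
#' @return A [CoverageTrack-class].
#' @examples
#' coverageTrack(data.frame(reference = "r", start = 10, end = 20),
#'               referenceLength = 30)
#' @export
coverageTrack <- function(placements, referenceLength, reference = NULL) {
  referenceLength <- as.integer(referenceLength)
  if ("reference" %in% names(placements)) {
    if (is.null(reference)) {
      refs <- unique(placements$reference)
      if (length(refs) > 1L)
        stop("multiple references present; pass 'reference'")
      reference <- if (length(refs)) refs else "reference"
    } else {
      placements <- placements[placements$reference == reference, ,
                               drop = FALSE]
    }
  } else if (is.null(reference)) reference <- "reference"
  validatePlacements(placements, referenceLength)
  ir <- IRanges::IRanges(start = placements$start + 1L,
                         end = placements$end)
  new("CoverageTrack", reference = as.character(reference),
      depth = IRanges::coverage(ir, width = referenceLength),
      normFactor = 1)
}

#' @rdname CoverageTrack-class
#' @export
setMethod("depth", "CoverageTrack", function(x) x@depth)

#' @rdname CoverageTrack-class
#' @export
setMethod("normFactor", "CoverageTrack", function(x) x@normFactor)

#' @rdname CoverageTrack-class
#' @export
setMethod("normalizedDepth", "CoverageTrack",
          function(x) x@depth / x@normFactor)

#' @rdname CoverageTrack-class
#' @export
setMethod("length", "CoverageTrack", function(x) length(x@depth))

#' @rdname CoverageTrack-class
#' @param object A `CoverageTrack`.
#' @export
setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf(
    "CoverageTrack '%s': %d bp, mean raw depth %.2f, normFactor %.4g\n",
    object@reference, length(object@depth),
    mean(as.numeric(object@depth)), object@normFactor))
})

#' Normalize a track to the reference centromeres
#'
#' Sets the track's normalization factor to the average of the read counts
#' over the centromeres of chromosomes 1 and 3, the internal reference used
#' to put ChIP experiments on a common scale. Raw depth is retained;
#' [normalizedDepth()] divides by the factor, so re-scaling by
#' `normFactor` recovers the raw track exactly.
#'
#' @param track A [CoverageTrack-class].
#' @param countCen1,countCen3 Read counts over the two reference
#'   centromeres (both > 0).
#' @return The track with `normFactor = (countCen1 + countCen3) / 2`.
#' @export
normalizeToReference <- function(track, countCen1, countCen3) {
  if (countCen1 <= 0 || countCen3 <= 0)
    stop("reference read counts must be positive")
  track@normFactor <- (countCen1 + countCen3) / 2
  methods::validObject(track)
  track
}

#' Export a coverage track as bedGraph
#'
#' @param track A [CoverageTrack-class].
#' @param file Output path.
#' @param normalized Write normalized (default) or raw depth.
#' @export
writeTrackBedGraph <- function(track, file, normalized = TRUE) {
  val <- if (normalized) normalizedDepth(track) else
    methods::as(depth(track), "Rle")
  cov <- S4Vectors::runValue(val)
  lens <- S4Vectors::runLength(val)
  ends <- cumsum(lens)
  gr <- GenomicRanges::GRanges(
    seqnames = track@reference,
    ranges = IRanges::IRanges(start = ends - lens + 1L, end = ends),
    score = as.numeric(cov))
  rtracklayer::export(gr, con = file, format = "bedGraph")
  invisible(file)
}

#' Build a marker junction-word index
#'
#' For every deletion in `markers`, extracts the word spanning the deletion
#' junction in the experimental (marked) sequence (`2 * flank` bp) and the
#' matched undeleted word of the native sequence (`deletion + 2 * flank`
#' bp). Construction fails if any word collides: duplicate words, an
#' experimental word occurring in the native sequence, or a native word
#' occurring in the marked sequence would make read assignment ambiguous
#' by design.
#'
#' @param original The unmodified (native-identical) sequence the markers
#'   were introduced into.
#' @param markers The [MarkerSet-class] from [introduceMarkers()].
#' @param flank Flank width either side of the deletion (default 10 bp).
#' @return A [MarkerIndex-class].
#' @export
markerIndex <- function(original, markers, flank = 10L) {
  original <- asAnnSeq(original)
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be >= 1")
  if (!length(markers@starts)) stop("marker set is empty")
  s <- as.character(residues(original))
  lens <- nchar(markers@removed)
  ends <- markers@starts + lens - 1L
  if (any(markers@starts - flank < 1L) || any(ends + flank > nchar(s)))
    stop("flank extends beyond the sequence for at least one marker")
  natWords <- substring(s, markers@starts - flank, ends + flank)
  expWords <- paste0(substring(s, markers@starts - flank,
                               markers@starts - 1L),
                     substring(s, ends + 1L, ends + flank))
  marked <- as.character(residues(applyMarkers(original, markers)))
  collide <- vapply(expWords, function(w) grepl(w, s, fixed = TRUE),
                    logical(1)) |
    vapply(natWords, function(w) grepl(w, marked, fixed = TRUE),
           logical(1))
  if (any(collide))
    stop(sprintf("colliding junction word(s) for marker(s) %s",
                 paste(which(collide), collapse = ", ")))
  new("MarkerIndex", expWords = expWords, natWords = natWords,
      flank = flank, starts = markers@starts)
}

#' @rdname MarkerIndex-class
#' @param object A `MarkerIndex`.
#' @export
setMethod("show", "MarkerIndex", function(object) {
  cat(sprintf(
    "MarkerIndex: %d marker(s), flank %d bp (exp word %d bp, native %d bp)\n",
    length(object@expWords), object@flank, 2L * object@flank,
    unique(nchar(object@natWords))[1]))
})

#' Partition reads between experimental and native origin
#'
#' A read containing at least one experimental junction word and no native
#' word is called `experimental`; the converse is `native`; reads matching
#' neither (they lie wholly between markers, where the two variants are
#' identical) or both are `ambiguous`. The partition is exhaustive and
#' disjoint. Reads shorter than the experimental junction word can never
#' be assigned and are reported ambiguous with reason `too_short`.
#'
#' @param placements Placement data.frame with a `sequence` column.
#' @param index A [MarkerIndex-class].
#' @return A data.frame with columns `class` (factor: `experimental`,
#'   `native`, `ambiguous`) and `reason` (`exp_word`, `native_word`,
#'   `no_marker_word`, `both_words`, `too_short`), one row per read.
#' @export
assignReads <- function(placements, index) {
  if (is.null(placements$sequence))
    stop("read sequences are required for marker discrimination")
  reads <- toupper(placements$sequence)
  n <- length(reads)
  minWord <- 2L * index@flank
  hasExp <- rep(FALSE, n); hasNat <- rep(FALSE, n)
  for (w in index@expWords) hasExp <- hasExp | grepl(w, reads, fixed = TRUE)
  for (w in index@natWords) hasNat <- hasNat | grepl(w, reads, fixed = TRUE)
  tooShort <- nchar(reads) < minWord
  cls <- ifelse(hasExp & !hasNat, "experimental",
         ifelse(hasNat & !hasExp, "native", "ambiguous"))
  cls[tooShort] <- "ambiguous"
  reason <- ifelse(hasExp & !hasNat, "exp_word",
            ifelse(hasNat & !hasExp, "native_word",
            ifelse(hasExp & hasNat, "both_words", "no_marker_word")))
  reason[tooShort] <- "too_short"
  data.frame(class = factor(cls, levels = c("experimental", "native",
                                            "ambiguous")),
             reason = reason, stringsAsFactors = FALSE)
}

#' Regression of CENP-A binding on segment A+T content
#'
#' Tiles the sequence into non-overlapping segments (default 180 bp;
#' trailing partial segment dropped), takes the segment A+T fraction as
#' predictor and the segment's binding level as response, and fits
#' ordinary least squares with a two-sided t test of the slope. The
#' default response is mean normalized depth; `response = "read_count"`
#' instead counts reads whose placement midpoint falls in the segment
#' (requires `placements`).
#'
#' @param track A [CoverageTrack-class] over the sequence.
#' @param x The sequence (same length as the track).
#' @param segment Segment width in bp (default 180).
#' @param normalized Use normalized (default) or raw depth for the
#'   `mean_depth` response.
#' @param response `"mean_depth"` (default) or `"read_count"`.
#' @param placements Placement data.frame, required for
#'   `response = "read_count"`.
#' @return A list with elements `slope`, `intercept`, `slopeSE`,
#'   `rSquared`, `pValue`, `nSegments`, `segment` and `response`.
#' @export
bindingATRegression <- function(track, x, segment = 180L,
                                normalized = TRUE,
                                response = c("mean_depth", "read_count"),
                                placements = NULL) {
  response <- match.arg(response)
  x <- asAnnSeq(x)
  segment <- as.integer(segment)
  if (length(track) != length(x))
    stop("track and sequence must have the same length")
  if (length(x) < 2L * segment)
    stop("sequence must cover at least two segments")
  nSeg <- length(x) %/% segment
  if (nSeg < 3L) stop("fewer than 3 segments: regression undefined")
  at <- windowedAT(x, window = segment, step = segment)@values[seq_len(nSeg)]
  segIdx <- rep(seq_len(nSeg), each = segment)
  if (response == "mean_depth") {
    dep <- as.numeric(if (normalized) normalizedDepth(track)
                      else depth(track))
    y <- as.numeric(tapply(dep[seq_len(nSeg * segment)], segIdx, mean))
  } else {
    if (is.null(placements))
      stop("'placements' required for read_count response")
    mid <- (placements$start + placements$end) / 2 + 0.5  # 1-based midpoint
    seg <- ceiling(mid / segment)
    y <- as.numeric(tabulate(seg[seg >= 1 & seg <= nSeg], nbins = nSeg))
    if (normalized) y <- y / track@normFactor
  }
  base <- list(nSegments = nSeg, segment = segment, response = response,
               normalized = normalized)
  if (stats::var(y) == 0)
    return(c(list(slope = 0, intercept = y[1], slopeSE = NA_real_,
                  rSquared = 0, pValue = 1), base))
  if (stats::var(at) == 0)
    stop("zero variance in segment A+T: regression undefined")
  fit <- stats::lm(y ~ at)
  sm <- summary(fit)
  c(list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         slopeSE = unname(sm$coefficients[2L, 2L]),
         rSquared = sm$r.squared,
         pValue = unname(sm$coefficients[2L, 4L])), base)
}
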