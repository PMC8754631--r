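#' Construct an AnnotatedSequence
#'
#' Validating constructor for [AnnotatedSequence-class]. Residues are
#' normalized to upper case. By default any residue outside A/C/G/T raises
#' an error naming the first offending position (strict mode); with
#' `ambig = "gc"` IUPAC ambiguity codes are accepted and resolved for
#' composition purposes: `W` (A/T ambiguity) becomes `A`, all other codes
#' become `G` so they count as G/C-equivalent.
#'
#' @param id Single character identifier.
#' @param residues DNA as a character string or [Biostrings::DNAString].
#' @param features Optional feature table: either an [IRanges::IRanges] with
#'   a `kind` metadata column or a data.frame with columns `start`, `end`
#'   (1-based, closed) and `kind`.
#' @param ambig `"error"` (default, strict) or `"gc"` (resolve ambiguity
#'   codes as described above).
#' @return An `AnnotatedSequence`.
#' @examples
#' s <- AnnotatedSequence("demo", "acgtACGT")
#' atFraction(s)
#' @export
AnnotatedSequence <- function(id, residues, features = NULL,
                              ambig = c("error", "gc")) {
  ambig <- match.arg(ambig)
  if (is(residues, "DNAString")) residues <- as.character(residues)
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) < 1L) stop("empty sequence")
  residues <- toupper(residues)
  bad <- regexpr("[^ACGT]", residues)
  if (bad > 0L) {
    if (ambig == "error") {
      stop(sprintf("non-ACGT residue '%s' at position %d of '%s'",
                   substr(residues, bad, bad), bad, id))
    }
    # IUPAC resolution: W is A/T-ambiguous -> A; everything else counts G/C.
    residues <- chartr("WRYSKMBDHVN", "AGGGGGGGGGG", residues)
    if (regexpr("[^ACGT]", residues) > 0L)
      stop("residues outside the IUPAC DNA alphabet")
  }
  if (is.null(features)) {
    fr <- emptyFeatures()
  } else if (is(features, "IRanges")) {
    fr <- features
  } else {
    fr <- makeFeatures(features$start, features$end, features$kind)
  }
  new("AnnotatedSequence", id = as.character(id),
      seq = Biostrings::DNAString(residues), features = fr)
}

#' @rdname AnnotatedSequence
#' @export
setMethod("seqId", "AnnotatedSequence", function(x) x@id)

#' @rdname AnnotatedSequence
#' @export
setMethod("residues", "AnnotatedSequence", function(x) x@seq)

#' @rdname AnnotatedSequence
#' @export
setMethod("seqFeatures", "AnnotatedSequence", function(x) x@features)

#' @rdname AnnotatedSequence
#' @export
setMethod("length", "AnnotatedSequence", function(x) length(x@seq))

#' @rdname AnnotatedSequence
#' @param object An `AnnotatedSequence`.
#' @export
setMethod("show", "AnnotatedSequence", function(object) {
  cat(sprintf("AnnotatedSequence '%s': %d bp, A+T %.4f, %d feature(s)\n",
              object@id, length(object@seq), atFraction(object),
              length(object@features)))
})

#' @rdname AnnotatedSequence
#' @export
setMethod("as.character", "AnnotatedSequence",
          function(x) as.character(x@seq))

#' Read and write annotated sequences as FASTA
#'
#' Multi-record FASTA I/O built on [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] (wrapped at 60 columns on output).
#' Interval features are not representable in FASTA and are dropped on
#' write; reading yields feature-less records.
#'
#' @param file Path to a FASTA file.
#' @param ambig Passed to [AnnotatedSequence()].
#' @return `readFasta`: a named list of [AnnotatedSequence-class] objects.
#' @export
readFasta <- function(file, ambig = c("error", "gc")) {
  ambig <- match.arg(ambig)
  set <- Biostrings::readDNAStringSet(file)
  out <- lapply(seq_along(set), function(i) {
    AnnotatedSequence(id = names(set)[i],
                      residues = as.character(set[[i]]), ambig = ambig)
  })
  names(out) <- names(set)
  out
}

#' @rdname readFasta
#' @param x An `AnnotatedSequence` or list of them.
#' @export
writeFasta <- function(x, file) {
  if (is(x, "AnnotatedSequence")) x <- list(x)
  set <- Biostrings::DNAStringSet(vapply(x, as.character, character(1)))
  names(set) <- vapply(x, seqId, character(1))
  Biostrings::writeXStringSet(set, filepath = file, width = 60L)
  invisible(file)
}
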