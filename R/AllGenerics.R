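#' @include AllClasses.R
NULL

#' @rdname atFraction
#' @export
setGeneric("atFraction", function(x, ...) standardGeneric("atFraction"))

#' @rdname AnnotatedSequence
#' @param x An `AnnotatedSequence`.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname AnnotatedSequence
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname AnnotatedSequence
#' @export
setGeneric("seqFeatures", function(x) standardGeneric("seqFeatures"))

#' @rdname CoverageTrack
#' @param x A `CoverageTrack`.
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @rdname CoverageTrack
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))

#' @rdname CoverageTrack
#' @export
setGeneric("normalizedDepth", function(x) standardGeneric("normalizedDepth"))
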