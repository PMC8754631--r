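# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded operations never perturb
# the global stream. A NULL seed uses (and advances) the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed for a named component stream, so adding a
# generator never perturbs existing fixtures (kept below 2^31).
subSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

# Coerce character / DNAString input to AnnotatedSequence.
asAnnSeq <- function(x, id = "seq") {
  if (is(x, "AnnotatedSequence")) return(x)
  AnnotatedSequence(id = id, residues = x)
}

# Character-vector view of the residues (one element per base).
seqChars <- function(x) {
  strsplit(as.character(residues(asAnnSeq(x))), "", fixed = TRUE)[[1L]]
}

emptyFeatures <- function() {
  fr <- IRanges::IRanges()
  S4Vectors::mcols(fr) <- S4Vectors::DataFrame(kind = character(0))
  fr
}

makeFeatures <- function(start, end, kind) {
  fr <- IRanges::IRanges(start = as.integer(start), end = as.integer(end))
  S4Vectors::mcols(fr) <- S4Vectors::DataFrame(kind = as.character(kind))
  fr
}
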