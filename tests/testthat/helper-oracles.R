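# Independent brute-force oracles used to cross-check the implementation.

# Per-window A+T by direct recount on the character vector.
oracleWindowAT <- function(s, window, step) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  starts <- seq.int(1L, nchar(s) - window + 1L, by = step)
  vapply(starts, function(st)
    sum(ch[st:(st + window - 1L)] %in% c("A", "T")) / window, numeric(1))
}

# Maximal single-base A/T runs by position-wise scanning (quadratic-ish,
# deliberately naive).
oracleRuns <- function(s, minLen) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (ch[i] %in% c("A", "T")) {
      j <- i
      while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
      if (j - i + 1L >= minLen)
        out[[length(out) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, out)
}

# Smallest p such that a Binomial(n, p) yields zero successes with
# probability at most 1 - confidence, found by bisection on the exact
# zero-success probability (continuous n allowed).
oracleZeroEventBound <- function(trials, confidence, tol = 1e-12) {
  lo <- 0; hi <- 1
  target <- 1 - confidence
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if ((1 - mid)^trials > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Per-base coverage by interval stabbing, one read at a time
# (0-based half-open placements).
oracleCoverage <- function(starts0, ends0, len) {
  depth <- integer(len)
  for (k in seq_along(starts0)) {
    idx <- (starts0[k] + 1L):ends0[k]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Random ACGT string with roughly the given A+T fraction (i.i.d. bases);
# independent of the package's two-state generator.
oracleRandomSeq <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}
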