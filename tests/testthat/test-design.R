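test_that("concatemerize lengths and composition behave exactly", {
  unit <- genSequence(889, 0.70, seed = 11, id = "u889")
  expect_equal(length(concatemerize(unit, 7)), 6223L)
  expect_equal(length(concatemerize(unit, 5)), 4445L)
  expect_equal(round(6223 / 1000, 1), 6.2)
  expect_equal(round(4445 / 1000, 1), 4.4)
  one <- concatemerize(unit, 1)
  expect_identical(as.character(one), as.character(unit))
  # composition invariant under concatemerization
  expect_equal(atFraction(concatemerize(unit, 7)), atFraction(unit))
  # unit features annotate each copy
  fr <- seqFeatures(concatemerize(unit, 3))
  expect_equal(IRanges::start(fr), c(1L, 890L, 1779L))
  expect_error(concatemerize(unit, 0), ">= 1")
})

test_that("buildInterleaved alternates pools and truncates to segments", {
  pa <- genSegmentPool(30, 20, 0.94, seed = 21)
  pb <- genSegmentPool(30, 20, 0.55, seed = 22)
  il <- buildInterleaved(pa, pb, 20, 5900, seed = 23)
  expect_equal(length(il), 5900L)
  fr <- seqFeatures(il)
  expect_equal(S4Vectors::mcols(fr)$kind[1:4],
               c("segment_a", "segment_b", "segment_a", "segment_b"))
  # truncation: 130 bp total emits 6 whole 20 bp segments
  il2 <- buildInterleaved(pa, pb, 20, 130, seed = 23)
  expect_equal(length(il2), 120L)
  # single-segment design returns one A-pool segment
  il3 <- buildInterleaved(pa, pb, 20, 20, seed = 24)
  expect_true(as.character(il3) %in% pa)
  expect_error(buildInterleaved(character(0), pb, 20, 100), "non-empty")
})

test_that("interleaved composition equals the segment-weighted mean", {
  set.seed(31)
  for (i in 1:5) {
    pa <- genSegmentPool(10, 15, runif(1, 0.7, 1), seed = 100 + i)
    pb <- genSegmentPool(10, 15, runif(1, 0.3, 0.6), seed = 200 + i)
    il <- buildInterleaved(pa, pb, 15, 450, seed = 300 + i)
    fr <- seqFeatures(il)
    segAT <- vapply(seq_along(fr), function(j)
      atFraction(substr(as.character(il), IRanges::start(fr)[j],
                        IRanges::end(fr)[j])), numeric(1))
    expect_equal(atFraction(il), mean(segAT))
  }
})

test_that("introduceMarkers places one revertible deletion per kb block", {
  g <- genSequence(9460, 0.72, seed = 41, id = "cc")
  mk <- introduceMarkers(g, seed = 42)
  expect_equal(length(mk$markers), 9L)
  expect_equal(length(mk$seq), 9424L)
  expect_equal(sum(nchar(markerRemoved(mk$markers))),
               length(g) - length(mk$seq))
  # deletions sorted, non-overlapping, away from the ends
  st <- markerStarts(mk$markers)
  expect_true(all(diff(st) > 4L))
  expect_true(st[1] > 4L && max(st) + 3L <= length(g) - 4L)
  # round trip reconstructs the input byte-for-byte
  expect_identical(as.character(revertMarkers(mk$seq, mk$markers)),
                   as.character(g))
})

test_that("marker round trips hold across seeds and zero-length no-op", {
  g <- genSequence(3500, 0.65, seed = 43)
  for (sd in c(1, 7, 99)) {
    mk <- introduceMarkers(g, seed = sd)
    expect_identical(as.character(revertMarkers(mk$seq, mk$markers)),
                     as.character(g))
  }
  noop <- introduceMarkers(g, delLen = 0, seed = 1)
  expect_identical(as.character(noop$seq), as.character(g))
  expect_equal(length(noop$markers), 0L)
  expect_error(introduceMarkers(g, spacing = 100, jitter = 60, seed = 1),
               "jitter")
})

test_that("marker sets serialize to TSV and BED", {
  g <- genSequence(4200, 0.7, seed = 44)
  mk <- introduceMarkers(g, seed = 45)
  tsv <- tempfile(fileext = ".tsv")
  writeMarkerTSV(mk$markers, tsv)
  back <- readMarkerTSV(tsv)
  expect_equal(markerStarts(back), markerStarts(mk$markers))
  expect_equal(markerRemoved(back), markerRemoved(mk$markers))
  bed <- tempfile(fileext = ".bed")
  writeMarkerBed(mk$markers, "cand", bed)
  df <- read.delim(bed, header = FALSE)
  expect_equal(df$V2 + 1L, markerStarts(mk$markers))
  expect_equal(df$V3 - df$V2, nchar(markerRemoved(mk$markers)))
})

test_that("disruptRuns breaks runs minimally with G/C substitutions", {
  out <- as.character(disruptRuns("AAAA", seed = 1))
  expect_match(out, "^AA[GC]A$")
  expect_identical(as.character(disruptRuns("ACGTACGT", seed = 1)),
                   "ACGTACGT")
  # seeded determinism
  g <- genSequence(2000, 0.75, runIntensity = 3, seed = 51)
  expect_identical(as.character(disruptRuns(g, seed = 5)),
                   as.character(disruptRuns(g, seed = 5)))
})

test_that("disruptRuns postconditions hold on structured sequences", {
  set.seed(52)
  for (i in 1:10) {
    g <- genSequence(sample(300:1500, 1), runif(1, 0.55, 0.85),
                     runIntensity = runif(1, 1, 4), seed = 500 + i)
    mr <- sample(2:3, 1)
    out <- disruptRuns(g, maxRun = mr, seed = 600 + i)
    expect_equal(length(out), length(g))
    runs <- findATRuns(out, minLen = mr + 1L)
    expect_equal(length(runs), 0L)
    # A+T drop equals substitutions / length, and substitution count is
    # the greedy minimum
    inRuns <- findATRuns(g, minLen = mr + 1L)
    nSub <- sum(IRanges::width(inRuns) %/% (mr + 1L))
    expect_equal(atFraction(g) - atFraction(out), nSub / length(g))
  }
})

test_that("reduceATPreservingRuns preserves runs and hits the target", {
  # worked example: the AAAA run is untouched and substitutions fall
  # outside it, landing within 1/length of the target
  out <- reduceATPreservingRuns("AAAATGTG", 0.5, seed = 1)
  expect_equal(substr(as.character(out), 1, 4), "AAAA")
  expect_true(abs(atFraction(out) - 0.5) <= 1 / 8)
  ch_in <- strsplit("AAAATGTG", "")[[1L]]
  ch_out <- strsplit(as.character(out), "")[[1L]]
  expect_true(all(which(ch_in != ch_out) %in% c(5L, 7L)))

  # identity when target equals current composition
  g <- genSequence(1200, 0.7, runIntensity = 2, seed = 61)
  same <- reduceATPreservingRuns(g, atFraction(g), seed = 62)
  expect_identical(as.character(same), as.character(g))
})

test_that("reduceATPreservingRuns conserves run structure on random input", {
  set.seed(63)
  for (i in 1:10) {
    g <- genSequence(sample(400:1200, 1), runif(1, 0.6, 0.8),
                     runIntensity = runif(1, 1, 3), seed = 700 + i)
    target <- atFraction(g) - runif(1, 0.02, 0.08)
    out <- reduceATPreservingRuns(g, target, seed = 800 + i)
    expect_identical(findATRuns(out, 3), findATRuns(g, 3))
    expect_true(abs(atFraction(out) - target) <= 1 / length(g))
  }
})

test_that("reduceATPreservingRuns rejects unachievable targets", {
  g <- genSequence(1000, 0.8, runIntensity = 4, seed = 71)
  expect_error(reduceATPreservingRuns(g, 0.01, seed = 72),
               "minimum achievable")
  expect_error(reduceATPreservingRuns(g, 0.95, seed = 73), "above current")
})

test_that("selectATWindows ranks windows and recovers planted islands", {
  flat <- genSequence(6000, 0.60, seed = 81)
  expect_equal(nrow(selectATWindows(flat, 500, 0.75)), 0L)

  # plant a 0.78 island in a 0.55 background
  bg <- as.character(genSequence(8000, 0.55, seed = 82))
  island <- as.character(genSequence(500, 0.78, seed = 83))
  genome <- paste0(substr(bg, 1, 4000), island, substr(bg, 4501, 8000))
  hits <- selectATWindows(genome, 500, 0.70)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$start[1], 4001)
  expect_equal(hits$at[1], 0.78)

  # ranking equals an exhaustive recount
  all <- selectATWindows(genome, 500, 0)
  oracle <- oracleWindowAT(genome, 500, 500)
  expect_equal(all$at, sort(oracle, decreasing = TRUE))
})
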