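test_that("coverage tracks count interval stabbing exactly", {
  empty <- coverageTrack(
    data.frame(reference = character(0), start = integer(0),
               end = integer(0)), 30, reference = "r")
  expect_equal(as.numeric(depth(empty)), rep(0, 30))

  one <- coverageTrack(data.frame(reference = "r", start = 10, end = 20),
                       referenceLength = 30)
  d <- as.numeric(depth(one))
  expect_equal(d[11:20], rep(1, 10))
  expect_equal(sum(d), 10)

  set.seed(91)
  n <- 10000L; L <- 300L
  starts <- sample.int(L - 20L, n, replace = TRUE) - 1L
  ends <- starts + sample(5:20, n, replace = TRUE)
  pl <- data.frame(reference = "r", start = starts, end = ends)
  trk <- coverageTrack(pl, L)
  expect_equal(as.numeric(depth(trk)), oracleCoverage(starts, ends, L))
  # integral conservation
  expect_equal(sum(as.numeric(depth(trk))), sum(ends - starts))
})

test_that("placements beyond the reference are rejected with offenders", {
  pl <- data.frame(reference = "r", start = c(0, 290, 5),
                   end = c(10, 310, 3))
  expect_error(coverageTrack(pl, 300), "2 invalid placement")
})

test_that("normalization scales by the mean reference read count", {
  pl <- data.frame(reference = "r", start = rep(0, 100), end = rep(50, 100))
  trk <- coverageTrack(pl, 50)
  n1 <- normalizeToReference(trk, 100, 100)
  expect_equal(as.numeric(normalizedDepth(n1)), rep(1, 50))
  n2 <- normalizeToReference(trk, 100, 300)
  expect_equal(normFactor(n2), 200)
  expect_equal(as.numeric(normalizedDepth(n2)), rep(0.5, 50))
  # re-scaling by the factor recovers the raw track
  expect_equal(as.numeric(normalizedDepth(n2)) * normFactor(n2),
               as.numeric(depth(n2)))
  expect_error(normalizeToReference(trk, 0, 10), "positive")
})

test_that("placement TSV and SAM readers agree", {
  ref <- genSequence(400, 0.6, seed = 101, id = "cand")
  reads <- substring(as.character(ref), c(1, 51, 101), c(50, 100, 150))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:cand\tLN:400",
    sprintf("r1\t0\tcand\t1\t60\t50M\t*\t0\t0\t%s\t*", reads[1]),
    sprintf("r2\t0\tcand\t51\t60\t50M\t*\t0\t0\t%s\t*", reads[2]),
    sprintf("r3\t16\tcand\t101\t60\t50M\t*\t0\t0\t%s\t*", reads[3]),
    # unmapped and secondary records must be dropped
    sprintf("r4\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", reads[1]),
    sprintf("r5\t256\tcand\t1\t60\t50M\t*\t0\t0\t%s\t*", reads[1])
  ), sam)
  fromSam <- readPlacementsSam(sam)
  expect_equal(nrow(fromSam), 3L)
  expect_equal(fromSam$start, c(0L, 50L, 100L))
  expect_equal(fromSam$end, c(50L, 100L, 150L))

  tsv <- tempfile(fileext = ".tsv")
  writePlacements(fromSam[, c("reference", "start", "end", "sequence")], tsv)
  fromTsv <- readPlacements(tsv)
  expect_equal(fromTsv$start, fromSam$start)
  expect_equal(fromTsv$end, fromSam$end)
  # both feed the same coverage
  expect_equal(as.numeric(depth(coverageTrack(fromSam, 400))),
               as.numeric(depth(coverageTrack(fromTsv, 400))))
})

test_that("marker index words discriminate by construction", {
  g <- genSequence(5200, 0.70, seed = 111, id = "cand")
  mk <- introduceMarkers(g, seed = 112)
  idx <- markerIndex(g, mk$markers)
  marked <- as.character(residues(mk$seq))
  native <- as.character(g)
  for (w in idx@expWords) {
    expect_true(grepl(w, marked, fixed = TRUE))
    expect_false(grepl(w, native, fixed = TRUE))
  }
  for (w in idx@natWords) {
    expect_true(grepl(w, native, fixed = TRUE))
    expect_false(grepl(w, marked, fixed = TRUE))
  }
})

test_that("marker index construction fails on colliding words", {
  # periodic sequence: junction words recur elsewhere in the native copy
  per <- AnnotatedSequence("per", strrep("ACGTTGCA", 400))
  mk <- introduceMarkers(per, seed = 113)
  expect_error(markerIndex(per, mk$markers), "colliding")
})

test_that("reads partition into experimental/native/ambiguous", {
  g <- genSequence(4100, 0.72, seed = 121, id = "cand")
  mk <- introduceMarkers(g, seed = 122)
  idx <- markerIndex(g, mk$markers)
  marked <- as.character(residues(mk$seq))
  native <- as.character(g)
  p1 <- markerStarts(mk$markers)[1]

  reads <- data.frame(
    reference = "cand",
    start = 0L, end = 60L,
    sequence = c(
      substr(marked, p1 - 30, p1 + 29),   # spans a junction, marked copy
      substr(native, p1 - 30, p1 + 33),   # same locus, native copy
      substr(marked, p1 + 30, p1 + 89),   # between markers: identical
      substr(marked, p1 - 8, p1 + 6)),    # 15 bp: shorter than any word
    stringsAsFactors = FALSE)
  asn <- assignReads(reads, idx)
  expect_equal(as.character(asn$class),
               c("experimental", "native", "ambiguous", "ambiguous"))
  expect_equal(asn$reason,
               c("exp_word", "native_word", "no_marker_word", "too_short"))
  expect_error(assignReads(reads[, 1:3], idx), "sequence")
})

test_that("a planted 70:30 mixture is recovered from unambiguous reads", {
  g <- genSequence(3600, 0.72, seed = 131, id = "cand")
  mk <- introduceMarkers(g, seed = 132)
  idx <- markerIndex(g, mk$markers)
  sim <- genChipExperiment(mk$seq, g, depth = 120, readLen = 100,
                           errorRate = 0, mixture = 0.7, seed = 133)
  asn <- assignReads(sim$placements, idx)
  tb <- table(asn$class)
  nU <- tb[["experimental"]] + tb[["native"]]
  pHat <- tb[["experimental"]] / nU
  se <- sqrt(0.7 * 0.3 / nU)
  expect_lt(abs(pHat - 0.7), 3 * se)
  # no unambiguous read is misassigned at zero error rate
  cls <- as.character(asn$class)
  expect_true(all(sim$placements$origin[cls == "experimental"] ==
                    "experimental"))
  expect_true(all(sim$placements$origin[cls == "native"] == "native"))
})

test_that("sequencing errors inflate only the ambiguous fraction", {
  g <- genSequence(3600, 0.72, seed = 141, id = "cand")
  mk <- introduceMarkers(g, seed = 142)
  idx <- markerIndex(g, mk$markers)
  frac <- vapply(c(0, 0.05, 0.15), function(e) {
    sim <- genChipExperiment(mk$seq, g, depth = 60, readLen = 100,
                             errorRate = e, mixture = 0.5, seed = 143)
    mean(assignReads(sim$placements, idx)$class == "ambiguous")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("binding regression handles degenerate and exact cases", {
  s <- genSequence(1800, 0.7, seed = 151)
  flat <- coverageTrack(data.frame(start = rep(0, 50), end = rep(1800, 50)),
                        1800, reference = "s")
  f0 <- bindingATRegression(flat, s)
  expect_equal(f0$slope, 0)
  expect_equal(f0$rSquared, 0)
  expect_equal(f0$nSegments, 10L)

  # depth exactly proportional to segment A+T gives R^2 = 1
  at <- profileValues(windowedAT(s, 180, 180))
  prop <- new("CoverageTrack", reference = "s",
              depth = S4Vectors::Rle(rep(100 * at, each = 180)),
              normFactor = 1)
  f1 <- suppressWarnings(bindingATRegression(prop, s)) # exact fit warns
  expect_equal(f1$rSquared, 1)
  expect_equal(f1$slope, 100)

  short <- genSequence(350, 0.7, seed = 152)
  trk <- coverageTrack(data.frame(start = 0, end = 350), 350)
  expect_error(bindingATRegression(trk, short), "two segments|3 segments")
})

test_that("binding regression recovers a planted slope", {
  set.seed(161)
  s <- genSequence(9000, 0.7, runIntensity = 2, seed = 162)
  at <- profileValues(windowedAT(s, 180, 180))
  y <- 10 - 5 * at + rnorm(length(at), 0, 0.3)
  trk <- new("CoverageTrack", reference = "s",
             depth = S4Vectors::Rle(rep(y, each = 180)), normFactor = 1)
  fit <- bindingATRegression(trk, s)
  expect_lt(abs(fit$slope - (-5)), 3 * fit$slopeSE)
})

test_that("binding regression is invariant to segment order", {
  s <- genSequence(3600, 0.7, seed = 171)
  set.seed(172)
  y <- runif(20, 0, 10)
  trk <- new("CoverageTrack", reference = "s",
             depth = S4Vectors::Rle(rep(y, each = 180)), normFactor = 1)
  fit <- bindingATRegression(trk, s)
  # permute whole segments of both sequence and track
  perm <- sample(20)
  ch <- strsplit(as.character(s), "")[[1L]]
  segs <- split(ch, rep(1:20, each = 180))
  s2 <- AnnotatedSequence("perm",
                          paste(unlist(segs[perm]), collapse = ""))
  trk2 <- new("CoverageTrack", reference = "s",
              depth = S4Vectors::Rle(rep(y[perm], each = 180)),
              normFactor = 1)
  fit2 <- bindingATRegression(trk2, s2)
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$rSquared, fit$rSquared)
})

test_that("read-count response mode matches placements", {
  s <- genSequence(1800, 0.7, seed = 181)
  pl <- data.frame(start = c(rep(10, 30), rep(900, 10)),
                   end = c(rep(110, 30), rep(1000, 10)))
  trk <- coverageTrack(pl, 1800, reference = "s")
  fit <- bindingATRegression(trk, s, response = "read_count",
                             placements = pl)
  expect_equal(fit$response, "read_count")
  expect_equal(fit$nSegments, 10L)
})
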