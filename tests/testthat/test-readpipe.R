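test_that("quality-tail truncation cuts at the first sub-cutoff base", {
  r <- truncateTail("ACGT", c(30L, 30L, 19L, 30L), qCutoff = 20)
  expect_identical(r$seq, "AC")
  expect_identical(r$qual, c(30L, 30L))
  r2 <- truncateTail("ACGT", rep(20L, 4), qCutoff = 20)
  expect_identical(r2$seq, "ACGT")
  r3 <- truncateTail("ACGT", c(10L, 30L, 30L, 30L), qCutoff = 20)
  expect_identical(r3$seq, "")
  expect_length(r3$qual, 0L)
})

test_that("pair merging reconstructs the fragment and applies reject rules", {
  set.seed(41)
  frag <- randomSeq(215)
  r1 <- substr(frag, 1, 150)
  r2 <- revcompStr(substr(frag, 66, 215))
  q <- rep(35L, 150)
  m <- mergePair(r1, q, r2, q)
  expect_identical(m$seq, frag)               # ~85 bp error-free overlap
  expect_identical(m$overlapDiffs, 0L)
  expect_identical(m$overlapLen, 85L)

  # plant conflicts inside the overlap region of R1
  conflict <- function(k) {
    r1c <- mutateSeq(r1, sample(66:150, k))
    mergePair(r1c, q, r2, q)
  }
  expect_null(conflict(6))                    # > 5 differences: discarded
  m5 <- conflict(5)
  expect_false(is.null(m5))                   # boundary: 5 still merges
  expect_identical(m5$overlapDiffs, 5L)

  # conflict resolution: higher-quality base wins, quality |Q1 - Q2|
  q1 <- q; q1[100] <- 12L
  r1c <- mutateSeq(r1, 100)
  mc <- mergePair(r1c, q1, r2, q)
  expect_identical(substr(mc$seq, 100, 100), substr(frag, 100, 100))
  expect_identical(mc$qual[100], 35L - 12L)
})

test_that("merging agrees with the brute-force overlap oracle", {
  set.seed(42)
  q <- rep(30L, 150)
  for (i in 1:60) {
    frag <- randomSeq(sample(180:260, 1))
    n <- nchar(frag)
    r1 <- substr(frag, 1, 150)
    r2 <- revcompStr(substr(frag, n - 149, n))
    r1 <- mutateSeq(r1, sample(150, sample(0:6, 1)))
    got <- mergePair(r1, q, r2, q)
    want <- bruteMerge(r1, r2, minOverlap = 16, maxDiffs = 5)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$overlapLen, want$overlap)
      expect_identical(got$overlapDiffs, want$diffs)
      expect_identical(nchar(got$seq), nchar(want$seq))
    }
  }
})

test_that("primer stripping is anchored and mismatch-tolerant", {
  pair <- primerPair(EEL_FWD, EEL_REV)
  core <- randomSeq(167)
  read <- paste0(EEL_FWD, core, revcompStr(EEL_REV))
  qual <- rep(35L, nchar(read))
  s <- stripPrimers(read, qual, pair)
  expect_identical(s$seq, core)
  expect_length(s$qual, 167L)
  # missing reverse-primer tail -> reject
  short <- substr(read, 1, nchar(read) - 10)
  expect_null(stripPrimers(short, qual[1:nchar(short)], pair))
  # one mismatch in the forward primer is tolerated
  read1 <- read
  substr(read1, 3, 3) <- "G"
  expect_false(is.null(stripPrimers(read1, qual, pair)))
  # three mismatches exceed the default tolerance
  read3 <- mutateSeq(read, c(2, 5, 9))
  expect_null(stripPrimers(read3, qual, pair, maxMm = 2))
})

test_that("expected-error filter is a rate with an inclusive boundary", {
  expect_true(eeFilter(rep(20L, 150)))        # EE = 1.5, rate exactly 0.01
  expect_false(eeFilter(rep(19L, 150)))       # rate 0.0126 > 0.01
  expect_false(eeFilter(rep(40L, 119)))       # perfect but too short
  expect_true(eeFilter(rep(40L, 120)))
})

test_that("dereplication drops rare uniques and conserves read counts", {
  seqs <- c(rep("AAAA", 5), rep("CCCC", 3), "GGGG")
  u <- dereplicate(seqs)
  expect_identical(u$seq, "AAAA")
  expect_identical(u$abundance, 5L)
  expect_identical(attr(u, "totalInput"), 9L)
  expect_identical(attr(u, "dropped"), 4L)
  expect_identical(sum(u$abundance) + attr(u, "dropped"), 9L)
  expect_identical(nrow(dereplicate(character())), 0L)
  # ordering: abundance descending, ties lexicographic
  u2 <- dereplicate(c(rep("TTTT", 4), rep("AAAA", 4)), minAbundance = 4)
  expect_identical(u2$seq, c("AAAA", "TTTT"))
})

test_that("abundance-skew denoising follows the beta(d) rule", {
  u <- data.frame(seq = c("AAAAAAAAAA", "AAAAAAAAAC"),
                  abundance = c(100L, 2L))
  # skew 0.02 <= beta(1) = 1/2^3 = 0.125 -> merged
  d <- denoise(u, alpha = 2)
  expect_identical(nrow(d), 1L)
  expect_identical(d$abundance, 102L)
  # abundant variant exceeds the skew bound -> its own centroid
  u2 <- data.frame(seq = c("AAAAAAAAAA", "AAAAAAAAAC"),
                   abundance = c(100L, 20L))
  d2 <- denoise(u2, alpha = 2)
  expect_identical(nrow(d2), 2L)
  expect_identical(sum(d2$abundance), 120L)
  # singleton input is its own centroid
  d3 <- denoise(data.frame(seq = "ACGT", abundance = 7L))
  expect_identical(d3$seq, "ACGT")
  expect_identical(d3$abundance, 7L)
})

test_that("identity assignment honours the 98.5% threshold boundary", {
  set.seed(51)
  ref <- randomSeq(167)
  refdb <- referencePanel(c(refA = ref, refB = mutateSeq(ref, 1:30)),
                          taxon = c(refA = "taxA", refB = "taxB"))
  centroid <- function(k) data.frame(
    seq = if (k == 0) ref else mutateSeq(ref, sample(20:150, k)),
    abundance = 10L)
  # 0-2 substitutions over 167 pass (>= 98.5%), 3 fail
  for (k in 0:2) {
    a <- assignReads(centroid(k), refdb)
    expect_identical(unname(a["taxA"]), 10)
  }
  a3 <- assignReads(centroid(3), refdb)
  expect_identical(unname(a3["unassigned"]), 10)
  expect_identical(unname(a3["taxA"]), 0)
  # reference order never changes the result
  refdb2 <- referencePanel(c(refB = mutateSeq(ref, 1:30), refA = ref),
                           taxon = c(refB = "taxB", refA = "taxA"))
  c1 <- centroid(1)
  expect_identical(assignReads(c1, refdb), assignReads(c1, refdb2))
  # a tie across two taxa is ambiguous, not split
  twin <- referencePanel(c(r1 = ref, r2 = ref),
                         taxon = c(r1 = "taxA", r2 = "taxB"))
  at <- assignReads(centroid(0), twin)
  expect_identical(unname(at["unassigned"]), 10)
  expect_error(assignReads(centroid(0), referencePanel(character())))
})

test_that("pipeline conserves read counts and recovers zero-error truth", {
  pl <- plantMarkerAlignment(nTaxa = 5, coreLen = 167, minCoreDiffs = 5,
                             seed = 61)
  pair <- primerPair(pl$truth$fwdPrimer, pl$truth$revPrimer)
  amp <- extractAmplicons(pair, pl$panel, maxMm = 2)
  refdb <- referencePanel(amp$cores,
                          taxon = setNames(names(amp$cores),
                                           names(amp$cores)))
  comp <- c(taxon01 = 60, taxon03 = 40, taxon05 = 25)
  sim <- simulateMockReads(comp, pair, pl$panel, errorModel = "none",
                           seed = 62)
  blank <- simulateMockReads(setNames(numeric(0), character(0)), pair,
                             pl$panel, seed = 63, sampleName = "blank")
  res <- runPipeline(list(mock = sim, blank = blank), pair, refdb,
                     blanks = "blank")
  log <- stageLog(res)
  # monotone survival and explicit conservation at the rare-unique stage
  expect_true(all(log$merged <= log$input))
  expect_true(all(log$stripped <= log$merged))
  expect_true(all(log$filtered <= log$stripped))
  expect_identical(log$dereplicated + log$rareDropped, log$filtered)
  expect_identical(log$denoised, log$dereplicated)
  expect_identical(log$assigned + log$unassigned, log$denoised)
  # column sums equal the per-sample denoised abundance
  expect_identical(unname(colSums(assignmentCounts(res))),
                   as.numeric(log$denoised))
  # zero-error mock: the table equals the truth exactly
  counts <- assignmentCounts(res)[, "mock"]
  expect_identical(counts[names(comp)], comp)
  expect_identical(sum(counts), sum(comp))
  expect_false(isContaminated(res))
  expect_identical(unname(colSums(assignmentCounts(res))["blank"]), 0)
})

test_that("reads in a declared blank flag the run as contaminated", {
  pl <- plantMarkerAlignment(nTaxa = 4, coreLen = 167, minCoreDiffs = 5,
                             seed = 71)
  pair <- primerPair(pl$truth$fwdPrimer, pl$truth$revPrimer)
  amp <- extractAmplicons(pair, pl$panel, maxMm = 2)
  refdb <- referencePanel(amp$cores,
                          taxon = setNames(names(amp$cores),
                                           names(amp$cores)))
  dirty <- simulateMockReads(setNames(numeric(0), character(0)), pair,
                             pl$panel, contamination = c(taxon02 = 7),
                             errorModel = "none", seed = 72,
                             sampleName = "blankX")
  res <- runPipeline(list(blankX = dirty), pair, refdb, blanks = "blankX")
  expect_true(isContaminated(res))
  expect_identical(unname(assignmentCounts(res)["taxon02", "blankX"]), 7)
  expect_error(runPipeline(list(blankX = dirty), pair, refdb,
                           blanks = "nosuch"), "not in input")
})
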