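test_that("gcContent matches hand arithmetic, fractional ambiguity codes", {
  expect_equal(gcContent(EEL_FWD), 50)
  expect_equal(gcContent(EEL_REV), 100 * 10 / 26, tolerance = 1e-12)
  expect_equal(round(gcContent(EEL_REV)), 38)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("SSSS"), 100)
  expect_equal(gcContent("RYKM"), 50)
  set.seed(2)
  for (i in 1:10) {
    s <- randomSeq(30)
    expect_equal(gcContent(s) + atContent(s), 100)
    expect_equal(gcContent(s), gcContent(revcompStr(s)))
  }
  expect_error(gcContent(""))
})

test_that("nnTm reproduces benchmark primers and duplex symmetry", {
  expect_equal(nnTm(EEL_FWD), 55.7, tolerance = 0.01)
  expect_equal(nnTm(EEL_REV), 55.9, tolerance = 0.01)
  set.seed(3)
  for (i in 1:10) {
    s <- randomSeq(sample(10:30, 1))
    expect_equal(nnTm(s), nnTm(revcompStr(s)))
  }
  expect_error(nnTm("ACGTNACGTA"), "invalid")
  expect_error(nnTm("ACGT"), "short")
  # longer and GC-richer oligos melt higher under any table
  expect_gt(nnTm(paste(rep("GC", 10), collapse = "")),
            nnTm(paste(rep("AT", 10), collapse = "")))
})

test_that("conservationProfile counts every template in every column", {
  panel <- referencePanel(c(t1 = "CCAA-G", t2 = "CCGA-G", t3 = "CCAA-T"))
  prof <- conservationProfile(panel)
  expect_true(all(colSums(prof) == 3L))
  expect_identical(unname(prof["C", 1]), 3L)            # invariant column
  expect_identical(unname(prof[c("A", "G"), 3]), c(2L, 1L))
  expect_identical(unname(prof["gap", 5]), 3L)          # all-gap column
  expect_identical(unname(attr(prof, "invariant")),
                   c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(conservationProfile(referencePanel(c(a = "ACG", b = "AC"))),
               "aligned")
})

test_that("conserved-window scan finds planted blocks and honours budgets", {
  set.seed(11)
  block <- randomSeq(25)
  # independently drawn divergent backgrounds around an identical block
  seqs <- setNames(vapply(1:6, function(i)
    paste0(randomSeq(40), block, randomSeq(40)), ""), paste0("t", 1:6))
  panel <- referencePanel(seqs)
  win <- findConservedWindows(panel, winMin = 20, winMax = 30,
                              maxMmPerTemplate = 0)
  hit <- win$start <= 41 & win$end >= 65
  expect_true(any(hit))
  expect_error(findConservedWindows(panel, winMin = 25, winMax = 20),
               "winMin")
})

test_that("single-mismatch windows pass at budget 1 and fail at 0", {
  pl <- eelLikePanel(seed = 4)
  panel <- pl$panel
  tr <- pl$truth
  win1 <- findConservedWindows(panel, maxMmPerTemplate = 1)
  covers <- function(w) any(w$start <= tr$fwdWindow["start"] &
                            w$end >= tr$fwdWindow["end"])
  expect_true(covers(win1))
  # with a zero budget no window can span the planted mismatch columns
  win0 <- findConservedWindows(panel, maxMmPerTemplate = 0)
  expect_false(covers(win0))
  # gap columns are excluded from windows
  gp <- plantMarkerAlignment(nTaxa = 5, coreLen = 100, minCoreDiffs = 2,
                             nGapColumns = 3, seed = 9)
  prof <- conservationProfile(gp$panel)
  expect_true(any(prof["gap", ] > 0))
})

test_that("candidate enumeration respects core length and difference floor", {
  pl <- plantMarkerAlignment(nTaxa = 8, flankLen = 25, coreLen = 150,
                             minCoreDiffs = 5, seed = 21)
  win <- findConservedWindows(pl$panel, maxMmPerTemplate = 1)
  cand5 <- enumerateCandidates(win, pl$panel, maxCoreLen = 200,
                               minCoreDiffs = 5)
  expect_true(recoversPlanted(cand5, pl$truth))
  cand6 <- enumerateCandidates(win, pl$panel, maxCoreLen = 200,
                               minCoreDiffs = 6)
  expect_identical(nrow(cand6), 0L)   # planted minimum is exactly 5
  # a core longer than the cap excludes the pair
  candShort <- enumerateCandidates(win, pl$panel, maxCoreLen = 100,
                                   minCoreDiffs = 5)
  expect_false(recoversPlanted(candShort, pl$truth))
})

test_that("binding-site search agrees with the brute-force Hamming oracle", {
  set.seed(31)
  for (trial in 1:8) {
    tpl <- randomSeq(400)
    p <- substr(tpl, 151, 172)                 # planted exact forward site
    maxMm <- sample(0:2, 1)
    for (sense in c("forward", "reverse")) {
      prm <- primer("p", p, sense)
      got <- findBindingSites(prm, tpl, maxMm = maxMm)
      want <- bruteBindingSites(p, tpl, maxMm, sense)
      expect_identical(got$start, want$start)
      expect_identical(got$mismatchCount, want$mismatches)
    }
  }
  # degenerate template base matches only a contained primer base
  expect_identical(
    findBindingSites(primer("p", "ACGTACGTAC", "forward"),
                     "TTACGTACGTACTT", maxMm = 0)$start, 3L)
  got <- findBindingSites(primer("p", "ACGTACGTAC", "forward"),
                          "TTACGTRCGTACTT", maxMm = 0)
  expect_identical(got$start, 3L)              # R = {A,G} contains A
  expect_error(findBindingSites(primer("p", "ACGTACGTAC", "forward"),
                                "ACGT", maxMm = -1), "maxMm")
})

test_that("mismatch classification follows the annealed-strand convention", {
  # forward primer base T over plus-strand template C anneals to G -> T:G
  tpl <- paste0("AAAAA", "ACGCACGTACGT", "AAAAA")
  prm <- primer("p", "ACGTACGTACGT", "forward")   # T at offset 4 vs C
  sites <- findBindingSites(prm, tpl, maxMm = 1)
  expect_identical(sites$mismatchCount, 1L)
  d <- sites$mismatchDetail[[1]]
  expect_identical(d$offset, 4L)
  expect_identical(d$primerBase, "T")
  expect_identical(d$annealedBase, "G")
  expect_identical(d$pairingClass, "T:G")
  expect_identical(unname(classifyMismatches(sites)), c(1L, 0L, 0L))
  # empty site list tallies to zeros
  empty <- sites[0, , drop = FALSE]
  expect_identical(unname(classifyMismatches(empty)), c(0L, 0L, 0L))
})

test_that("planted forward-primer mismatches tally 10 wobble + 2 A:C", {
  pl <- eelLikePanel(seed = 1)
  pair <- primerPair(EEL_FWD, EEL_REV)
  fsites <- findBindingSites(forwardPrimer(pair), pl$panel, maxMm = 1)
  expect_identical(nrow(fsites), 19L)
  expect_identical(sum(fsites$mismatchCount == 1L), 12L)
  tally <- classifyMismatches(fsites)
  expect_identical(unname(tally["T:G"]), 10L)
  expect_identical(unname(tally["A:C"]), 2L)
  rsites <- findBindingSites(reversePrimer(pair), pl$panel, maxMm = 1)
  expect_identical(nrow(rsites), 19L)
  expect_true(all(rsites$mismatchCount == 0L))
})

test_that("amplicon extraction returns the inter-primer core", {
  fwd <- "ACGTACGTACGTACGTACGT"
  rev <- "TGCATGCATGCATGCATGCA"
  core <- randomSeq(50)
  tpl <- paste0("GGGGG", fwd, core, revcompStr(rev), "GGGGG")
  pair <- primerPair(fwd, rev, maxCoreLen = 200)
  amp <- extractAmplicons(pair, referencePanel(c(x = tpl)), maxMm = 0)
  expect_identical(unname(amp$cores["x"]), core)
  expect_identical(amp$status$coreLen, 50L)
  # missing reverse site -> reported, not fatal
  tpl2 <- paste0("GGGGG", fwd, core, "GGGGG")
  amp2 <- extractAmplicons(pair, referencePanel(c(x = tpl, y = tpl2)),
                           maxMm = 0)
  expect_identical(amp2$status$status[amp2$status$template == "y"],
                   "no-amplification")
  expect_identical(names(amp2$cores), "x")
  # planted panel: every template amplifies a 167 bp core
  pl <- eelLikePanel(seed = 2)
  amp3 <- extractAmplicons(primerPair(EEL_FWD, EEL_REV), pl$panel, maxMm = 2)
  expect_identical(unname(amp3$status$coreLen), rep(167L, 19L))
  expect_true(all(nchar(amp3$cores) == 167L))
})
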