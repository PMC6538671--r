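# Independent oracles and small fixture builders used across test files.
# These deliberately avoid the package's internal code paths: brute-force
# scans written in a different style, so agreement is evidence.

DNA_BASES <- c("A", "C", "G", "T")

randomSeq <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

revcompStr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

mutateSeq <- function(s, positions) {
  v <- strsplit(s, "")[[1]]
  for (p in positions) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
  paste(v, collapse = "")
}

# Brute-force binding-site oracle: slide the pattern over every start
# position of the plus strand and count literal mismatches.
bruteBindingSites <- function(primerSeq, template, maxMm, sense = "forward") {
  pat <- if (sense == "forward") primerSeq else revcompStr(primerSeq)
  pv <- strsplit(pat, "")[[1]]
  tv <- strsplit(template, "")[[1]]
  L <- length(pv)
  hits <- data.frame(start = integer(), mismatches = integer())
  for (s in seq_len(length(tv) - L + 1)) {
    mm <- sum(pv != tv[s:(s + L - 1)])
    if (mm <= maxMm)
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
  }
  hits
}

# Brute-force merge oracle: score every proper overlap offset of r1 against
# revcomp(r2), maximise matched positions (ties to the longer overlap), and
# apply the same reject rules.
bruteMerge <- function(seq1, seq2, minOverlap, maxDiffs) {
  r2rc <- revcompStr(seq2)
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(r2rc, "")[[1]]
  n1 <- length(a); n2 <- length(b)
  bestScore <- -1; best <- NULL
  for (o in seq(min(n1, n2), minOverlap)) {
    tailA <- a[(n1 - o + 1):n1]
    headB <- b[1:o]
    matches <- sum(tailA == headB)
    if (matches > bestScore) {
      bestScore <- matches
      best <- list(overlap = o, diffs = o - matches)
    }
  }
  if (is.null(best) || best$diffs > maxDiffs) return(NULL)
  list(overlap = best$overlap, diffs = best$diffs,
       seq = paste(c(a[seq_len(n1 - best$overlap)], b), collapse = ""))
}

# Planted eel-like acceptance panel: 19 templates named with three
# subspecies pairs, the benchmark primer pair as flanks, a 167 bp core with
# subspecies separated by 1/3/3 differences, and 12 forward-primer
# mismatches (10 wobble T:G, 2 A:C).
EEL_FWD <- "CTTACAGCAAACCTGACAGCAG"
EEL_REV <- "TTGGTGTGCCATTATACGTTTTCTTG"

eelLikePanel <- function(seed = 1L) {
  nm <- c(sprintf("species%02d", 1:13),
          "speciesA_aus", "speciesA_sch",
          "speciesB_ben", "speciesB_lab",
          "speciesC_bic", "speciesC_pac")
  plantMarkerAlignment(
    nTaxa = 19L, coreLen = 167L, minCoreDiffs = 5L,
    fwdFlank = EEL_FWD, revPrimer = EEL_REV,
    fwdMismatchClasses = c(rep("T:G", 10), rep("A:C", 2)),
    subspeciesPairs = list(list(a = 14, b = 15, diffs = 3),
                           list(a = 16, b = 17, diffs = 1),
                           list(a = 18, b = 19, diffs = 3)),
    taxaNames = nm, seed = seed)
}

# does the candidate list contain the planted marker? (windows may extend
# into conserved neighbours, so containment is the recovery criterion)
recoversPlanted <- function(candidates, truth) {
  any(candidates$fwdStart <= truth$fwdWindow["start"] &
      candidates$fwdEnd >= truth$fwdWindow["end"] &
      candidates$revStart <= truth$revWindow["start"] &
      candidates$revEnd >= truth$revWindow["end"])
}

writeTestFastq <- function(path, ids, seqs, quals) {
  lines <- character()
  for (i in seq_along(ids)) {
    lines <- c(lines, paste0("@", ids[i]), seqs[i], "+",
               rawToChar(as.raw(quals[[i]] + 33L)))
  }
  writeLines(lines, path)
  path
}
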