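#' @include AllClasses.R thermo.R
NULL

#' Per-column base composition of an aligned panel
#'
#' Counts of A, C, G, T, gap and other (ambiguity codes) per alignment
#' column; the WebLogo-style profile used to judge conservation.  Column
#' counts always sum to the number of templates.
#'
#' @param panel an aligned [ReferencePanel-class] with >= 2 records.
#' @return a 6 x L integer matrix with rows `A,C,G,T,gap,other` and
#'   attributes `nTemplates` and `invariant` (logical per column: exactly
#'   one non-gap base carried by every template).
#' @export
conservationProfile <- function(panel) {
  if (!isAligned(panel)) stop("panel must be aligned")
  if (length(panel) < 2L) stop("need at least 2 records")
  cm <- Biostrings::consensusMatrix(panelSeqs(panel))
  L <- ncol(cm)
  get <- function(b) if (b %in% rownames(cm)) cm[b, ] else integer(L)
  prof <- rbind(A = get("A"), C = get("C"), G = get("G"), T = get("T"),
                gap = get("-"))
  prof <- rbind(prof, other = colSums(cm) - colSums(prof))
  storage.mode(prof) <- "integer"
  n <- length(panel)
  attr(prof, "nTemplates") <- n
  attr(prof, "invariant") <- apply(prof[c("A", "C", "G", "T"), , drop = FALSE],
                                   2, max) == n
  prof
}

# Character matrix (templates x columns) of an aligned panel.
.charMatrix <- function(panel) {
  s <- as.character(panelSeqs(panel))
  matrix(unlist(strsplit(s, ""), use.names = FALSE),
         nrow = length(s), byrow = TRUE, dimnames = list(names(s), NULL))
}

# Majority consensus per column over A/C/G/T; ties broken alphabetically
# (equal counts imply equal total mismatches, so the alphabetical base is the
# deterministic representative).  Columns without any A/C/G/T give NA.
.columnConsensus <- function(profile) {
  acgt <- profile[c("A", "C", "G", "T"), , drop = FALSE]
  top <- apply(acgt, 2, function(v)
    if (all(v == 0L)) NA_character_ else rownames(acgt)[which.max(v)])
  top
}

#' Find conserved gap-free windows in an aligned panel
#'
#' A window qualifies when it contains no gap column and its majority
#' consensus differs from *every* template by at most `maxMmPerTemplate`
#' positions (degenerate template bases count as mismatches unless the
#' consensus base lies in their IUPAC set).  Only maximal windows are
#' reported (a qualifying window contained in a longer qualifying window is
#' dropped), ordered widest-first.
#'
#' @param panel aligned [ReferencePanel-class].
#' @param winMin,winMax window width bounds in bp (primer-sized, default
#'   20-30).
#' @param maxMmPerTemplate per-template mismatch budget against the window
#'   consensus (default 1).
#' @param profile optional precomputed [conservationProfile()].
#' @return data.frame with columns `start`, `end`, `width`, `consensus`,
#'   `maxMismatch` (worst template), `nMismatched` (templates with >= 1
#'   mismatch); 1-based closed alignment coordinates.
#' @export
findConservedWindows <- function(panel, winMin = 20L, winMax = 30L,
                                 maxMmPerTemplate = 1L, profile = NULL) {
  if (winMin > winMax) stop("winMin must be <= winMax")
  if (!isAligned(panel)) stop("panel must be aligned")
  if (is.null(profile)) profile <- conservationProfile(panel)
  cons <- .columnConsensus(profile)
  chars <- .charMatrix(panel)
  L <- ncol(chars)
  n <- nrow(chars)
  gapCol <- profile["gap", ] > 0L | is.na(cons)

  # mismatch indicator per template x column against the consensus base
  mm <- matrix(TRUE, n, L)
  for (i in seq_len(n)) {
    same <- chars[i, ] == cons
    amb <- !same & chars[i, ] %in% setdiff(IUPAC_CODES, c("A", "C", "G", "T"))
    if (any(amb)) {
      hit <- vapply(which(amb), function(j)
        .baseMatches(cons[j], chars[i, j]), TRUE)
      same[which(amb)[hit]] <- TRUE
    }
    mm[i, ] <- !same
  }
  mm[, gapCol] <- TRUE    # gap columns can never sit inside a window

  cum <- apply(mm, 1, function(v) cumsum(v))        # L x n
  cum <- rbind(0, cum)
  gapCum <- c(0L, cumsum(gapCol))

  res <- list()
  for (w in seq(winMax, winMin)) {
    if (w > L) next
    starts <- seq_len(L - w + 1L)
    gapIn <- gapCum[starts + w] - gapCum[starts] > 0L
    wsum <- cum[starts + w, , drop = FALSE] - cum[starts, , drop = FALSE]
    ok <- !gapIn & apply(wsum, 1, max) <= maxMmPerTemplate
    for (s in starts[ok]) {
      res[[length(res) + 1L]] <- data.frame(
        start = s, end = s + w - 1L, width = w,
        consensus = paste(cons[s:(s + w - 1L)], collapse = ""),
        maxMismatch = max(wsum[s, ]),
        nMismatched = sum(wsum[s, ] > 0L))
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(), width = integer(),
                      consensus = character(), maxMismatch = integer(),
                      nMismatched = integer()))
  out <- do.call(rbind, res)
  # keep maximal windows only
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    contained <- out$start <= out$start[i] & out$end >= out$end[i] &
      out$width > out$width[i]
    if (any(contained)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$width, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate marker candidates from conserved windows
#'
#' All ordered window pairs whose inter-window core is shorter than
#' `maxCoreLen` bp (ungapped, in every template) and whose minimum pairwise
#' core difference count reaches `minCoreDiffs` become candidates.  The
#' forward primer is the consensus of the left window; the reverse primer is
#' the reverse complement of the consensus of the right window; both carry
#' melting temperature and G/C content.
#'
#' @param windows output of [findConservedWindows()].
#' @param panel the aligned [ReferencePanel-class] the windows came from.
#' @param maxCoreLen maximum ungapped core length, bp (default 200, the
#'   degraded-eDNA amplicon bound).
#' @param minCoreDiffs minimum pairwise nucleotide-difference count the core
#'   must separate every template pair by (default 5).
#' @param thermo [ThermoParams-class] for the primer Tm.
#' @return data.frame of candidates: window and core coordinates, primer
#'   sequences, per-primer Tm and GC, core length range and pairwise
#'   difference summary, ordered by decreasing `minDiffs`.
#' @export
enumerateCandidates <- function(windows, panel, maxCoreLen = 200L,
                                minCoreDiffs = 5L,
                                thermo = thermoParams()) {
  empty <- data.frame(
    fwdStart = integer(), fwdEnd = integer(), revStart = integer(),
    revEnd = integer(), coreStart = integer(), coreEnd = integer(),
    fwdPrimer = character(), revPrimer = character(),
    fwdTm = numeric(), revTm = numeric(), fwdGC = numeric(),
    revGC = numeric(), coreLenMin = integer(), coreLenMax = integer(),
    minDiffs = integer(), meanDiffs = numeric(), maxDiffs = integer())
  if (nrow(windows) < 2L) return(empty)
  chars <- .charMatrix(panel)
  n <- nrow(chars)
  res <- list()
  for (i in seq_len(nrow(windows))) for (j in seq_len(nrow(windows))) {
    if (windows$start[j] - windows$end[i] <= 1L) next
    coreCols <- (windows$end[i] + 1L):(windows$start[j] - 1L)
    sub <- chars[, coreCols, drop = FALSE]
    lens <- rowSums(sub != "-")
    if (any(lens >= maxCoreLen) || any(lens == 0L)) next
    # pairwise difference counts over columns where neither template gapped
    diffs <- matrix(0L, n, n)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      use <- sub[a, ] != "-" & sub[b, ] != "-"
      diffs[a, b] <- sum(sub[a, use] != sub[b, use])
    }
    dv <- diffs[upper.tri(diffs)]
    if (min(dv) < minCoreDiffs) next
    fwdP <- windows$consensus[i]
    revP <- .revcomp(windows$consensus[j])
    res[[length(res) + 1L]] <- data.frame(
      fwdStart = windows$start[i], fwdEnd = windows$end[i],
      revStart = windows$start[j], revEnd = windows$end[j],
      coreStart = windows$end[i] + 1L, coreEnd = windows$start[j] - 1L,
      fwdPrimer = fwdP, revPrimer = revP,
      fwdTm = nnTm(fwdP, thermo), revTm = nnTm(revP, thermo),
      fwdGC = gcContent(fwdP), revGC = gcContent(revP),
      coreLenMin = min(lens), coreLenMax = max(lens),
      minDiffs = min(dv), meanDiffs = mean(dv), maxDiffs = max(dv))
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(-out$minDiffs, out$fwdStart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate primer binding sites on templates
#'
#' Scans the (degapped) plus strand of each template for the primer in both
#' annealing senses, tolerating up to `maxMm` mismatches.  Each mismatch is
#' classified by the base pair formed in the annealed duplex: the primer
#' base pairs with the complement of the plus-strand base for a
#' forward-sense site, and with the plus-strand base directly for a
#' reverse-sense site.  Classes are `T:G` (wobble), `A:C`, or `other`.
#'
#' @param primer a [Primer-class] (or bare sequence, taken as forward).
#' @param templates a [ReferencePanel-class], named character vector, or a
#'   single string.
#' @param maxMm maximum mismatches per site (>= 0).
#' @param orientation which annealing sense to scan: `"auto"` (the primer's
#'   own orientation), `"forward"`, `"reverse"`, or `"both"`.
#' @return data.frame with columns `template`, `start`, `end`,
#'   `orientation`, `mismatchCount` and a list-column `mismatchDetail`
#'   (per-mismatch `offset` in primer 5'->3' coordinates, `primerBase`,
#'   `templateBase` on the plus strand, `annealedBase`, `pairingClass`).
#'   Coordinates are 1-based on the degapped plus strand.
#' @export
findBindingSites <- function(primer, templates, maxMm = 0L,
                             orientation = c("auto", "forward", "reverse",
                                             "both")) {
  orientation <- match.arg(orientation)
  if (maxMm < 0L) stop("maxMm must be >= 0")
  if (is.character(primer))
    primer <- new("Primer", name = "primer", seq = toupper(primer),
                  orientation = "forward", adapter = NA_character_)
  if (is(templates, "ReferencePanel"))
    templates <- as.character(panelSeqs(templates))
  if (is.null(names(templates)))
    names(templates) <- if (length(templates) == 1L) "template"
                        else sprintf("template%d", seq_along(templates))
  senses <- switch(orientation,
                   auto = primer@orientation,
                   both = c("forward", "reverse"),
                   orientation)
  pseq <- primer@seq
  L <- nchar(pseq)
  pbase <- strsplit(pseq, "")[[1]]
  rows <- list()
  for (tid in names(templates)) {
    tpl <- .degap(toupper(templates[[tid]]))
    subj <- Biostrings::DNAString(tpl)
    for (sense in senses) {
      pat <- if (sense == "forward") pseq else .revcomp(pseq)
      hits <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMm,
                                       with.indels = FALSE, fixed = FALSE)
      if (!length(hits)) next
      mmpos <- Biostrings::mismatch(Biostrings::DNAString(pat), hits)
      for (h in seq_along(hits)) {
        s <- BiocGenerics::start(hits)[h]
        pos <- mmpos[[h]]                       # offsets within the pattern
        detail <- if (length(pos)) {
          tplBase <- substring(tpl, s + pos - 1L, s + pos - 1L)
          if (sense == "forward") {
            offset <- pos
            annealed <- .complementBase(tplBase)
          } else {
            offset <- L - pos + 1L
            annealed <- tplBase
          }
          prm <- pbase[offset]
          cls <- vapply(seq_along(pos), function(k) {
            pairset <- sort(c(prm[k], annealed[k]))
            if (identical(pairset, c("G", "T"))) "T:G"
            else if (identical(pairset, c("A", "C"))) "A:C"
            else "other"
          }, "")
          ord <- order(offset)
          data.frame(offset = offset[ord], primerBase = prm[ord],
                     templateBase = tplBase[ord],
                     annealedBase = annealed[ord],
                     pairingClass = cls[ord])
        } else {
          data.frame(offset = integer(), primerBase = character(),
                     templateBase = character(), annealedBase = character(),
                     pairingClass = character())
        }
        rows[[length(rows) + 1L]] <- data.frame(
          template = tid, start = s, end = s + L - 1L, orientation = sense,
          mismatchCount = length(pos),
          mismatchDetail = I(list(detail)))
      }
    }
  }
  if (!length(rows))
    return(data.frame(template = character(), start = integer(),
                      end = integer(), orientation = character(),
                      mismatchCount = integer(),
                      mismatchDetail = I(list())))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally primer-template mismatches by duplex pairing class
#'
#' @param sites output of [findBindingSites()].
#' @return named integer vector with entries `T:G`, `A:C`, `other`.
#' @export
classifyMismatches <- function(sites) {
  tally <- c("T:G" = 0L, "A:C" = 0L, other = 0L)
  for (d in sites$mismatchDetail) {
    if (nrow(d)) {
      t <- table(d$pairingClass)
      tally[names(t)] <- tally[names(t)] + as.integer(t)
    }
  }
  tally
}

#' Extract inter-primer amplicon cores from a panel (in-silico PCR)
#'
#' Locates the forward primer and the reverse primer (as its reverse
#' complement) on the degapped plus strand of each template and returns the
#' inter-primer core (primers excluded).  Templates with zero or multiple
#' compatible site pairs are reported, not fatal.
#'
#' @param pair a [PrimerPair-class].
#' @param panel a [ReferencePanel-class] (aligned panels are degapped
#'   first).
#' @param maxMm per-primer mismatch tolerance (default 1).
#' @return list with `cores` (named character vector of core sequences for
#'   amplified templates, plus-strand orientation) and `status` (data.frame:
#'   `template`, `status` in `amplified|no-amplification|multiple-products`,
#'   `coreLen`, `fwdMismatches`, `revMismatches`).
#' @export
extractAmplicons <- function(pair, panel, maxMm = 1L) {
  tpl <- vapply(as.character(panelSeqs(panel)), .degap, "")
  names(tpl) <- names(panel)
  maxCore <- pair@maxCoreLen
  cores <- character()
  status <- list()
  for (tid in names(tpl)) {
    fsites <- findBindingSites(pair@fwd, setNames(tpl[tid], tid), maxMm,
                               orientation = "forward")
    rsites <- findBindingSites(pair@rev, setNames(tpl[tid], tid), maxMm,
                               orientation = "reverse")
    combos <- list()
    if (nrow(fsites) && nrow(rsites)) {
      for (a in seq_len(nrow(fsites))) for (b in seq_len(nrow(rsites))) {
        coreLen <- rsites$start[b] - fsites$end[a] - 1L
        if (coreLen >= 1L && coreLen <= maxCore)
          combos[[length(combos) + 1L]] <- c(a, b, coreLen)
      }
    }
    if (length(combos) == 1L) {
      a <- combos[[1]][1]; b <- combos[[1]][2]
      core <- substring(tpl[tid], fsites$end[a] + 1L, rsites$start[b] - 1L)
      cores[tid] <- core
      status[[length(status) + 1L]] <- data.frame(
        template = tid, status = "amplified",
        coreLen = combos[[1]][3],
        fwdMismatches = fsites$mismatchCount[a],
        revMismatches = rsites$mismatchCount[b])
    } else {
      status[[length(status) + 1L]] <- data.frame(
        template = tid,
        status = if (length(combos)) "multiple-products"
                 else "no-amplification",
        coreLen = NA_integer_, fwdMismatches = NA_integer_,
        revMismatches = NA_integer_)
    }
  }
  list(cores = cores, status = do.call(rbind, status))
}
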