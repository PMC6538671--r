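#' @include AllClasses.R markerdesign.R
NULL

#' Default thresholds of the read-processing chain
#'
#' One config block holding every stage threshold: quality-tail cutoff
#' Phred 20, best-overlap merging with at most 5 conflicting positions and
#' a 16 bp minimum overlap, primer stripping with up to 2 mismatches per
#' primer, expected-error *rate* filter at 1% with a 120 bp length floor,
#' removal of uniques seen fewer than 4 times (singletons through
#' tripletons), abundance-skew denoising with `alpha = 2`, and a 98.5%
#' assignment identity threshold (two differences tolerated over a ~167 bp
#' core).
#'
#' @param qCutoff Phred score below which the read tail is truncated.
#' @param minOverlap minimum pair overlap, bp.
#' @param maxDiffs maximum conflicting positions tolerated in the overlap.
#' @param stripMaxMm per-primer mismatch tolerance when stripping.
#' @param maxEeRate maximum expected errors per base (rate, not absolute).
#' @param minLen minimum stripped-core length, bp.
#' @param minAbundance minimum copies a unique sequence needs to survive
#'   dereplication.
#' @param alpha abundance-skew steepness of the denoiser.
#' @param minIdentity assignment identity threshold, percent.
#' @return named list of thresholds.
#' @export
pipelineConfig <- function(qCutoff = 20L, minOverlap = 16L, maxDiffs = 5L,
                           stripMaxMm = 2L, maxEeRate = 0.01, minLen = 120L,
                           minAbundance = 4L, alpha = 2, minIdentity = 98.5) {
  list(qCutoff = qCutoff, minOverlap = minOverlap, maxDiffs = maxDiffs,
       stripMaxMm = stripMaxMm, maxEeRate = maxEeRate, minLen = minLen,
       minAbundance = minAbundance, alpha = alpha, minIdentity = minIdentity)
}

#' Truncate a read at its first low-quality base
#'
#' The suffix starting at the first base with Phred below `qCutoff` is
#' removed (the whole read may vanish; downstream stages reject empties).
#'
#' @param seq read sequence.
#' @param qual integer Phred vector, parallel to `seq`.
#' @param qCutoff Phred threshold (default 20).
#' @return list with truncated `seq` and `qual`.
#' @export
truncateTail <- function(seq, qual, qCutoff = 20L) {
  bad <- which(qual < qCutoff)
  if (length(bad)) {
    keep <- bad[1] - 1L
    seq <- substring(seq, 1L, keep)
    qual <- qual[seq_len(keep)]
  }
  list(seq = seq, qual = qual)
}

# score every proper overlap of r1 with revcomp(r2): offset s means
# revcomp(r2) starts at position s of r1, with the overlap fully covering
# the r1 suffix (fragment = r1[1..s-1] + r2rc).
.bestOverlap <- function(r1, r2rc, minOverlap) {
  n1 <- nchar(r1); n2 <- nchar(r2rc)
  if (n1 == 0L || n2 == 0L) return(NULL)
  v1 <- charToRaw(r1); v2 <- charToRaw(r2rc)
  best <- NULL
  for (s in seq_len(n1)) {
    o <- n1 - s + 1L
    if (o < minOverlap || o > n2) next
    diffs <- sum(v1[s:n1] != v2[seq_len(o)])
    matches <- o - diffs
    if (is.null(best) || matches > best$matches ||
        (matches == best$matches && o > best$overlap)) {
      best <- list(offset = s, overlap = o, diffs = diffs,
                   matches = matches)
    }
  }
  best
}

#' Merge a read pair over its best ungapped overlap
#'
#' Scores every proper overlap of the forward read with the
#' reverse-complemented reverse read (fragment = R1 prefix + R2
#' reverse-complement), picks the best-matching one, and rejects the pair
#' when the best overlap is shorter than `minOverlap` or carries more than
#' `maxDiffs` conflicting positions.  At agreeing positions the merged
#' quality is `max(Q1, Q2)`; at conflicts the higher-quality base wins with
#' quality `|Q1 - Q2|`.
#'
#' @param seq1,qual1 forward read (already tail-truncated).
#' @param seq2,qual2 reverse read (as sequenced; reverse-complemented
#'   internally).
#' @param minOverlap minimum acceptable overlap, bp (default 16).
#' @param maxDiffs maximum conflicting overlap positions (default 5).
#' @return list with `seq`, `qual`, `overlapLen`, `overlapDiffs`, or `NULL`
#'   when the pair is rejected.
#' @export
mergePair <- function(seq1, qual1, seq2, qual2, minOverlap = 16L,
                      maxDiffs = 5L) {
  r2rc <- .revcomp(seq2)
  q2r <- rev(qual2)
  best <- .bestOverlap(seq1, r2rc, minOverlap)
  if (is.null(best) || best$diffs > maxDiffs) return(NULL)
  s <- best$offset; o <- best$overlap
  n2 <- nchar(r2rc)
  b1 <- strsplit(seq1, "")[[1]]
  b2 <- strsplit(r2rc, "")[[1]]
  ovBase <- character(o); ovQual <- integer(o)
  for (k in seq_len(o)) {
    i1 <- s + k - 1L
    if (b1[i1] == b2[k]) {
      ovBase[k] <- b1[i1]
      ovQual[k] <- max(qual1[i1], q2r[k])
    } else if (qual1[i1] >= q2r[k]) {
      ovBase[k] <- b1[i1]
      ovQual[k] <- abs(qual1[i1] - q2r[k])
    } else {
      ovBase[k] <- b2[k]
      ovQual[k] <- abs(qual1[i1] - q2r[k])
    }
  }
  seq <- paste0(substring(seq1, 1L, s - 1L), paste(ovBase, collapse = ""),
                if (o < n2) substring(r2rc, o + 1L, n2) else "")
  qual <- c(qual1[seq_len(s - 1L)], ovQual,
            if (o < n2) q2r[(o + 1L):n2] else integer())
  list(seq = seq, qual = qual, overlapLen = o, overlapDiffs = best$diffs)
}

# anchored mismatch count of a primer against a read prefix/suffix
.anchoredMismatches <- function(primerSeq, readPart) {
  if (nchar(readPart) < nchar(primerSeq)) return(Inf)
  pb <- strsplit(primerSeq, "")[[1]]
  rb <- strsplit(readPart, "")[[1]]
  sum(vapply(seq_along(pb), function(k) {
    if (pb[k] == rb[k]) FALSE
    else !.baseMatches(pb[k], rb[k]) && !.baseMatches(rb[k], pb[k])
  }, TRUE))
}

#' Strip primer sequences off a merged read
#'
#' The forward primer must sit at the 5' end and the reverse complement of
#' the reverse primer at the 3' end, each within `maxMm` mismatches; the
#' inter-primer core (with its qualities) is returned, otherwise the read
#' is rejected.
#'
#' @param seq,qual merged read.
#' @param pair a [PrimerPair-class].
#' @param maxMm per-primer mismatch tolerance (default 2; primer-region
#'   sequencing errors should not discard reads).
#' @return list with core `seq` and `qual`, or `NULL` when either primer is
#'   missing.
#' @export
stripPrimers <- function(seq, qual, pair, maxMm = 2L) {
  fwd <- primerSeq(forwardPrimer(pair))
  revrc <- .revcomp(primerSeq(reversePrimer(pair)))
  lf <- nchar(fwd); lr <- nchar(revrc); n <- nchar(seq)
  if (n < lf + lr + 1L) return(NULL)
  if (.anchoredMismatches(fwd, substring(seq, 1L, lf)) > maxMm) return(NULL)
  if (.anchoredMismatches(revrc, substring(seq, n - lr + 1L, n)) > maxMm)
    return(NULL)
  list(seq = substring(seq, lf + 1L, n - lr),
       qual = qual[(lf + 1L):(n - lr)])
}

#' Expected-error rate filter
#'
#' Keeps a core iff its expected number of errors per base
#' (`sum(10^(-Q/10)) / length`) does not exceed `maxEeRate` and its length
#' reaches `minLen`.  The boundary is kept: a read at exactly the rate
#' passes.
#'
#' @param qual integer Phred vector of the stripped core.
#' @param maxEeRate maximum expected-error rate (default 0.01).
#' @param minLen minimum length, bp (default 120).
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
eeFilter <- function(qual, maxEeRate = 0.01, minLen = 120L) {
  n <- length(qual)
  if (n < minLen) return(FALSE)
  sum(.phredToErr(qual)) / n <= maxEeRate
}

#' Dereplicate cores and drop low-abundance uniques
#'
#' Exact-sequence grouping sorted by descending abundance (ties broken
#' lexicographically); uniques with abundance below `minAbundance` (by
#' default singletons, doubletons and tripletons) are removed.
#'
#' @param seqs character vector of quality-filtered cores.
#' @param minAbundance minimum copies to survive (default 4).
#' @return data.frame with `seq` and `abundance`, carrying attributes
#'   `totalInput` (reads in) and `dropped` (reads removed with rare
#'   uniques).
#' @export
dereplicate <- function(seqs, minAbundance = 4L) {
  if (!length(seqs)) {
    out <- data.frame(seq = character(), abundance = integer())
    attr(out, "totalInput") <- 0L
    attr(out, "dropped") <- 0L
    return(out)
  }
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), abundance = as.integer(tab))
  out <- out[order(-out$abundance, out$seq), , drop = FALSE]
  keep <- out$abundance >= minAbundance
  dropped <- sum(out$abundance[!keep])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totalInput") <- length(seqs)
  attr(out, "dropped") <- as.integer(dropped)
  out
}

# Hamming distance for equal lengths, Levenshtein otherwise.
.seqDist <- function(a, b) {
  if (nchar(a) == nchar(b))
    sum(charToRaw(a) != charToRaw(b))
  else
    as.integer(utils::adist(a, b))
}

#' Denoise dereplicated uniques by abundance skew
#'
#' Greedy centroid clustering: uniques are processed in order of decreasing
#' abundance; a unique `u` is merged into an existing centroid `c` when its
#' abundance skew `abund_u / abund_c` does not exceed
#' `1 / 2^(alpha * d(u, c) + 1)` for `d` the (Hamming or edit) distance;
#' otherwise `u` founds a new centroid.  Merged abundances are pooled into
#' the centroid.  Among several qualifying centroids the closest wins, ties
#' going to the more abundant.
#'
#' @param uniques data.frame from [dereplicate()] (`seq`, `abundance`,
#'   sorted by descending abundance).
#' @param alpha skew steepness (default 2).
#' @return data.frame of centroids with pooled `abundance`, descending.
#' @export
denoise <- function(uniques, alpha = 2) {
  if (!nrow(uniques))
    return(data.frame(seq = character(), abundance = integer()))
  cseq <- character(); cab <- integer(); pooled <- integer()
  for (i in seq_len(nrow(uniques))) {
    u <- uniques$seq[i]; au <- uniques$abundance[i]
    merged <- FALSE
    if (length(cseq)) {
      d <- vapply(cseq, .seqDist, 0L, b = u)
      beta <- 1 / 2^(alpha * d + 1)
      ok <- which(au / cab <= beta)
      if (length(ok)) {
        pick <- ok[order(d[ok], -cab[ok])][1]
        pooled[pick] <- pooled[pick] + au
        merged <- TRUE
      }
    }
    if (!merged) {
      cseq <- c(cseq, u); cab <- c(cab, au); pooled <- c(pooled, au)
    }
  }
  out <- data.frame(seq = cseq, abundance = pooled)
  out <- out[order(-out$abundance, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# identity (percent) between a query and a reference: ungapped Hamming
# identity for equal lengths, otherwise end-gap-free global alignment with
# matches over alignment columns (terminal end-gaps excluded, internal gaps
# counted in the denominator).
.identityPct <- function(query, ref) {
  if (nchar(query) == nchar(ref)) {
    100 * sum(charToRaw(query) == charToRaw(ref)) / nchar(ref)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix =
        Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1)
    p <- as.character(Biostrings::alignedPattern(aln))
    s <- as.character(Biostrings::alignedSubject(aln))
    cols <- nchar(p)
    if (cols == 0L) return(0)
    100 * sum(charToRaw(p) == charToRaw(s)) / cols
  }
}

#' Assign denoised centroids to reference taxa at an identity threshold
#'
#' Each centroid is compared with every reference amplicon; it is assigned
#' to the best-identity reference iff that identity reaches `minIdentity`.
#' When several references tie at the top score, the centroid is assigned
#' only if all tied references carry the same taxon label; otherwise it is
#' counted as unassigned (ambiguous).  The result is invariant under
#' permutation of the reference set.
#'
#' @param centroids data.frame from [denoise()].
#' @param refdb a [ReferencePanel-class] of reference amplicons with taxon
#'   labels.
#' @param minIdentity identity threshold, percent (default 98.5).
#' @return named numeric vector of abundances per taxon plus `unassigned`.
#' @export
assignReads <- function(centroids, refdb, minIdentity = 98.5) {
  if (length(refdb) == 0L) stop("empty reference set")
  refSeq <- vapply(as.character(panelSeqs(refdb)), .degap, "")
  taxa <- panelTaxa(refdb)
  taxa[is.na(taxa)] <- names(refdb)[is.na(taxa)]
  counts <- setNames(numeric(length(unique(taxa)) + 1L),
                     c(sort(unique(unname(taxa))), "unassigned"))
  for (i in seq_len(nrow(centroids))) {
    ids <- vapply(refSeq, .identityPct, 0, query = centroids$seq[i])
    top <- max(ids)
    if (top >= minIdentity) {
      tied <- unique(unname(taxa[names(refSeq)[ids >= top - 1e-9]]))
      if (length(tied) == 1L)
        counts[tied] <- counts[tied] + centroids$abundance[i]
      else
        counts["unassigned"] <- counts["unassigned"] + centroids$abundance[i]
    } else {
      counts["unassigned"] <- counts["unassigned"] + centroids$abundance[i]
    }
  }
  counts
}

#' Run the six-step read-processing chain over samples
#'
#' Applies, per sample: (1) quality-tail truncation and best-overlap pair
#' merging, (2) primer stripping, (3) expected-error-rate and length
#' filtering, (4) dereplication with rare-unique removal, (5)
#' abundance-skew denoising, (6) identity-threshold taxonomic assignment —
#' and tabulates read abundances per taxon and sample.  Any reads surviving
#' to the table in a declared blank sample mark the whole run as
#' contaminated.
#'
#' @param samples named list; each element is either
#'   `list(r1 = path, r2 = path)` (FASTQ files) or the list returned by
#'   [readFastqPairs()].
#' @param pair the [PrimerPair-class] that generated the amplicons.
#' @param refdb [ReferencePanel-class] of reference amplicon cores with
#'   taxon labels.
#' @param config threshold block from [pipelineConfig()].
#' @param blanks sample names that are no-template controls.
#' @return an [AssignmentResult-class]; see [assignmentCounts()],
#'   [stageLog()], [isContaminated()].
#' @export
runPipeline <- function(samples, pair, refdb, config = pipelineConfig(),
                        blanks = character()) {
  stopifnot(!is.null(names(samples)), all(nzchar(names(samples))))
  badBlank <- setdiff(blanks, names(samples))
  if (length(badBlank))
    stop("blank sample(s) not in input: ", paste(badBlank, collapse = ", "))
  taxa <- panelTaxa(refdb)
  taxa[is.na(taxa)] <- names(refdb)[is.na(taxa)]
  taxaLevels <- c(sort(unique(unname(taxa))), "unassigned")
  counts <- matrix(0, nrow = length(taxaLevels), ncol = length(samples),
                   dimnames = list(taxaLevels, names(samples)))
  logRows <- list()
  for (sm in names(samples)) {
    x <- samples[[sm]]
    if (!is.null(x$r1) && is.character(x$r1)) x <- readFastqPairs(x$r1, x$r2)
    d1 <- .decodeReads(x$r1); d2 <- .decodeReads(x$r2)
    nIn <- length(d1$seq)
    merged <- list(); nMerged <- 0L
    for (i in seq_len(nIn)) {
      t1 <- truncateTail(d1$seq[i], d1$qual[[i]], config$qCutoff)
      t2 <- truncateTail(d2$seq[i], d2$qual[[i]], config$qCutoff)
      if (!nchar(t1$seq) || !nchar(t2$seq)) next
      m <- mergePair(t1$seq, t1$qual, t2$seq, t2$qual,
                     minOverlap = config$minOverlap,
                     maxDiffs = config$maxDiffs)
      if (!is.null(m)) { merged[[length(merged) + 1L]] <- m }
    }
    nMerged <- length(merged)
    stripped <- list()
    for (m in merged) {
      s <- stripPrimers(m$seq, m$qual, pair, maxMm = config$stripMaxMm)
      if (!is.null(s)) stripped[[length(stripped) + 1L]] <- s
    }
    nStripped <- length(stripped)
    keptCores <- character()
    for (s in stripped)
      if (eeFilter(s$qual, config$maxEeRate, config$minLen))
        keptCores <- c(keptCores, s$seq)
    nFiltered <- length(keptCores)
    uniq <- dereplicate(keptCores, minAbundance = config$minAbundance)
    nDerep <- sum(uniq$abundance)
    cent <- denoise(uniq, alpha = config$alpha)
    nDenoised <- sum(cent$abundance)
    if (nrow(cent)) {
      asg <- assignReads(cent, refdb, minIdentity = config$minIdentity)
      counts[names(asg), sm] <- asg
    }
    logRows[[sm]] <- data.frame(
      sample = sm, input = nIn, merged = nMerged, stripped = nStripped,
      filtered = nFiltered, rareDropped = attr(uniq, "dropped"),
      dereplicated = nDerep, denoised = nDenoised,
      assigned = as.integer(
        sum(counts[setdiff(taxaLevels, "unassigned"), sm])),
      unassigned = as.integer(counts["unassigned", sm]))
  }
  stage <- do.call(rbind, logRows)
  rownames(stage) <- NULL
  contaminated <- length(blanks) > 0L &&
    any(colSums(counts)[blanks] > 0)
  new("AssignmentResult", counts = counts, stageLog = stage,
      blanks = as.character(blanks), contaminated = contaminated)
}
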