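#' @include AllClasses.R markerdesign.R seqio.R
NULL

# pick template plus-strand bases that create a requested duplex mismatch
# class against a primer base (forward sense: primer pairs the complement of
# the plus strand; reverse sense: primer pairs the plus strand directly).
.mismatchTemplateBase <- function(primerBase, class, sense = "forward") {
  want <- switch(class,
                 "T:G" = c(T = "G", G = "T"),
                 "A:C" = c(A = "C", C = "A"),
                 stop("unsupported mismatch class: ", class))
  partner <- want[primerBase]
  if (is.na(partner)) return(NA_character_)
  if (sense == "forward") .complementBase(partner) else partner
}

#' Plant a marker architecture into a synthetic alignment
#'
#' Generates an aligned panel with the conserved-flank / variable-core
#' architecture a marker scan looks for: two gap-free conserved windows
#' (optionally fixed to a given primer pair) around a core whose minimum
#' pairwise difference count equals `minCoreDiffs` exactly, embedded in
#' divergent background.  Selected templates can carry a single planted
#' forward-primer mismatch of a chosen duplex class (T:G wobble or A:C),
#' and designated template pairs can be made near-identical "subspecies"
#' differing by a fixed small number of core positions.
#'
#' @param nTaxa number of templates (default 19).
#' @param flankLen conserved window width when no primer is supplied
#'   (default 25, within the primer-sized 20-30 bp band).
#' @param coreLen variable core length, bp (< 200; default 167).
#' @param minCoreDiffs exact minimum pairwise core difference count
#'   (default 5).
#' @param fwdFlank optional plus-strand consensus of the forward window
#'   (e.g. a forward primer sequence).
#' @param revPrimer optional reverse primer 5'->3'; the reverse window
#'   consensus is its reverse complement.
#' @param fwdMismatchClasses character vector of duplex classes (`"T:G"`,
#'   `"A:C"`), one per template that should carry a single forward-window
#'   mismatch; assigned to templates 2, 3, ... in order.
#' @param subspeciesPairs list of `list(a=, b=, diffs=)` (template indices):
#'   template `b`'s core is rewritten as template `a`'s plus `diffs` fresh
#'   substitutions.
#' @param backgroundLen total background flanking the marker, bp (default
#'   120, split evenly).
#' @param divergence per-base probability that a background position
#'   deviates from the background consensus in a template (default 0.2).
#' @param nGapColumns number of background columns given a gap in one
#'   template (default 0).
#' @param taxaNames optional template ids.
#' @param seed RNG seed; identical inputs give identical panels.
#' @return list with `panel` (a [ReferencePanel-class]) and `truth`:
#'   window/core coordinates (1-based alignment columns), the implied
#'   primer pair, the per-template mismatch plan, and the planted minimum
#'   core difference count.
#' @export
plantMarkerAlignment <- function(nTaxa = 19L, flankLen = 25L, coreLen = 167L,
                                 minCoreDiffs = 5L, fwdFlank = NULL,
                                 revPrimer = NULL,
                                 fwdMismatchClasses = character(),
                                 subspeciesPairs = list(),
                                 backgroundLen = 120L, divergence = 0.2,
                                 nGapColumns = 0L, taxaNames = NULL,
                                 seed = 1L) {
  if (coreLen >= 200L) stop("coreLen must be < 200")
  if (minCoreDiffs < 1L || minCoreDiffs > coreLen)
    stop("infeasible spec: need 1 <= minCoreDiffs <= coreLen")
  if (length(fwdMismatchClasses) > nTaxa - 1L)
    stop("more mismatch classes than available templates")
  subsB <- vapply(subspeciesPairs, function(p) as.integer(p$b), 0L)
  nPrivate <- nTaxa - 1L - length(subsB)
  needed <- nPrivate * minCoreDiffs +
    sum(vapply(subspeciesPairs, function(p) as.integer(p$diffs), 0L))
  if (needed > coreLen)
    stop("infeasible spec: core too short for the requested differences")
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    if (is.null(fwdFlank)) fwdFlank <- .randomDna(1L, flankLen)
    fwdFlank <- toupper(fwdFlank)
    if (is.null(revPrimer)) {
      revWindow <- .randomDna(1L, flankLen)
    } else {
      revWindow <- .revcomp(toupper(revPrimer))
    }
    lf <- nchar(fwdFlank); lr <- nchar(revWindow)
    bg1 <- floor(backgroundLen / 2); bg2 <- backgroundLen - bg1
    bgCons <- .randomDna(1L, backgroundLen)
    coreCons <- strsplit(.randomDna(1L, coreLen), "")[[1]]

    if (is.null(taxaNames)) taxaNames <- sprintf("taxon%02d", seq_len(nTaxa))
    stopifnot(length(taxaNames) == nTaxa)

    # core per template: template 1 is the consensus; the rest get
    # minCoreDiffs private substitutions at globally disjoint positions, so
    # the pairwise minimum is hit exactly by (template1, template_i) pairs.
    # Core-edge columns are kept mutation-free: conserved windows may
    # legitimately extend a few columns into a conserved core boundary, and
    # an eroded core must still retain every planted difference.
    edge <- max(0L, min(10L, (coreLen - needed) %/% 2L))
    inner <- (edge + 1L):(coreLen - edge)
    pool <- sample(inner, length(inner))
    take <- function(k) { p <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; p }
    cores <- vector("list", nTaxa)
    cores[[1]] <- coreCons
    for (i in setdiff(2:nTaxa, subsB)) {
      v <- coreCons
      for (p in take(minCoreDiffs))
        v[p] <- sample(setdiff(bases, v[p]), 1L)
      cores[[i]] <- v
    }
    for (sp in subspeciesPairs) {
      v <- cores[[as.integer(sp$a)]]
      if (is.null(v)) stop("subspecies pair references an unset template")
      for (p in take(as.integer(sp$diffs)))
        v[p] <- sample(setdiff(bases, v[p]), 1L)
      cores[[as.integer(sp$b)]] <- v
    }

    # forward-window mismatches: cycle over primer positions that support
    # each class, never letting one column collect a majority of mutants
    fwdBases <- strsplit(fwdFlank, "")[[1]]
    plan <- data.frame(taxon = character(), position = integer(),
                       class = character(), templateBase = character())
    flanks <- matrix(rep(fwdBases, nTaxa), nrow = nTaxa, byrow = TRUE)
    if (length(fwdMismatchClasses)) {
      carriers <- 2:(1L + length(fwdMismatchClasses))
      for (k in seq_along(fwdMismatchClasses)) {
        cls <- fwdMismatchClasses[k]
        ok <- which(!is.na(vapply(fwdBases, .mismatchTemplateBase, "",
                                  class = cls)))
        if (!length(ok))
          stop("forward window cannot host a ", cls, " mismatch")
        posUse <- ok[(k - 1L) %% length(ok) + 1L]
        tb <- .mismatchTemplateBase(fwdBases[posUse], cls)
        i <- carriers[k]
        flanks[i, posUse] <- tb
        plan <- rbind(plan, data.frame(
          taxon = taxaNames[i], position = posUse, class = cls,
          templateBase = tb))
      }
      colTally <- table(plan$position)
      if (any(colTally > floor((nTaxa - 1) / 2)))
        stop("mismatch plan would overturn the window consensus")
    }

    seqs <- character(nTaxa)
    for (i in seq_len(nTaxa)) {
      bg <- strsplit(bgCons, "")[[1]]
      mut <- runif(backgroundLen) < divergence
      bg[mut] <- vapply(bg[mut], function(b)
        sample(setdiff(bases, b), 1L), "")
      seqs[i] <- paste0(
        paste(bg[seq_len(bg1)], collapse = ""),
        paste(flanks[i, ], collapse = ""),
        paste(cores[[i]], collapse = ""),
        revWindow,
        paste(bg[(bg1 + 1L):backgroundLen], collapse = ""))
    }
    if (nGapColumns > 0L) {
      gapCols <- sample.int(bg1, min(nGapColumns, bg1))
      for (g in gapCols) {
        i <- sample.int(nTaxa, 1L)
        substr(seqs[i], g, g) <- "-"
      }
    }
    names(seqs) <- taxaNames
    panel <- referencePanel(seqs, taxon = setNames(taxaNames, taxaNames))
    truth <- list(
      fwdWindow = c(start = bg1 + 1L, end = bg1 + lf),
      core = c(start = bg1 + lf + 1L, end = bg1 + lf + coreLen),
      revWindow = c(start = bg1 + lf + coreLen + 1L,
                    end = bg1 + lf + coreLen + lr),
      fwdPrimer = fwdFlank,
      revPrimer = .revcomp(revWindow),
      minCoreDiffs = if (length(subspeciesPairs))
        min(minCoreDiffs,
            min(vapply(subspeciesPairs, function(p)
              as.integer(p$diffs), 0L)))
      else minCoreDiffs,
      mismatchPlan = plan)
    list(panel = panel, truth = truth)
  })
}

#' Simulate mock-community paired-end amplicon reads
#'
#' Draws read pairs from the per-template amplification fragment
#' (forward primer + core + reverse-complemented reverse primer) under a
#' Phred-governed substitution error model: per-base qualities are drawn
#' from a clipped normal and each base is substituted with probability
#' `10^(-Q/10)`.  Per-template read counts are scaled by
#' `pcrBias^(primer mismatch count)` before rounding, emulating
#' amplification dropout from primer-template mismatches.
#'
#' @param composition named numeric vector: reads requested per template id
#'   (panel record ids); may be empty for a blank.
#' @param pair the [PrimerPair-class] used for amplification.
#' @param panel the reference panel (aligned panels are degapped).
#' @param readLen read length, bp (default 150, clipped to the fragment).
#' @param meanQ,sdQ quality profile; normal mean/sd, clipped to `[2, 40]`
#'   (default 35/3, a typical 2 x 150 bp benchtop profile).
#' @param pcrBias per-mismatch amplification efficiency multiplier in
#'   `(0, 1]` (default 1 = no bias).
#' @param contamination optional named vector of extra reads per template
#'   (no bias applied), emulating stray laboratory DNA.
#' @param errorModel `"phred"` (substitutions at the Phred-implied rate) or
#'   `"none"` (error-free reads; qualities still drawn).
#' @param ampMaxMm mismatch tolerance used when locating the amplicons.
#' @param seed RNG seed; identical inputs give identical reads.
#' @param sampleName sample id used in read names.
#' @param outDir if given, R1/R2 FASTQ, the reference core FASTA, the
#'   taxonomy TSV and the truth TSV are written there.
#' @return list with `r1`, `r2` (`QualityScaledDNAStringSet`), `truth`
#'   (data.frame: `template`, `taxon`, `requested`, `generated`,
#'   `contaminant`), and `paths` when `outDir` was given.
#' @export
simulateMockReads <- function(composition, pair, panel, readLen = 150L,
                              meanQ = 35, sdQ = 3, pcrBias = 1,
                              contamination = NULL,
                              errorModel = c("phred", "none"),
                              ampMaxMm = 2L, seed = 1L, sampleName = "sample1",
                              outDir = NULL) {
  errorModel <- match.arg(errorModel)
  if (pcrBias <= 0 || pcrBias > 1) stop("pcrBias must be in (0, 1]")
  amp <- extractAmplicons(pair, panel, maxMm = ampMaxMm)
  wanted <- union(names(composition), names(contamination))
  bad <- setdiff(wanted, names(amp$cores))
  if (length(bad))
    stop("unamplifiable template(s) in composition: ",
         paste(bad, collapse = ", "))
  fwd <- primerSeq(forwardPrimer(pair))
  revrc <- .revcomp(primerSeq(reversePrimer(pair)))
  frag <- setNames(paste0(fwd, amp$cores[wanted], revrc), wanted)
  mmCount <- setNames(
    amp$status$fwdMismatches + amp$status$revMismatches,
    amp$status$template)
  taxa <- panelTaxa(panel)
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    seqs1 <- character(); quals1 <- list()
    seqs2 <- character(); quals2 <- list()
    ids <- character()
    truth <- list()
    oneRead <- function(tpl) {
      n <- nchar(tpl)
      rl <- min(readLen, n)
      q <- pmin(pmax(round(rnorm(rl, meanQ, sdQ)), 2L), 40L)
      b <- strsplit(substring(tpl, 1L, rl), "")[[1]]
      if (errorModel == "phred") {
        err <- runif(rl) < .phredToErr(q)
        if (any(err))
          b[err] <- vapply(b[err], function(x)
            sample(setdiff(bases, x), 1L), "")
      }
      list(seq = paste(b, collapse = ""), qual = as.integer(q))
    }
    emit <- function(tid, n, contaminant) {
      f <- frag[[tid]]
      frc <- .revcomp(f)
      gen <- 0L
      for (i in seq_len(n)) {
        r1 <- oneRead(f)
        r2 <- oneRead(frc)
        idx <- length(ids) + 1L
        ids[idx] <<- sprintf("%s_%s_%05d%s", sampleName, tid, i,
                             if (contaminant) "_contam" else "")
        seqs1[idx] <<- r1$seq; quals1[[idx]] <<- r1$qual
        seqs2[idx] <<- r2$seq; quals2[[idx]] <<- r2$qual
        gen <- gen + 1L
      }
      gen
    }
    for (tid in names(composition)) {
      req <- composition[[tid]]
      n <- as.integer(round(req * pcrBias^mmCount[[tid]]))
      gen <- if (n > 0L) emit(tid, n, FALSE) else 0L
      truth[[length(truth) + 1L]] <- data.frame(
        template = tid, taxon = unname(taxa[tid]), requested = req,
        generated = gen, contaminant = FALSE)
    }
    for (tid in names(contamination)) {
      n <- as.integer(contamination[[tid]])
      gen <- if (n > 0L) emit(tid, n, TRUE) else 0L
      truth[[length(truth) + 1L]] <- data.frame(
        template = tid, taxon = unname(taxa[tid]), requested = n,
        generated = gen, contaminant = TRUE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(template = character(), taxon = character(),
                 requested = numeric(), generated = integer(),
                 contaminant = logical())
    r1 <- .encodeReads(seqs1, quals1, ids)
    r2 <- .encodeReads(seqs2, quals2, ids)
    out <- list(r1 = r1, r2 = r2, truth = truth)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      p <- list(
        r1 = file.path(outDir, paste0(sampleName, "_R1.fastq")),
        r2 = file.path(outDir, paste0(sampleName, "_R2.fastq")),
        refs = file.path(outDir, "reference_cores.fasta"),
        taxonomy = file.path(outDir, "taxonomy.tsv"),
        truth = file.path(outDir, paste0(sampleName, "_truth.tsv")))
      writeFastqPairs(r1, r2, p$r1, p$r2)
      writeFasta(amp$cores, p$refs)
      tt <- data.frame(id = names(amp$cores),
                       taxon = unname(taxa[names(amp$cores)]))
      write.table(tt, p$taxonomy, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(truth, p$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- p
    }
    out
  })
}
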