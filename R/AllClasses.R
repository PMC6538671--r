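#' @include utils.R
NULL

# ---------------------------------------------------------------- Primer ----

#' Primer oligo
#'
#' An adapter-free oligonucleotide written 5'→3' with its binding
#' orientation.  The optional `adapter` slot carries a 5' tail (sequencing
#' adapter) that is never part of binding-site arithmetic.
#'
#' @slot name single character identifier.
#' @slot seq 5'→3' sequence, length >= 10, IUPAC codes, no gaps.
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot adapter optional 5' tail (`NA_character_` if absent).
#' @exportClass Primer
setClass("Primer", representation(
  name = "character", seq = "character",
  orientation = "character", adapter = "character"
))

setValidity("Primer", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@seq) != 1L || nchar(object@seq) < 10L)
    msg <- c(msg, "seq must be a single string of length >= 10")
  else {
    bad <- tryCatch({ .checkDna(object@seq, "primer seq"); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(bad)) msg <- c(msg, bad)
  }
  if (!identical(length(object@orientation), 1L) ||
      !object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(msg)) msg else TRUE
})

#' Construct a [Primer-class] object
#'
#' @param name identifier.
#' @param seq 5'→3' sequence (adapter-free).
#' @param orientation `"forward"` or `"reverse"`.
#' @param adapter optional 5' adapter tail.
#' @return a `Primer` object.
#' @examples
#' primer("eelF", "CTTACAGCAAACCTGACAGCAG", "forward")
#' @export
primer <- function(name, seq, orientation = c("forward", "reverse"),
                   adapter = NA_character_) {
  orientation <- match.arg(orientation)
  new("Primer", name = name, seq = toupper(seq), orientation = orientation,
      adapter = adapter)
}

#' @describeIn primer primer sequence accessor
#' @param x a `Primer`.
#' @export
primerSeq <- function(x) x@seq

#' @describeIn primer orientation accessor
#' @export
primerOrientation <- function(x) x@orientation

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s (%s): 5'-%s-3' (%d nt)\n", object@name,
              object@orientation, object@seq, nchar(object@seq)))
})

# ------------------------------------------------------------ PrimerPair ----

#' Primer pair
#'
#' A forward/reverse oligo pair defining a marker, with the maximum length
#' allowed for the inter-primer variable core.
#'
#' @slot fwd forward [Primer-class].
#' @slot rev reverse [Primer-class].
#' @slot maxCoreLen maximum inter-primer core length in bp (default 200;
#'   degraded eDNA favours short amplicons).
#' @exportClass PrimerPair
setClass("PrimerPair", representation(
  fwd = "Primer", rev = "Primer", maxCoreLen = "integer"
))

setValidity("PrimerPair", function(object) {
  msg <- character()
  if (object@fwd@orientation != "forward")
    msg <- c(msg, "fwd must have orientation 'forward'")
  if (object@rev@orientation != "reverse")
    msg <- c(msg, "rev must have orientation 'reverse'")
  if (length(object@maxCoreLen) != 1L || object@maxCoreLen < 1L)
    msg <- c(msg, "maxCoreLen must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a [PrimerPair-class]
#'
#' @param fwd forward [Primer-class] (or sequence string).
#' @param rev reverse [Primer-class] (or sequence string).
#' @param maxCoreLen maximum inter-primer core length (bp).
#' @param name stem used when bare sequences are given.
#' @return a `PrimerPair`.
#' @export
primerPair <- function(fwd, rev, maxCoreLen = 200L, name = "pair") {
  if (is.character(fwd)) fwd <- primer(paste0(name, "-F"), fwd, "forward")
  if (is.character(rev)) rev <- primer(paste0(name, "-R"), rev, "reverse")
  new("PrimerPair", fwd = fwd, rev = rev, maxCoreLen = as.integer(maxCoreLen))
}

#' @describeIn primerPair forward primer accessor
#' @param x a `PrimerPair`.
#' @export
forwardPrimer <- function(x) x@fwd

#' @describeIn primerPair reverse primer accessor
#' @export
reversePrimer <- function(x) x@rev

setMethod("show", "PrimerPair", function(object) {
  cat("PrimerPair (maxCoreLen =", object@maxCoreLen, "bp)\n")
  show(object@fwd); show(object@rev)
})

# -------------------------------------------------------- ReferencePanel ----

#' Reference sequence panel
#'
#' A set of reference sequences (aligned or not) with optional taxon labels,
#' the central input of marker design and assignment.  Wraps a
#' [Biostrings::DNAStringSet].
#'
#' @slot seqs `DNAStringSet`, named by unique record ids.
#' @slot taxon character vector parallel to `seqs` (`NA` where unknown).
#' @slot aligned `TRUE` iff all sequences have equal length (gapped
#'   alignment coordinates apply).
#' @exportClass ReferencePanel
setClass("ReferencePanel", representation(
  seqs = "DNAStringSet", taxon = "character", aligned = "logical"
))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all records must have non-empty ids")
  else if (anyDuplicated(ids))
    msg <- c(msg, "record ids must be unique")
  if (length(object@taxon) != length(object@seqs))
    msg <- c(msg, "taxon must be parallel to seqs")
  if (any(BiocGenerics::width(object@seqs) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  w <- BiocGenerics::width(object@seqs)
  if (isTRUE(object@aligned) && length(unique(w)) > 1L)
    msg <- c(msg, "aligned panel must have equal-length sequences")
  if (length(msg)) msg else TRUE
})

#' Construct a [ReferencePanel-class]
#'
#' @param seqs named character vector or `DNAStringSet`.  The gap character
#'   is `-` only; `.` is rejected.
#' @param taxon optional taxon labels (named by id, or parallel vector).
#' @return a `ReferencePanel`; `aligned` is set iff all lengths are equal.
#' @export
referencePanel <- function(seqs, taxon = NULL) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("seqs must be named by record id")
    seqs <- toupper(seqs)
    for (i in seq_along(seqs))
      .checkDna(seqs[[i]], paste0("record '", names(seqs)[i], "'"),
                allowGaps = TRUE)
    seqs <- Biostrings::DNAStringSet(seqs)
  } else {
    seqs <- Biostrings::DNAStringSet(seqs)
    letters <- Biostrings::uniqueLetters(seqs)
    bad <- setdiff(letters, c(IUPAC_CODES, "-"))
    if (length(bad))
      stop("invalid characters in sequences: ",
           paste(sQuote(bad), collapse = ", "),
           " (gap character is '-' only)")
  }
  n <- length(seqs)
  tax <- rep(NA_character_, n)
  if (!is.null(taxon)) {
    if (!is.null(names(taxon))) {
      missing <- setdiff(names(taxon), names(seqs))
      if (length(missing))
        stop("taxonomy ids absent from panel: ",
             paste(sQuote(missing), collapse = ", "))
      tax[match(names(taxon), names(seqs))] <- unname(taxon)
    } else {
      if (length(taxon) != n)
        stop("unnamed taxon vector must be parallel to seqs")
      tax <- as.character(taxon)
    }
  }
  aligned <- length(unique(BiocGenerics::width(seqs))) == 1L && n > 0L
  new("ReferencePanel", seqs = seqs, taxon = tax, aligned = aligned)
}

#' @describeIn referencePanel the underlying `DNAStringSet`
#' @param x a `ReferencePanel`.
#' @export
panelSeqs <- function(x) x@seqs

#' @describeIn referencePanel taxon labels, named by record id
#' @export
panelTaxa <- function(x) setNames(x@taxon, names(x@seqs))

#' @describeIn referencePanel is the panel aligned?
#' @export
isAligned <- function(x) x@aligned

setMethod("length", "ReferencePanel", function(x) length(x@seqs))

setMethod("names", "ReferencePanel", function(x) names(x@seqs))

setMethod("[", "ReferencePanel", function(x, i, j, ..., drop = TRUE) {
  referencePanel(as.character(x@seqs[i]), taxon = x@taxon[i])
})

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d records, %s\n", length(object@seqs),
              if (object@aligned)
                sprintf("aligned (%d columns)",
                        BiocGenerics::width(object@seqs)[1])
              else "unaligned"))
  ntax <- sum(!is.na(object@taxon))
  cat(sprintf("  taxon labels: %d/%d\n", ntax, length(object@seqs)))
})

# ----------------------------------------------------------- AmpliconDist ----

#' Pairwise distance matrix of amplicon sequences
#'
#' @slot mat symmetric numeric matrix with zero diagonal, labelled.
#' @slot model `"p"` (uncorrected proportion), `"k2p"` (Kimura
#'   two-parameter) or `"diffs"` (nucleotide difference counts).
#' @slot gapMode `"complete"` (columns gapped in any sequence dropped
#'   panel-wide) or `"pairwise"` (per-pair deletion).
#' @exportClass AmpliconDist
setClass("AmpliconDist", representation(
  mat = "matrix", model = "character", gapMode = "character"
))

setValidity("AmpliconDist", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "matrix must be square and symmetric")
  if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(m < 0)) msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn distanceMatrix extract the plain numeric matrix
#' @export
distMat <- function(x) x@mat

#' @describeIn distanceMatrix min/mean/max over off-diagonal pairs
#' @export
distSummary <- function(x) {
  v <- x@mat[upper.tri(x@mat)]
  c(min = min(v), mean = mean(v), max = max(v))
}

setMethod("show", "AmpliconDist", function(object) {
  s <- distSummary(object)
  cat(sprintf(
    "AmpliconDist: %d sequences, model=%s, gapMode=%s\n", nrow(object@mat),
    object@model, object@gapMode))
  cat(sprintf("  off-diagonal min/mean/max: %.4g / %.4g / %.4g\n",
              s["min"], s["mean"], s["max"]))
})

# ------------------------------------------------------ AssignmentResult ----

#' Result of the read-processing pipeline
#'
#' Taxon-by-sample read counts (with an `unassigned` row), per-stage read
#' tallies, and the contamination flag raised when any declared blank sample
#' retains reads after denoising.
#'
#' @slot counts numeric matrix, rows = taxa plus `"unassigned"`, columns =
#'   samples; column sums equal the denoised read abundance per sample.
#' @slot stageLog data.frame of per-sample read counts surviving each stage.
#' @slot blanks sample ids declared as no-template controls.
#' @slot contaminated `TRUE` iff any blank retained reads.
#' @exportClass AssignmentResult
setClass("AssignmentResult", representation(
  counts = "matrix", stageLog = "data.frame",
  blanks = "character", contaminated = "logical"
))

#' @describeIn runPipeline taxon-by-sample count matrix
#' @export
assignmentCounts <- function(x) x@counts

#' @describeIn runPipeline per-stage read tallies
#' @export
stageLog <- function(x) x@stageLog

#' @describeIn runPipeline was any read found in a declared blank?
#' @export
isContaminated <- function(x) x@contaminated

setMethod("show", "AssignmentResult", function(object) {
  cat(sprintf("AssignmentResult: %d taxa x %d samples\n",
              nrow(object@counts) - 1L, ncol(object@counts)))
  if (length(object@blanks))
    cat(sprintf("  blanks: %s -> %s\n",
                paste(object@blanks, collapse = ", "),
                if (object@contaminated) "CONTAMINATED" else "clean"))
  tot <- colSums(object@counts)
  cat("  reads/sample:", paste(sprintf("%s=%d", names(tot), tot),
                               collapse = " "), "\n")
})
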