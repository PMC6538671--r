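#' @include AllClasses.R
NULL

#' Read a reference panel from FASTA (plus optional taxonomy)
#'
#' Reads an aligned or unaligned FASTA into a [ReferencePanel-class].  The
#' `aligned` flag is set iff all sequences have equal length.  Record ids are
#' the first whitespace-delimited token of each header and must be unique.
#' The only accepted gap character is `-`.
#'
#' @param path FASTA file.
#' @param taxonomyPath optional TSV with a header line and exactly two
#'   columns (id, taxon).  Duplicate taxon labels are allowed (several
#'   references per species); ids absent from the FASTA are an error.
#' @return a [ReferencePanel-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT-ACGT", ">b", "ACGTTACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, taxonomyPath = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings first: the DNA reader silently drops invalid
  # letters, and loading must never alter a record
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  names(seqs) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  for (i in seq_along(seqs))
    .checkDna(seqs[[i]], paste0("record '", names(seqs)[i], "' in ", path),
              allowGaps = TRUE)
  taxon <- NULL
  if (!is.null(taxonomyPath)) taxon <- readTaxonomy(taxonomyPath)
  referencePanel(seqs, taxon = taxon)
}

#' @describeIn readFasta read the two-column taxonomy TSV on its own;
#'   returns a character vector of taxa named by sequence id.
#' @export
readTaxonomy <- function(taxonomyPath) {
  if (!file.exists(taxonomyPath)) stop("file not found: ", taxonomyPath)
  tab <- read.delim(taxonomyPath, header = TRUE, sep = "\t",
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) != 2L)
    stop("taxonomy table must have exactly two columns (id, taxon), got ",
         ncol(tab))
  if (anyDuplicated(tab[[1]]))
    stop("duplicate ids in taxonomy table")
  setNames(tab[[2]], tab[[1]])
}

#' Write a panel (or named sequences) to FASTA
#'
#' @param x a [ReferencePanel-class], `DNAStringSet`, or named character
#'   vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "ReferencePanel")) x <- panelSeqs(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a pair of FASTQ files as mated reads
#'
#' Qualities are decoded as Phred+33 (the Illumina convention); quality
#' characters implying scores outside `[0, 60]` are rejected as a wrong
#' offset.  Records pair up by order and the two files must have equal
#' record counts.
#'
#' @param pathR1,pathR2 FASTQ files for the forward and reverse mates.
#' @return a list with elements `r1` and `r2`, each a
#'   `QualityScaledDNAStringSet`.
#' @export
readFastqPairs <- function(pathR1, pathR2) {
  r1 <- .readFastq(pathR1)
  r2 <- .readFastq(pathR2)
  if (length(r1) != length(r2))
    stop("unpaired FASTQ files: ", length(r1), " records in R1 vs ",
         length(r2), " in R2")
  list(r1 = r1, r2 = r2)
}

.readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      # harmless notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qr <- range(unlist(as(Biostrings::quality(x), "IntegerList")))
  if (length(x) && (qr[1] < 0 || qr[2] > 60))
    stop("Phred scores outside [0, 60] in ", path,
         "; only Phred+33 FASTQ is accepted")
  x
}

#' Write mated reads to a pair of FASTQ files (Phred+33)
#'
#' @param r1,r2 `QualityScaledDNAStringSet` objects of equal length.
#' @param pathR1,pathR2 output files.
#' @return the two paths, invisibly.
#' @export
writeFastqPairs <- function(r1, r2, pathR1, pathR2) {
  stopifnot(length(r1) == length(r2))
  Biostrings::writeQualityScaledXStringSet(r1, pathR1)
  Biostrings::writeQualityScaledXStringSet(r2, pathR2)
  invisible(c(pathR1, pathR2))
}

# Decode a QualityScaledDNAStringSet into parallel character/integer-list
# vectors used by the pipeline stages.
.decodeReads <- function(x) {
  list(seq = as.character(x),
       qual = as.list(as(Biostrings::quality(x), "IntegerList")))
}

.encodeReads <- function(seqs, quals, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  q <- vapply(quals, function(v) rawToChar(as.raw(v + 33L)), "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(q))
}

#' Read primer pairs from a key-value config file
#'
#' The config is YAML with a top-level `primers` list; each entry has keys
#' `name`, `forward`, `reverse` and optionally `max_core_len` (default 200).
#' An empty `primers` list yields an empty result.
#'
#' @param path YAML config file.
#' @return a list of [PrimerPair-class] objects, named by pair name.
#' @export
readPrimerConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$primers)) stop("malformed primer config: no 'primers' key")
  out <- lapply(cfg$primers, function(p) {
    if (is.null(p$name) || is.null(p$forward) || is.null(p$reverse))
      stop("malformed primer entry: needs name, forward, reverse")
    primerPair(
      primer(paste0(p$name, "-F"), p$forward, "forward",
             adapter = if (is.null(p$adapter_forward)) NA_character_
                       else p$adapter_forward),
      primer(paste0(p$name, "-R"), p$reverse, "reverse",
             adapter = if (is.null(p$adapter_reverse)) NA_character_
                       else p$adapter_reverse),
      maxCoreLen = if (is.null(p$max_core_len)) 200L
                   else as.integer(p$max_core_len))
  })
  names(out) <- vapply(cfg$primers, `[[`, "", "name")
  out
}

#' Write a taxon-by-sample counts table as TSV
#'
#' @param x an [AssignmentResult-class] or a numeric matrix with row and
#'   column names.
#' @param path output file.
#' @param provenance optional character vector written as leading `#`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(x, path, provenance = NULL) {
  if (is(x, "AssignmentResult")) x <- assignmentCounts(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- data.frame(taxon = rownames(x), x, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn writeCountsTable read a counts table back; returns the
#'   numeric matrix.
#' @export
readCountsTable <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so trees
#' round-trip losslessly (topology, branch lengths, support labels).
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `writeNewickTree`: `path` invisibly; `readNewickTree`: a `phylo`.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) ape::read.tree(path)
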