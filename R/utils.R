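# Shared sequence helpers. Sequences are plain uppercase character strings at
# this level; the S4 containers wrap Biostrings objects.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

.checkDna <- function(seq, what = "sequence", allowGaps = FALSE,
                      allowAmbiguous = TRUE) {
  chars <- unique(strsplit(seq, "")[[1]])
  ok <- IUPAC_CODES
  if (!allowAmbiguous) ok <- c("A", "C", "G", "T")
  if (allowGaps) ok <- c(ok, "-")
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop(what, " contains invalid characters: ",
         paste(sQuote(bad), collapse = ", "))
  invisible(seq)
}

.revcomp <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN-", "TGCAYRSWMKVHDBN-", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

.complementBase <- function(base) {
  chartr("ACGTRYSWKMBDHVN-", "TGCAYRSWMKVHDBN-", base)
}

# Does a literal primer base anneal at a template base?  Exact match for
# plain A/C/G/T templates; a degenerate template base matches only if the
# primer base is contained in its IUPAC set (conservative call).
.baseMatches <- function(primerBase, templateBase) {
  set <- IUPAC_SETS[[templateBase]]
  if (is.null(set)) return(FALSE)
  primerBase %in% set
}

.degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

# Seed scoping: run `expr` under `seed` without clobbering the caller's RNG
# stream.  Generators call this so identical (spec, seed) inputs give
# identical output regardless of surrounding RNG use.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage-specific sub-seed from a master seed, kept inside 32-bit
# integer range.
.subSeed <- function(seed, stage) {
  (as.integer(seed) * 1103L + as.integer(stage) * 12289L) %% 2147483587L
}

.randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

.phredToErr <- function(q) 10^(-q / 10)
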