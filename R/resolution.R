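#' @include AllClasses.R
NULL

# Columns retained for a pair of aligned sequences: both sides must carry a
# plain A/C/G/T base (gaps and ambiguity codes are treated as missing data).
.retainedColumns <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv))
    stop("sequences must have equal (aligned) length")
  use <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  list(a = av[use], b = bv[use], n = sum(use))
}

#' Nucleotide differences between two aligned sequences
#'
#' Hamming count over the columns retained by `gapMode`.  For a single pair
#' the two deletion modes coincide (columns with a gap or ambiguity on
#' either side are dropped); they differ only at the matrix level, where
#' `"complete"` drops a column for all pairs once any sequence is gapped
#' there.
#'
#' @param a,b aligned sequences (equal length).
#' @param gapMode `"complete"` or `"pairwise"` deletion.
#' @return integer count.
#' @export
ntDifferences <- function(a, b, gapMode = c("complete", "pairwise")) {
  gapMode <- match.arg(gapMode)
  r <- .retainedColumns(a, b)
  sum(r$a != r$b)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' @inheritParams ntDifferences
#' @return proportion of differing retained columns.
#' @export
pDistance <- function(a, b, gapMode = c("complete", "pairwise")) {
  r <- .retainedColumns(a, b)
  if (r$n == 0L) stop("no retained columns (all gapped/ambiguous)")
  sum(r$a != r$b) / r$n
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion over retained columns.  Saturated pairs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are an error, not silently clamped.
#'
#' @inheritParams ntDifferences
#' @return the corrected distance (>= p-distance whenever both defined).
#' @export
k2pDistance <- function(a, b, gapMode = c("complete", "pairwise")) {
  r <- .retainedColumns(a, b)
  if (r$n == 0L) stop("no retained columns (all gapped/ambiguous)")
  diff <- r$a != r$b
  purine <- c("A", "G")
  transition <- diff & ((r$a %in% purine) == (r$b %in% purine))
  P <- sum(transition) / r$n
  Q <- sum(diff & !transition) / r$n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("K2P saturation: distances not estimable for this pair ",
         sprintf("(P = %.3f, Q = %.3f)", P, Q))
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Pairwise distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector of aligned sequences (or an aligned
#'   [ReferencePanel-class]).
#' @param model `"p"`, `"k2p"` or `"diffs"`.
#' @param gapMode `"complete"` drops columns gapped (or ambiguous) in any
#'   sequence before any pair is compared; `"pairwise"` drops per pair.
#' @return an [AmpliconDist-class]; see [distSummary()] for the off-diagonal
#'   min/mean/max.
#' @export
distanceMatrix <- function(seqs, model = c("p", "k2p", "diffs"),
                           gapMode = c("complete", "pairwise")) {
  model <- match.arg(model)
  gapMode <- match.arg(gapMode)
  if (is(seqs, "ReferencePanel")) seqs <- as.character(panelSeqs(seqs))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal length)")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (gapMode == "complete") {
    nm <- names(seqs)
    chars <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
    keep <- apply(chars, 2, function(col)
      all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no columns retained under complete deletion")
    seqs <- setNames(
      apply(chars[, keep, drop = FALSE], 1, paste, collapse = ""), nm)
  }
  n <- length(seqs)
  fn <- switch(model, p = pDistance, k2p = k2pDistance, diffs = ntDifferences)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- fn(seqs[[i]], seqs[[j]], gapMode = "pairwise")
  new("AmpliconDist", mat = m, model = model, gapMode = gapMode)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration, deterministic: ties in the
#' rate-corrected criterion are broken toward the join whose (sorted) label
#' pair is lexicographically smallest.  Negative branch lengths are clamped
#' to zero with the deficit transferred to the sibling branch, so path
#' lengths between the joined pair are preserved.
#'
#' @param d an [AmpliconDist-class] or a symmetric numeric matrix with
#'   labels; n >= 3.
#' @return an unrooted `ape::phylo` tree.
#' @export
njTree <- function(d) {
  if (is(d, "AmpliconDist")) d <- distMat(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  # active nodes carried as Newick fragments; smallestLabel orders ties
  frag <- labels
  small <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(small[ij[1]], small[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newFrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newSmall <- min(small[i], small[j])
    dNew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    small <- c(small[keep], newSmall)
    D <- D2
  }
  # final three nodes joined at the central unrooted node
  v1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  v2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  v3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], v[1],
                 frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = nwk)
}

# Unrooted bipartitions of a phylo tree: for each internal edge, the leaf
# set on the far side canonicalised to exclude the first label
# (alphabetically), returned as sorted |-joined strings.
.bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  ntip <- length(tree$tip.label)
  out <- character()
  # subtree leaf sets via a single post-order pass
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- sort(desc[[child]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Compare two unrooted tree topologies by their bipartition sets
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return `TRUE` iff the non-trivial bipartition sets are identical.
#' @export
sameTopology <- function(t1, t2) {
  setequal(.bipartitions(t1), .bipartitions(t2))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `replicates` times; the support of each
#' internal edge is the percentage of replicate NJ trees containing the
#' same bipartition (branch lengths ignored).  Supports are attached as
#' `node.label` in the ape convention.
#'
#' @param seqs named aligned sequences (or aligned [ReferencePanel-class]).
#' @param model distance model passed to [distanceMatrix()].
#' @param replicates number of bootstrap replicates (default 300).
#' @param seed RNG seed controlling the resampling.
#' @param gapMode deletion mode for the distances.
#' @return an `ape::phylo` with per-internal-node support in `[0, 100]`.
#' @export
bootstrapSupports <- function(seqs, model = "k2p", replicates = 300L,
                              seed = 1L, gapMode = "complete") {
  if (is(seqs, "ReferencePanel")) seqs <- as.character(panelSeqs(seqs))
  if (length(seqs) < 4L) stop("need at least 4 taxa for internal edges")
  if (replicates < 1L) stop("replicates must be >= 1")
  full <- njTree(distanceMatrix(seqs, model = model, gapMode = gapMode))
  target <- .bipartitions(full)
  chars <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE,
                  dimnames = list(names(seqs), NULL))
  L <- ncol(chars)
  hits <- setNames(numeric(length(target)), target)
  withSeed(seed, {
    for (rep in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      bt <- tryCatch(
        njTree(distanceMatrix(res, model = model, gapMode = gapMode)),
        error = function(e) NULL)
      if (is.null(bt)) next
      bp <- .bipartitions(bt)
      inTree <- target %in% bp
      hits[inTree] <- hits[inTree] + 1
    }
  })
  support <- 100 * hits / replicates
  # attach as node labels: map each internal node to its bipartition
  ntip <- length(full$tip.label)
  nodeLab <- rep("", full$Nnode)
  desc <- vector("list", max(full$edge))
  for (i in seq_len(ntip)) desc[[i]] <- full$tip.label[i]
  for (e in ape::postorder(full)) {
    p <- full$edge[e, 1]; ch <- full$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  tips <- sort(full$tip.label)
  anchor <- tips[1]
  for (nd in (ntip + 1L):(ntip + full$Nnode)) {
    side <- sort(desc[[nd]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(support))
      nodeLab[nd - ntip] <- sprintf("%g", support[key])
  }
  full$node.label <- nodeLab
  full
}

#' Taxon-pair ambiguity report at an assignment tolerance
#'
#' Lists every taxon pair with its nucleotide-difference count and flags
#' pairs whose amplicons differ by at most `tolerance` nucleotides as
#' ambiguous: sequencing error of that magnitude can swap their
#' assignments.  With the default identity threshold of 98.5% over a
#' ~167 bp core, two differences are tolerated, so `tolerance = 2` marks the
#' pairs an assignment cannot reliably separate.
#'
#' @param diffs an [AmpliconDist-class] with `model = "diffs"` (or a plain
#'   count matrix).
#' @param taxonomy optional taxon labels named by sequence id.
#' @param tolerance maximum difference count flagged as ambiguous
#'   (default 2).
#' @return list with `pairs` (data.frame `id1`, `id2`, `taxon1`, `taxon2`,
#'   `diffs`, `ambiguous`, ordered by increasing `diffs`) and `summary`
#'   (min/mean/max difference count and the number of ambiguous pairs).
#' @export
resolutionReport <- function(diffs, taxonomy = NULL, tolerance = 2L) {
  if (is(diffs, "AmpliconDist")) {
    if (diffs@model != "diffs")
      stop("resolutionReport expects a difference-count matrix ",
           "(model = 'diffs')")
    diffs <- distMat(diffs)
  }
  ids <- rownames(diffs)
  n <- nrow(diffs)
  idx <- which(upper.tri(diffs), arr.ind = TRUE)
  tax <- function(id) {
    if (is.null(taxonomy)) NA_character_
    else unname(taxonomy[id])
  }
  pairs <- data.frame(
    id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
    taxon1 = vapply(ids[idx[, 1]], tax, ""),
    taxon2 = vapply(ids[idx[, 2]], tax, ""),
    diffs = diffs[idx])
  pairs$ambiguous <- pairs$diffs <= tolerance
  pairs <- pairs[order(pairs$diffs, pairs$id1, pairs$id2), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       summary = c(min = min(pairs$diffs), mean = mean(pairs$diffs),
                   max = max(pairs$diffs),
                   nAmbiguous = sum(pairs$ambiguous)))
}
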