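#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment of two sequences under match/mismatch scores and
#' a linear gap penalty, with deterministic traceback tie-breaking
#' (diagonal, then up, then left). Identity is the fraction of matching
#' columns; by default terminal gap columns are excluded from the column
#' count and internal gap columns count as differences, following common
#' p-distance practice. Divergence is `1 - identity`.
#'
#' @param a,b Character strings (or XString objects) over a common alphabet;
#'   must be non-empty.
#' @param match,mismatch,gap Scoring parameters (defaults +1, -1, -2).
#' @param countTerminalGaps If `TRUE`, terminal gap columns are counted as
#'   differences instead of being excluded.
#' @return A list of class `"AlignmentResult"`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity` in `[0, 1]`,
#'   `divergence`, `n_columns`, `n_matches`.
#' @examples
#' globalAlign("ACGT", "AGGT")$identity   # 0.75
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2,
                        countTerminalGaps = FALSE) {
  a <- as.character(a)
  b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- .nwAlign(a, b, match, mismatch, gap)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ncol_total <- length(ca)
  gapcol <- ca == "-" | cb == "-"
  keep <- rep(TRUE, ncol_total)
  if (!countTerminalGaps && any(gapcol)) {
    r <- rle(gapcol)
    if (r$values[1]) keep[seq_len(r$lengths[1])] <- FALSE
    nr <- length(r$values)
    if (nr > 1 && r$values[nr])
      keep[(ncol_total - r$lengths[nr] + 1):ncol_total] <- FALSE
  }
  n_cols <- sum(keep)
  n_match <- sum(ca[keep] == cb[keep] & !gapcol[keep])
  identity <- if (n_cols > 0) n_match / n_cols else NA_real_
  structure(list(aligned_a = aln$aligned_a, aligned_b = aln$aligned_b,
                 score = aln$score, identity = identity,
                 divergence = 1 - identity, n_columns = n_cols,
                 n_matches = n_match),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat("Global alignment: score", x$score,
      sprintf("identity %.4f divergence %.4f over %d columns\n",
              x$identity, x$divergence, x$n_columns))
  if (nchar(x$aligned_a) <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Pairwise divergence matrix
#'
#' Aligns every pair of sequences with [globalAlign()] and returns the
#' symmetric matrix of divergences (zero diagonal).
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector
#'   of sequences.
#' @param ... Passed to [globalAlign()].
#' @return A symmetric numeric matrix with the sequence names as labels.
#' @export
divergenceMatrix <- function(seqs, ...) {
  labels <- names(seqs)
  s <- as.character(seqs)
  n <- length(s)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- globalAlign(s[i], s[j], ...)$divergence
      }
    }
  }
  d
}

#' Intragenomic SSU-rDNA divergence report
#'
#' Computes the full pairwise divergence matrix over a set of SSU-rDNA
#' copies and reports whether the intragenomic variation stays below the
#' species-level cap (default 3%): the pass flag is
#' `max divergence < maxDivergence`.
#'
#' @param copies A [Biostrings::DNAStringSet] (or named character vector) of
#'   at least two SSU-rDNA copies.
#' @param maxDivergence Divergence cap (default 0.03).
#' @param ... Passed to [globalAlign()].
#' @return A list: `n_copies`, `distance` (matrix), `max_divergence`,
#'   `mean_divergence` (off-diagonal mean), `pass`.
#' @export
ssuReport <- function(copies, maxDivergence = 0.03, ...) {
  s <- as.character(copies)
  if (length(s) < 2) stop("need at least 2 SSU copies")
  d <- divergenceMatrix(s, ...)
  off <- d[upper.tri(d)]
  list(n_copies = length(s), distance = d,
       max_divergence = max(off), mean_divergence = mean(off),
       pass = max(off) < maxDivergence)
}

#' Neighbor-joining tree from a divergence matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj]) on a symmetric
#' distance matrix with zero diagonal. Used here as a deterministic
#' corroboration engine for LGT candidates — an explicit simplification
#' relative to maximum-likelihood inference with bootstrap support; the
#' returned tree carries a `disclaimer` attribute saying so.
#'
#' @param d Symmetric numeric matrix (labels as dimnames) with >= 3 taxa.
#' @param allowNegative Keep negative NJ branch lengths if `TRUE`; default
#'   clamps them to 0.
#' @return An [ape::phylo] tree.
#' @export
njTree <- function(d, allowNegative = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(d)
  if (!allowNegative) tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "disclaimer") <-
    "distance-based NJ corroboration; not a substitute for model-based phylogenetics"
  tr
}

# tip label sets below every edge of a phylo tree (child side)
.edgeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- max(tree$edge)
  below <- vector("list", nodes)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  # process edges child-first (reverse of a preorder edge list)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in rev(seq_len(nrow(edges)))) {
    parent <- edges[k, 1]
    child <- edges[k, 2]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) below[[tree$edge[k, 2]]])
}

#' Check whether a candidate nests among donor or recipient references
#'
#' Given a corroboration tree over an LGT candidate plus donor-side and
#' recipient-side reference sequences, finds the smallest bipartition side
#' containing the candidate and at least one other leaf. If the other
#' leaves on that side are all donors, the candidate nests in the donor
#' group; all recipients, in the recipient group; otherwise the placement
#' is unresolved. Internal edges shorter than `tol` are collapsed first, so
#' a candidate equidistant from everything is reported as unresolved rather
#' than being assigned to an arbitrary zero-length cherry.
#'
#' @param tree An [ape::phylo] tree (e.g. from [njTree()]).
#' @param candidate Tip label of the candidate gene.
#' @param donors,recipients Character vectors of reference tip labels
#'   (at least 2 per side).
#' @param tol Branch-length tolerance for collapsing unresolved edges.
#' @return One of `"nested_in_donor"`, `"nested_in_recipient"`,
#'   `"unresolved"`.
#' @export
donorNestingCheck <- function(tree, candidate, donors, recipients,
                              tol = 1e-8) {
  labs <- tree$tip.label
  missing <- setdiff(c(candidate, donors, recipients), labs)
  if (length(missing))
    stop("labels absent from tree: ", paste(missing, collapse = ", "))
  if (length(donors) < 2 || length(recipients) < 2)
    stop("need at least 2 donor and 2 recipient labels")
  tree <- ape::di2multi(tree, tol = tol)
  ntip <- length(tree$tip.label)
  sets <- .edgeTipSets(tree)
  sides <- c(sets, lapply(sets, function(s) setdiff(tree$tip.label, s)))
  sizes <- lengths(sides)
  has_cand <- vapply(sides, function(s) candidate %in% s, TRUE)
  ok <- has_cand & sizes >= 2 & sizes <= ntip - 1
  if (!any(ok)) return("unresolved")
  minimal <- sides[ok][sizes[ok] == min(sizes[ok])]
  verdicts <- unique(vapply(minimal, function(side) {
    others <- setdiff(side, candidate)
    if (all(others %in% donors)) "nested_in_donor"
    else if (all(others %in% recipients)) "nested_in_recipient"
    else "unresolved"
  }, ""))
  # equally small sides that disagree leave the placement unresolved
  if (length(verdicts) == 1) verdicts else "unresolved"
}
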