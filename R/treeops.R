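#' Prune taxa from a tree
#'
#' Removes the given tips and suppresses the resulting degree-2 nodes, summing
#' branch lengths across them, via [ape::drop.tip()]. The splits of the pruned
#' tree equal the restriction of the original splits to the retained taxa.
#'
#' @param tree a `phylo`
#' @param drop character vector of tip labels to remove (may be empty)
#' @return a `phylo`
#' @export
pruneTaxa <- function(tree, drop) {
  stopifnot(inherits(tree, "phylo"))
  drop <- unique(drop)
  bad <- setdiff(drop, tree$tip.label)
  if (length(bad)) stop("not a tip: ", paste(bad, collapse = ", "))
  if (!length(drop)) return(tree)
  nleft <- length(tree$tip.label) - length(drop)
  if (nleft < 2L)
    stop("pruning would leave fewer than 2 tips (", nleft, " remain)")
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj()]) with negative estimated branch
#' lengths clamped to zero. The matrix must be symmetric, finite,
#' non-negative with a zero diagonal, over at least 4 taxa.
#'
#' @param d symmetric numeric distance matrix with taxon dimnames
#' @return an unrooted `phylo`
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 4L) stop("neighbor joining needs >= 4 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise distances along a tree's branches
#'
#' Path-length (patristic) distances; exact on the tree, so `njTree()` on the
#' result recovers the generating topology for additive inputs.
#'
#' @param tree a `phylo` with branch lengths
#' @return symmetric numeric matrix
#' @export
treeDistances <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ape::cophenetic.phylo(tree)
}
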