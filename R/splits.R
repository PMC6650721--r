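## Bipartition (split) algebra over unrooted topologies.
## Canonical encoding: the stored side of a split is the one NOT containing
## the lexicographically first taxon of the universe, sorted; the key is the
## side joined with ";". Splits from trees missing universe taxa live on the
## tree's own (restricted) universe and must be restricted to a common taxon
## set before pooling.

.splitKey <- function(side) paste(side, collapse = ";")

.canonSide <- function(side, universe) {
  if (universe[1L] %in% side) side <- setdiff(universe, side)
  sort(side)
}

.newSplitSet <- function(sides, universe) {
  names(sides) <- vapply(sides, .splitKey, character(1))
  sides <- sides[!duplicated(names(sides))]
  new("SplitSet", universe = universe, sides = sides)
}

## tip-index sets below each internal edge, one postorder pass
.cladeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  e1 <- tr$edge[, 1L]; e2 <- tr$edge[, 2L]
  for (k in seq_along(e1))
    below[[e1[k]]] <- c(below[[e1[k]]], below[[e2[k]]])
  internal <- e2[e2 > ntip]
  lapply(internal, function(nd) below[[nd]])
}

#' Non-trivial bipartitions of an unrooted tree topology
#'
#' Enumerates every split of the unrooted topology with at least two taxa on
#' both sides, in the canonical encoding of [SplitSet]. A tree whose tips are
#' a proper subset of `universe` yields splits over its own tip set, carried
#' as the SplitSet's (restricted) universe.
#'
#' @param tree a `phylo`
#' @param universe optional taxon ordering the tips must belong to; defaults
#'   to the tree's own tips
#' @return a [SplitSet]
#' @export
bipartitions <- function(tree, universe = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(universe)) universe <- tips
  missing <- setdiff(tips, universe)
  if (length(missing))
    stop("tip(s) not in universe: ", paste(missing, collapse = ", "))
  u <- sort(tips)  # restricted universe
  ntip <- length(tips)
  if (ntip < 4L) return(.newSplitSet(list(), u))
  sets <- .cladeTipSets(tree)
  sides <- list()
  for (s in sets) {
    if (length(s) < 2L || length(s) > ntip - 2L) next
    sides[[length(sides) + 1L]] <- .canonSide(tips[s], u)
  }
  .newSplitSet(sides, u)
}

#' Restrict a split set to a subset of its taxa
#'
#' Intersects every split with the retained taxa, drops splits that become
#' trivial (fewer than two taxa on either side) and collapses duplicates.
#' This is the split-level counterpart of pruning taxa from the tree:
#' `bipartitions(pruneTaxa(t, d))` equals `restrictSplits(bipartitions(t),
#' setdiff(taxa, d))`.
#'
#' @param x a [SplitSet]
#' @param keep taxa to retain
#' @return a [SplitSet] over the restricted universe
#' @export
restrictSplits <- function(x, keep) {
  stopifnot(is(x, "SplitSet"))
  u <- intersect(x@universe, keep)
  u <- sort(u)
  if (length(u) < 4L) return(.newSplitSet(list(), u))
  sides <- list()
  for (s in x@sides) {
    a <- s[s %in% u]
    if (length(a) < 2L || length(a) > length(u) - 2L) next
    sides[[length(sides) + 1L]] <- .canonSide(a, u)
  }
  .newSplitSet(sides, u)
}

#' Robinson-Foulds split distance between two trees
#'
#' Size of the symmetric difference between the two trees' non-trivial split
#' sets. The trees must have identical tip sets.
#'
#' @param t1,t2 `phylo` trees over the same taxa
#' @return non-negative integer
#' @export
splitDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share one tip set")
  k1 <- splitKeys(bipartitions(t1))
  k2 <- splitKeys(bipartitions(t2))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Write a split table as TSV
#'
#' Columns: `split_bitmask_hex` (bit `i` set when the `i`-th universe taxon,
#' in sorted order, lies on the stored side), `side_taxa` (canonical side,
#' taxa joined by `";"`), and one frequency column per chain when `x` is a
#' [BipartitionTable].
#'
#' @param x a [SplitSet] or [BipartitionTable]
#' @param path output path
#' @export
writeSplitTable <- function(x, path) {
  u <- x@universe
  hex <- vapply(x@sides, function(s) {
    bits <- as.integer(u %in% s)
    bytes <- split(bits, ceiling(seq_along(bits) / 8))
    paste(vapply(bytes, function(b)
      sprintf("%02x", sum(b * 2^(seq_along(b) - 1L))), character(1)),
      collapse = "")
  }, character(1))
  df <- data.frame(split_bitmask_hex = hex, side_taxa = names(x@sides))
  if (is(x, "BipartitionTable"))
    df <- cbind(df, as.data.frame(x@freq, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
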