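## shared fixture builders; everything is generated in code at test time

## a TreeSample without touching disk
mkSample <- function(trees, chain = "c1") {
  new("TreeSample", chain = chain, trees = trees, burnin = 0,
      nTotal = length(trees), source = "in-memory")
}

## random unrooted binary tree via ape, unit branch lengths unless told
randTree <- function(n, lengths = TRUE) {
  tr <- ape::unroot(ape::rtree(n))
  if (!lengths) tr$edge.length <- NULL
  tr
}

## independent split enumeration: for every internal edge of the unrooted
## tree, collect the tip set below it via ape's clade extraction, and
## canonicalize the same way the package documents (side without the
## lexicographically first taxon, sorted, joined by ";")
oracleSplitKeys <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  first <- sort(tree$tip.label)[1L]
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= ntip) next
    side <- ape::extract.clade(tree, child)$tip.label
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (first %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = ";"))
  }
  unique(keys)
}

## brute-force species-overlap orthology oracle: enumerate every edge side
## (below-sets and complements, plus the full tip set), apply the
## qualification, maximality and greedy-disjointness rules independently
oracleUpho <- function(tree, minTaxa = 3L, delim = "@") {
  tips <- tree$tip.label
  sp <- vapply(strsplit(tips, delim, fixed = TRUE), `[[`, character(1), 1L)
  ntip <- length(tips)
  ## candidate sides: non-trivial bipartition sides plus the full tip set
  sides <- list(seq_len(ntip))
  rt <- if (ape::is.rooted(tree)) tree else ape::root(tree, 1, resolve.root = TRUE)
  for (nd in (ntip + 1L):(ntip + rt$Nnode)) {
    cl <- which(tips %in% ape::extract.clade(rt, nd)$tip.label)
    for (side in list(cl, setdiff(seq_len(ntip), cl)))
      if (length(side) >= 2L && length(side) <= ntip - 2L)
        sides <- c(sides, list(side))
  }
  sides <- unique(lapply(sides, sort))
  ok <- Filter(function(s) length(s) > 0 && !anyDuplicated(sp[s]) &&
                 length(unique(sp[s])) >= minTaxa, sides)
  if (!length(ok)) return(list())
  isMax <- vapply(seq_along(ok), function(i)
    !any(vapply(seq_along(ok), function(j)
      j != i && length(ok[[i]]) < length(ok[[j]]) && all(ok[[i]] %in% ok[[j]]),
      logical(1))), logical(1))
  ok <- ok[isMax]
  ord <- order(-vapply(ok, length, integer(1)),
               vapply(ok, function(s) paste(sort(tips[s]), collapse = ";"),
                      character(1)))
  ok <- ok[ord]
  used <- logical(ntip)
  out <- list()
  for (s in ok) {
    if (any(used[s])) next
    used[s] <- TRUE
    out[[length(out) + 1L]] <- sort(tips[s])
  }
  out
}

## apply a burn-in fraction to in-memory chains the same way loadChain does
applyBurnin <- function(samples, frac) {
  lapply(samples, function(s) {
    tr <- chainTrees(s)
    nb <- ceiling(frac * length(tr))
    mkSample(tr[(nb + 1L):length(tr)], chain = chainId(s))
  })
}
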