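## Posterior tree-sample diagnostics: bipartition frequency tables,
## across-chain maxdiff, rogue-taxon detection by greedy resolution gain,
## and masked majority-rule consensus.

#' Load one MCMC chain of sampled trees
#'
#' Reads a one-Newick-per-line tree list, discards the first
#' `ceiling(burninFraction * N)` trees, and checks that all retained trees
#' share one tip set; trees with a deviant tip set (e.g. from a truncated
#' sample file) are dropped with a message rather than failing the run.
#'
#' @param path tree-list file
#' @param burninFraction fraction in [0,1) discarded from the front
#' @param skip header lines to skip before the first tree
#' @param chain chain id (defaults to the file name)
#' @return a [TreeSample]
#' @export
loadChain <- function(path, burninFraction = 0.2, skip = 0L, chain = NULL) {
  if (burninFraction < 0 || burninFraction >= 1)
    stop("burninFraction must be in [0,1)")
  trees <- readTreeList(path, skip = skip)
  n <- length(trees)
  if (!n) stop("no trees in ", path)
  nb <- ceiling(burninFraction * n)
  if (nb > 0L) trees <- trees[-seq_len(nb)]
  if (!length(trees)) stop("empty post-burn-in sample in ", path)
  key <- vapply(trees, function(t) paste(sort(t$tip.label), collapse = ";"),
                character(1))
  modal <- names(sort(table(key), decreasing = TRUE))[1L]
  if (any(key != modal)) {
    message(sum(key != modal), " tree(s) with deviant tip sets dropped from ",
            path)
    trees <- trees[key == modal]
  }
  new("TreeSample", chain = chain %||% basename(path), trees = trees,
      burnin = burninFraction, nTotal = as.integer(n), source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## collapse a list of trees to unique topologies with weights; returns
## list(splits = list of SplitSet, weights, universe)
.poolTopologies <- function(trees) {
  keys <- vapply(trees, writeNewick, character(1), lengths = FALSE,
                 labels = FALSE)
  tab <- table(keys)
  first <- trees[match(names(tab), keys)]
  list(splits = lapply(first, bipartitions),
       weights = as.numeric(tab),
       universe = sort(trees[[1L]]$tip.label))
}

.chainUniverse <- function(sample) sort(sample@trees[[1L]]$tip.label)

#' Per-chain bipartition frequencies
#'
#' For every chain, the frequency of each non-trivial split is its number of
#' occurrences divided by the chain's post-burn-in sample count; the table
#' covers the union of splits over all chains, with absent splits at
#' frequency 0. Chains must share one taxon set (mask first if not).
#'
#' @param samples list of [TreeSample]
#' @return a [BipartitionTable]
#' @export
splitFrequencies <- function(samples) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, is, logical(1), "TreeSample")))
  unis <- lapply(samples, .chainUniverse)
  u <- unis[[1L]]
  for (i in seq_along(unis)[-1L]) {
    if (!identical(unis[[i]], u)) {
      d <- c(setdiff(unis[[i]], u), setdiff(u, unis[[i]]))
      stop("chains have mismatched taxon sets; difference: ",
           paste(d, collapse = ", "))
    }
  }
  perChain <- vector("list", length(samples))
  allKeys <- character(0)
  sideMap <- list()
  for (ci in seq_along(samples)) {
    pool <- .poolTopologies(samples[[ci]]@trees)
    counts <- new.env(parent = emptyenv())
    for (ti in seq_along(pool$splits)) {
      ss <- pool$splits[[ti]]
      w <- pool$weights[ti]
      for (k in names(ss@sides)) {
        prev <- if (exists(k, envir = counts)) get(k, envir = counts) else 0
        assign(k, prev + w, envir = counts)
        if (is.null(sideMap[[k]])) sideMap[[k]] <- ss@sides[[k]]
      }
    }
    keys <- ls(counts)
    perChain[[ci]] <- stats::setNames(
      vapply(keys, get, numeric(1), envir = counts) /
        length(samples[[ci]]@trees), keys)
    allKeys <- union(allKeys, keys)
  }
  allKeys <- sort(allKeys)
  freq <- matrix(0, length(allKeys), length(samples),
                 dimnames = list(allKeys,
                                 vapply(samples, chainId, character(1))))
  for (ci in seq_along(perChain))
    freq[names(perChain[[ci]]), ci] <- perChain[[ci]]
  new("BipartitionTable", universe = u, sides = sideMap[allKeys],
      freq = freq,
      counts = vapply(samples, function(s) length(s@trees), integer(1)))
}

#' Maximum across-chain bipartition frequency difference
#'
#' The convergence heuristic used to accept multi-chain Bayesian analyses:
#' the maximum, over every split observed in any chain, of the largest
#' pairwise absolute frequency difference between chains (a split absent
#' from a chain counts as frequency 0). Values below 0.2 are conventionally
#' read as acceptable convergence.
#'
#' @param table a [BipartitionTable] with >= 2 chains
#' @return a number in [0,1]
#' @export
maxdiff <- function(table) {
  stopifnot(is(table, "BipartitionTable"))
  if (ncol(table@freq) < 2L)
    stop("maxdiff is undefined for a single chain")
  if (!nrow(table@freq)) return(0)
  max(apply(table@freq, 1L, function(r) max(r) - min(r)))
}

## pooled split frequencies over all samples, restricted to `keep` taxa;
## returns named numeric vector (and sides via attr)
.pooledRestricted <- function(pool, keep, nPool) {
  counts <- new.env(parent = emptyenv())
  sideMap <- list()
  for (ti in seq_along(pool$splits)) {
    ss <- restrictSplits(pool$splits[[ti]], keep)
    w <- pool$weights[ti]
    for (k in names(ss@sides)) {
      prev <- if (exists(k, envir = counts)) get(k, envir = counts) else 0
      assign(k, prev + w, envir = counts)
      if (is.null(sideMap[[k]])) sideMap[[k]] <- ss@sides[[k]]
    }
  }
  keys <- ls(counts)
  out <- stats::setNames(vapply(keys, get, numeric(1), envir = counts) / nPool,
                         keys)
  attr(out, "sides") <- sideMap[keys]
  out
}

#' Score and flag rogue taxa
#'
#' Per-taxon instability is `1 - mean(pooled frequency of the taxon's
#' attachment split)`, where the attachment split in each sampled tree is the
#' smallest non-trivial split containing the taxon; a taxon whose local
#' neighbourhood is the same in every tree scores 0, a taxon reattached at
#' random scores near 1.
#'
#' Flagging is a greedy resolution-gain search. Resolution is measured as a
#' support deficiency: `(|retained| - 3) - sum(f_s)` over the splits `s` of
#' the strict-majority consensus on the retained taxa (greedy compatible
#' splits with pooled frequency `f_s` above `supportThreshold`) — the support
#' mass missing relative to a fully resolved, fully supported topology. The
#' taxon whose masking (pruning from every sampled tree) most reduces the
#' deficiency is flagged repeatedly until the best gain drops below
#' `gainThreshold` (default half a fully supported position). The deficiency
#' form is used rather than the raw majority-split count because masking
#' removes one resolvable position from the universe along with the taxon,
#' so the raw count stays constant even when masking a maximally unstable
#' taxon fully resolves and fully supports the remaining topology. An empty
#' flag set is a valid outcome.
#'
#' @param samples list of [TreeSample] (pooled sample must hold >= 20 trees)
#' @param supportThreshold pooled frequency defining a resolved split
#' @param gainThreshold minimum gain (new resolved splits) to keep flagging
#' @return a [RogueReport]
#' @export
rogueScores <- function(samples, supportThreshold = 0.5, gainThreshold = 0.5) {
  stopifnot(length(samples) >= 1L)
  trees <- do.call(c, lapply(samples, chainTrees))
  if (length(trees) < 20L) stop("pooled sample must hold >= 20 trees")
  u <- sort(trees[[1L]]$tip.label)
  pool <- .poolTopologies(trees)
  nPool <- sum(pool$weights)
  pooled <- .pooledRestricted(pool, u, nPool)

  ## instability scores
  scores <- stats::setNames(numeric(length(u)), u)
  for (t in u) {
    acc <- 0
    for (ti in seq_along(pool$splits)) {
      ss <- pool$splits[[ti]]
      f <- 1  # no resolution to contradict: trivially stable
      if (length(ss@sides)) {
        containing <- vapply(ss@sides, function(s) t %in% s, logical(1))
        sizes <- ifelse(containing, lengths(ss@sides),
                        length(u) - lengths(ss@sides))
        k <- names(ss@sides)[which.min(sizes)]
        f <- unname(pooled[k])
      }
      acc <- acc + pool$weights[ti] * f
    }
    scores[t] <- 1 - acc / nPool
  }

  deficiency <- function(keep) {
    f <- .pooledRestricted(pool, keep, nPool)
    (length(keep) - 3L) -
      .consensusSupportSum(f, attr(f, "sides"), keep, supportThreshold)
  }
  flagged <- character(0)
  trace <- data.frame(taxon = character(0), gain = numeric(0),
                      deficiency = numeric(0), stringsAsFactors = FALSE)
  base <- deficiency(u)
  repeat {
    cand <- setdiff(u, flagged)
    if (length(u) - length(flagged) <= 4L) break
    gains <- vapply(cand, function(x)
      base - deficiency(setdiff(u, c(flagged, x))), numeric(1))
    best <- order(-gains, cand)[1L]
    if (gains[best] < gainThreshold) break
    flagged <- c(flagged, cand[best])
    base <- base - gains[best]
    trace <- rbind(trace, data.frame(taxon = cand[best], gain = gains[best],
                                     deficiency = base,
                                     stringsAsFactors = FALSE))
  }
  new("RogueReport", scores = scores, flagged = flagged, trace = trace)
}

## summed pooled frequency of the greedy compatible majority splits (the
## would-be consensus); at most |keep| - 3
.consensusSupportSum <- function(pooled, sides, keep, threshold) {
  ord <- order(-pooled, names(pooled))
  sel <- list()
  total <- 0
  for (i in ord) {
    if (pooled[i] <= threshold) break
    if (all(vapply(sel, .splitsCompatible, logical(1), b = sides[[i]],
                   universe = keep))) {
      sel[[length(sel) + 1L]] <- sides[[i]]
      total <- total + pooled[i]
    }
  }
  total
}

.splitsCompatible <- function(a, b, universe) {
  if (!length(intersect(a, b))) return(TRUE)
  if (!length(setdiff(a, b)) || !length(setdiff(b, a))) return(TRUE)
  length(union(a, b)) == length(universe)
}

#' Masked majority-rule consensus with posterior probabilities
#'
#' Prunes `mask` from every sampled tree (pooled across chains), then builds
#' the majority-rule consensus: splits are considered in descending pooled
#' frequency and added while above `threshold` and compatible with the splits
#' already accepted. With the default strict-majority threshold all accepted
#' splits are automatically compatible; a threshold below 0.5 that meets an
#' incompatible split is an error. Each retained split is annotated with its
#' pooled frequency as a posterior probability (internal node labels).
#'
#' @param samples list of [TreeSample]
#' @param mask taxa to prune before summarizing (>= 4 must remain)
#' @param threshold minimum pooled frequency of a retained split
#' @return a [ConsensusTree]
#' @export
maskedConsensus <- function(samples, mask = character(0), threshold = 0.5) {
  stopifnot(length(samples) >= 1L)
  trees <- do.call(c, lapply(samples, chainTrees))
  u <- sort(trees[[1L]]$tip.label)
  bad <- setdiff(mask, u)
  if (length(bad)) stop("mask taxa not in samples: ", paste(bad, collapse = ", "))
  keep <- setdiff(u, mask)
  if (length(keep) < 4L) stop("masking leaves fewer than 4 taxa")
  pool <- .poolTopologies(trees)
  nPool <- sum(pool$weights)
  pooled <- .pooledRestricted(pool, keep, nPool)
  sides <- attr(pooled, "sides")
  ord <- order(-pooled, names(pooled))
  sel <- character(0)
  for (k in names(pooled)[ord]) {
    if (pooled[k] <= threshold) break
    ok <- all(vapply(sel, function(s)
      .splitsCompatible(sides[[k]], sides[[s]], keep), logical(1)))
    if (!ok) {
      if (threshold < 0.5)
        stop("incompatible splits above threshold ", threshold,
             "; only strict majority (>= 0.5) guarantees compatibility")
      next
    }
    sel <- c(sel, k)
  }
  support <- stats::setNames(as.numeric(pooled[sel]), sel)
  tree <- .treeFromClades(sides[sel], support, keep)
  new("ConsensusTree", tree = tree, support = support,
      masked = sort(as.character(mask)))
}

## build a rooted-for-display tree from nested clades (canonical sides never
## contain keep[1], so they are proper clades of a tree rooted on keep[1])
.treeFromClades <- function(cladeSides, support, universe) {
  n <- length(cladeSides)
  sizes <- if (n) lengths(cladeSides) else integer(0)
  ord <- if (n) order(-sizes) else integer(0)
  parent <- rep(0L, n)  # 0 = root
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (ii == 1L) next
    for (jj in rev(seq_len(ii - 1L))) {  # smallest enclosing earlier clade
      j <- ord[jj]
      if (all(cladeSides[[i]] %in% cladeSides[[j]])) { parent[i] <- j; break }
    }
  }
  children <- lapply(0:n, function(p) which(parent == p))
  names(children) <- as.character(0:n)
  build <- function(idx, taxaHere) {
    kids <- children[[as.character(idx)]]
    childTaxa <- unlist(lapply(kids, function(k) cladeSides[[k]]))
    own <- setdiff(taxaHere, childTaxa)
    parts <- c(sort(own),
               vapply(kids[order(vapply(kids, function(k)
                 min(cladeSides[[k]]), character(1)))],
                 function(k) build(k, cladeSides[[k]]), character(1)))
    lab <- if (idx == 0L) "" else format(support[idx], digits = 4)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  parseNewick(paste0(build(0L, universe), ";"))
}

#' Write a convergence summary TSV
#'
#' One row per analysis: maxdiff, per-chain post-burn-in counts, masked taxa.
#'
#' @param table a [BipartitionTable]
#' @param masked masked taxa (for the record)
#' @param path output path
#' @export
writeConvergenceSummary <- function(table, masked = character(0), path) {
  df <- data.frame(maxdiff = maxdiff(table),
                   chains = ncol(table@freq),
                   counts = paste(table@counts, collapse = ";"),
                   masked = paste(masked, collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a rogue report TSV
#'
#' @param report a [RogueReport]
#' @param path output path
#' @export
writeRogueReport <- function(report, path) {
  df <- data.frame(taxon = names(report@scores),
                   instability = unname(report@scores),
                   flagged = names(report@scores) %in% report@flagged)
  utils::write.table(df[order(-df$instability), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
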