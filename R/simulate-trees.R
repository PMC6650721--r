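## Synthetic species trees, gene families and tree-sample chains with known
## ground truth, used by the recovery tests for every downstream stage.

## Pure-birth (Yule) tree: start with 2 lineages at the root; while k < n
## lineages wait Exp(k * rate) and split a uniformly chosen lineage; after
## reaching n, extend all lineages by a final Exp(n * rate) wait. Ultrametric;
## E[height] = (1/rate) * sum_{k=2}^{n} 1/k.
.yuleNewick <- function(n, rate, labels) {
  if (n == 1L) return(labels[1L])
  len <- c(0, 0)
  kids <- list(NULL, NULL)
  active <- c(1L, 2L)
  while (length(active) < n) {
    w <- stats::rexp(1L, length(active) * rate)
    len[active] <- len[active] + w
    j <- active[sample.int(length(active), 1L)]
    newIdx <- length(len) + c(1L, 2L)
    kids[[j]] <- newIdx
    len <- c(len, 0, 0)
    kids <- c(kids, list(NULL, NULL))
    active <- c(setdiff(active, j), newIdx)
  }
  w <- stats::rexp(1L, n * rate)
  len[active] <- len[active] + w
  nextLab <- 0L
  build <- function(i) {
    if (is.null(kids[[i]])) {
      nextLab <<- nextLab + 1L
      return(paste0(labels[nextLab], ":", format(len[i], digits = 10)))
    }
    paste0("(", build(kids[[i]][1]), ",", build(kids[[i]][2]), "):",
           format(len[i], digits = 10))
  }
  paste0("(", build(1L), ",", build(2L), ")")
}

#' Simulate a clade-structured species tree
#'
#' Yule (pure-birth) topology with exponentially distributed waiting times
#' (ultrametric). With a multi-clade `cladeSpec`, a Yule backbone is drawn
#' over the clades and an independent Yule subtree of the requested size is
#' grafted at each backbone tip, so every clade is monophyletic by
#' construction. Deterministic given `seed`.
#'
#' @param nTaxa total number of tips (>= 4)
#' @param cladeSpec named integer vector `clade -> size` summing to `nTaxa`;
#'   `NULL` puts all taxa in clade `"ingroup"`
#' @param rate speciation rate (per lineage, per unit branch length)
#' @param seed optional RNG seed
#' @param prefix tip-label prefix
#' @return list with `tree` (phylo), `cladeMap` (named character vector
#'   taxon -> clade) and `seed`
#' @export
simulateSpeciesTree <- function(nTaxa, cladeSpec = NULL, rate = 1, seed = NULL,
                                prefix = "t") {
  if (nTaxa < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cladeSpec)) cladeSpec <- c(ingroup = nTaxa)
  if (any(cladeSpec < 1L)) stop("clade of size 0")
  if (sum(cladeSpec) != nTaxa) stop("clade sizes must sum to nTaxa")
  labels <- paste0(prefix, seq_len(nTaxa))
  if (length(cladeSpec) == 1L) {
    nwk <- paste0(.yuleNewick(nTaxa, rate, labels), ";")
    tr <- parseNewick(nwk)
    cm <- stats::setNames(rep(names(cladeSpec), nTaxa), labels)
    return(list(tree = tr, cladeMap = cm[tr$tip.label], seed = seed))
  }
  k <- length(cladeSpec)
  ph <- paste0("CLADEPLACEHOLDER", seq_len(k))
  backbone <- paste0(.yuleNewick(k, rate, ph), ";")
  offset <- c(0L, cumsum(cladeSpec))
  for (i in seq_len(k)) {
    labs <- labels[(offset[i] + 1L):offset[i + 1L]]
    sub <- .yuleNewick(length(labs), rate, labs)
    backbone <- sub(ph[i], sub, backbone, fixed = TRUE)
  }
  tr <- parseNewick(backbone)
  cm <- stats::setNames(rep(names(cladeSpec), cladeSpec), labels)
  list(tree = tr, cladeMap = cm[tr$tip.label], seed = seed)
}

#' Closed-form expected height of the simulated Yule tree
#'
#' For the construction used by [simulateSpeciesTree()]:
#' `E[height] = (1/rate) * sum(1/(2:n))`.
#'
#' @param nTaxa number of tips
#' @param rate speciation rate
#' @export
yuleExpectedHeight <- function(nTaxa, rate = 1) sum(1 / (2:nTaxa)) / rate

#' Simulate a gene family along a species tree
#'
#' A birth-death copy process: one gene copy enters the root and travels
#' along the species tree; on every branch each copy duplicates at `dupRate`
#' and is lost at `lossRate` (per unit branch length); at speciation nodes
#' copies are inherited by all descendant branches. Tips are labelled
#' `species@copyN`. With both rates zero the gene tree is topologically
#' congruent with the species tree. Gene-tree nodes left with a single child
#' (by loss) are suppressed with branch lengths summed.
#'
#' @param speciesTree a `phylo` with branch lengths
#' @param dupRate,lossRate non-negative event rates
#' @param seed optional RNG seed
#' @param delim species/copy delimiter in tip labels
#' @return a `phylo` gene family tree, or `NULL` if every copy was lost
#'   (the empty-family marker)
#' @export
simulateGeneFamily <- function(speciesTree, dupRate = 0, lossRate = 0,
                               seed = NULL, delim = "@") {
  stopifnot(inherits(speciesTree, "phylo"), !is.null(speciesTree$edge.length),
            dupRate >= 0, lossRate >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(speciesTree$tip.label)
  kids <- .childrenList(speciesTree)
  elen <- numeric(ntip + speciesTree$Nnode)
  elen[speciesTree$edge[, 2L]] <- speciesTree$edge.length
  counts <- new.env(parent = emptyenv())
  total <- dupRate + lossRate
  ## lineage travelling the branch ending at `node`, `rem` branch time left,
  ## `acc` gene-branch length since the last gene-tree node; returns
  ## list(str=newick substring, len=root edge length) or NULL (extinct)
  evolve <- function(node, rem, acc) {
    repeat {
      t <- if (total > 0) stats::rexp(1L, total) else Inf
      if (t >= rem) { acc <- acc + rem; break }
      acc <- acc + t; rem <- rem - t
      if (stats::runif(1L) < dupRate / total) {
        a <- evolve(node, rem, 0)
        b <- evolve(node, rem, 0)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(list(str = b$str, len = b$len + acc))
        if (is.null(b)) return(list(str = a$str, len = a$len + acc))
        return(list(str = paste0("(", a$str, ":", format(a$len, digits = 10),
                                 ",", b$str, ":", format(b$len, digits = 10), ")"),
                    len = acc))
      } else return(NULL)
    }
    if (node <= ntip) {
      sp <- speciesTree$tip.label[node]
      n <- (if (exists(sp, envir = counts)) get(sp, envir = counts) else 0L) + 1L
      assign(sp, n, envir = counts)
      return(list(str = paste0(sp, delim, "c", n), len = acc))
    }
    parts <- list()
    for (ch in kids[[node]]) {
      r <- evolve(ch, elen[ch], 0)
      if (!is.null(r)) parts[[length(parts) + 1L]] <- r
    }
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L)
      return(list(str = parts[[1]]$str, len = parts[[1]]$len + acc))
    inner <- paste(vapply(parts, function(p)
      paste0(p$str, ":", format(p$len, digits = 10)), character(1)),
      collapse = ",")
    list(str = paste0("(", inner, ")"), len = acc)
  }
  root <- ntip + 1L
  res <- evolve(root, 0, 0)
  if (is.null(res)) return(NULL)
  if (!grepl(",", res$str, fixed = TRUE))
    return(parseNewick(paste0("(", res$str, ");")))
  parseNewick(paste0(res$str, ";"))
}

#' Expected gene-family tip count under the copy process
#'
#' Branching-process closed form: the expected number of surviving copies at
#' a species tip at root-to-tip depth `d` is `exp((dupRate - lossRate) * d)`,
#' so the expected family size is the sum of that over all species tips.
#'
#' @param speciesTree a `phylo` with branch lengths
#' @param dupRate,lossRate event rates
#' @export
expectedFamilySize <- function(speciesTree, dupRate, lossRate) {
  depths <- ape::node.depth.edgelength(speciesTree)
  sum(exp((dupRate - lossRate) *
            depths[seq_along(speciesTree$tip.label)]))
}

#' Simulate MCMC-like tree-sample chains
#'
#' Each sampled tree equals the (unrooted) reference with probability
#' `1 - scatterProb` and is otherwise one random nearest-neighbour
#' interchange of it. If `rogueTaxon` is given, that tip is detached from
#' every sampled tree and reattached to a uniformly chosen branch (uniform
#' over branches, attachment point uniform along the branch), emulating a
#' taxon with no stable posterior position. Deterministic given `seed`.
#'
#' @param reference a `phylo` (>= 5 tips when a rogue is planted)
#' @param nChains,nSamples chain layout
#' @param scatterProb per-sample NNI probability in [0,1]
#' @param rogueTaxon optional tip label to scatter in every sample
#' @param seed optional RNG seed
#' @return list of [TreeSample] objects, one per chain (burn-in 0)
#' @export
simulateTreeChains <- function(reference, nChains = 4L, nSamples = 1000L,
                               scatterProb = 0.1, rogueTaxon = NULL,
                               seed = NULL) {
  stopifnot(inherits(reference, "phylo"), nChains >= 1L,
            scatterProb >= 0, scatterProb <= 1)
  if (!is.null(rogueTaxon) && !rogueTaxon %in% reference$tip.label)
    stop("rogue taxon not in tree: ", rogueTaxon)
  if (!is.null(seed)) set.seed(seed)
  ref <- ape::unroot(reference)
  if (is.null(ref$edge.length)) ref$edge.length <- rep(1, nrow(ref$edge))
  rogueLen <- if (!is.null(rogueTaxon))
    ref$edge.length[ref$edge[, 2L] == which(ref$tip.label == rogueTaxon)]
  lapply(seq_len(nChains), function(ci) {
    trees <- vector("list", nSamples)
    for (i in seq_len(nSamples)) {
      tr <- if (stats::runif(1L) < scatterProb) phangorn::rNNI(ref, 1L) else ref
      if (!is.null(rogueTaxon)) {
        pruned <- pruneTaxa(tr, rogueTaxon)
        if (is.null(pruned$edge.length))
          pruned$edge.length <- rep(1, nrow(pruned$edge))
        e <- sample.int(nrow(pruned$edge), 1L)
        tr <- phytools::bind.tip(pruned, rogueTaxon,
                                 edge.length = rogueLen,
                                 where = pruned$edge[e, 2L],
                                 position = stats::runif(1L) * pruned$edge.length[e])
      }
      trees[[i]] <- tr
    }
    new("TreeSample", chain = paste0("chain", ci), trees = trees,
        burnin = 0, nTotal = as.integer(nSamples),
        source = "simulateTreeChains")
  })
}
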