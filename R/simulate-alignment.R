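#' @importFrom stats rexp runif rgamma rnorm setNames
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate an amino-acid alignment with planted compositional bias
#'
#' Simulates a 20-state Markov process along the tree under equal
#' exchangeabilities (F81-style): along a branch of length `t` a site of
#' relative rate `r` keeps its state with probability `exp(-beta * r * t)`
#' and is otherwise redrawn from the equilibrium frequencies, with `beta`
#' normalizing to one expected substitution per unit branch length.
#' Site-specific rates are gamma distributed with shape `gammaShape`
#' (mean 1).
#'
#' A fraction of sites, planted in contiguous blocks of `blockLen` columns
#' (compositionally deviant regions cluster locally in real alignments, which
#' is also what window-smoothed trimmers assume), is made compositionally
#' biased: on branches lying entirely inside `biasedClade`, those sites
#' evolve toward a perturbed equilibrium vector (log-normal perturbation of
#' magnitude `biasMagnitude`) with an additional rate boost `biasRateBoost`,
#' producing the clade-restricted, saturated heterogeneity that entropy/gap
#' trimming targets.
#'
#' @param tree `phylo` with branch lengths (substitutions/site)
#' @param nSites number of columns (>= 1)
#' @param cladeMap named character vector taxon -> clade (only needed when
#'   `biasedClade` is set)
#' @param biasedClade clade label to bias, or `NULL`
#' @param biasedFraction fraction of sites planted as biased, in [0,1]
#' @param gammaShape shape of the gamma rate distribution (mean 1)
#' @param biasMagnitude log-scale magnitude of the equilibrium perturbation
#' @param biasRateBoost extra substitution rate on biased sites within the
#'   biased clade (per unit branch length)
#' @param baseFreqs baseline equilibrium frequencies (default uniform)
#' @param blockLen length of planted biased blocks
#' @param seed optional RNG seed
#' @return list with `alignment` (character matrix taxa x sites) and `truth`
#'   (list: `biasedSites` 1-based column indices, `piBias`, `rates`, `seed`)
#' @export
simulateAlignment <- function(tree, nSites, cladeMap = NULL, biasedClade = NULL,
                              biasedFraction = 0, gammaShape = 1,
                              biasMagnitude = 1, biasRateBoost = 20,
                              baseFreqs = NULL, blockLen = 10L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (nSites < 1L) stop("nSites must be >= 1")
  if (biasedFraction < 0 || biasedFraction > 1)
    stop("biasedFraction must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseFreqs)) baseFreqs <- rep(1 / 20, 20)
  stopifnot(length(baseFreqs) == 20, all(baseFreqs > 0))
  pi0 <- baseFreqs / sum(baseFreqs)
  ntip <- length(tree$tip.label)

  biasedTaxa <- character(0)
  if (!is.null(biasedClade)) {
    if (is.null(cladeMap)) stop("biasedClade needs a cladeMap")
    if (!biasedClade %in% cladeMap) stop("unknown clade: ", biasedClade)
    biasedTaxa <- names(cladeMap)[cladeMap == biasedClade]
  }

  nBias <- round(biasedFraction * nSites)
  biasedSites <- integer(0)
  if (nBias > 0L) {
    starts <- seq(1L, nSites, by = blockLen)
    starts <- sample(starts)
    got <- integer(0)
    for (s in starts) {
      if (length(got) >= nBias) break
      got <- c(got, s:min(s + blockLen - 1L, nSites))
    }
    biasedSites <- sort(got[seq_len(nBias)])
  }
  isBias <- rep(FALSE, nSites)
  isBias[biasedSites] <- TRUE

  piB <- pi0 * exp(biasMagnitude * stats::rnorm(20))
  piB <- piB / sum(piB)
  beta0 <- 1 / (1 - sum(pi0^2))
  betaB <- 1 / (1 - sum(piB^2))

  rates <- if (is.finite(gammaShape))
    stats::rgamma(nSites, shape = gammaShape, rate = gammaShape)
  else rep(1, nSites)

  ## edges entirely inside the biased clade (terminal edges included)
  sets <- .cladeTipSetsAll(tree)
  edgeBias <- vapply(seq_len(nrow(tree$edge)), function(k) {
    tipsBelow <- tree$tip.label[sets[[tree$edge[k, 2L]]]]
    length(biasedTaxa) > 0L && all(tipsBelow %in% biasedTaxa)
  }, logical(1))

  states <- matrix(0L, ntip + tree$Nnode, nSites)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, nSites, replace = TRUE, prob = pi0)
  prr <- ape::reorder.phylo(tree, "cladewise")  # preorder: parents first
  for (k in seq_len(nrow(prr$edge))) {
    p <- prr$edge[k, 1L]; ch <- prr$edge[k, 2L]
    len <- prr$edge.length[k]
    kk <- which(tree$edge[, 2L] == ch)[1]
    st <- states[p, ]
    if (edgeBias[kk]) {
      pch <- ifelse(isBias,
                    1 - exp(-betaB * len * (rates + biasRateBoost)),
                    1 - exp(-beta0 * len * rates))
      redraw <- stats::runif(nSites) < pch
      if (any(redraw & isBias))
        st[redraw & isBias] <- sample.int(20L, sum(redraw & isBias),
                                          replace = TRUE, prob = piB)
      if (any(redraw & !isBias))
        st[redraw & !isBias] <- sample.int(20L, sum(redraw & !isBias),
                                           replace = TRUE, prob = pi0)
    } else {
      pch <- 1 - exp(-beta0 * len * rates)
      redraw <- stats::runif(nSites) < pch
      if (any(redraw))
        st[redraw] <- sample.int(20L, sum(redraw), replace = TRUE, prob = pi0)
    }
    states[ch, ] <- st
  }
  aln <- matrix(AA20[states[seq_len(ntip), , drop = FALSE]], ntip, nSites)
  rownames(aln) <- tree$tip.label
  list(alignment = aln,
       truth = list(biasedSites = biasedSites, piBias = piB,
                    rates = rates, seed = seed))
}

## tip-index sets below every node (tips and internals)
.cladeTipSetsAll <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (k in seq_len(nrow(tr$edge)))
    below[[tr$edge[k, 1L]]] <- c(below[[tr$edge[k, 1L]]], below[[tr$edge[k, 2L]]])
  below
}

#' Plant near-identical isoform tips in a gene family tree
#'
#' Duplicates each chosen tip with a tiny branch length `eps` and the label
#' `species@isoN`, emulating redundant transcriptome isoforms (near-identical
#' same-species sequences) that grooming must collapse.
#'
#' @param tree a gene family `phylo` with `species@seqid` tip labels
#' @param tips tip labels to duplicate
#' @param eps branch length of the planted isoform pair
#' @param delim species/sequence delimiter
#' @return list with `tree` and `planted` (the new isoform tip labels)
#' @export
plantIsoforms <- function(tree, tips, eps = 1e-6, delim = "@") {
  stopifnot(inherits(tree, "phylo"))
  planted <- character(0)
  for (tp in tips) {
    if (!tp %in% tree$tip.label) stop("not a tip: ", tp)
    sp <- strsplit(tp, delim, fixed = TRUE)[[1]][1]
    iso <- paste0(sp, delim, "iso", length(planted) + 2L)
    w <- which(tree$tip.label == tp)
    tree <- phytools::bind.tip(tree, iso, edge.length = eps, where = w,
                               position = eps)
    planted <- c(planted, iso)
  }
  list(tree = tree, planted = planted)
}
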