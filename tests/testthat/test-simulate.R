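test_that("species trees honour clade structure and seeds", {
  s <- simulateSpeciesTree(8, c(X = 4, Y = 4), seed = 7)
  expect_length(s$tree$tip.label, 8)
  for (cl in c("X", "Y"))
    expect_true(ape::is.monophyletic(s$tree,
                                     names(s$cladeMap)[s$cladeMap == cl]))
  s2 <- simulateSpeciesTree(8, c(X = 4, Y = 4), seed = 7)
  expect_identical(writeNewick(s$tree), writeNewick(s2$tree))
  expect_error(simulateSpeciesTree(8, c(X = 8, Y = 0), seed = 1), "size 0")
  expect_error(simulateSpeciesTree(3, seed = 1), "4 taxa")
})

test_that("mean tree height matches the closed-form Yule expectation", {
  set.seed(55)
  h <- replicate(600, {
    tr <- simulateSpeciesTree(10, rate = 2)$tree
    max(ape::node.depth.edgelength(tr)[1:10])
  })
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - yuleExpectedHeight(10, 2)), 3 * se)
})

test_that("gene families are congruent with the species tree without events", {
  sp <- simulateSpeciesTree(10, seed = 3)$tree
  fam <- simulateGeneFamily(sp, 0, 0, seed = 1)
  fam$tip.label <- sub("@c1$", "", fam$tip.label)
  expect_equal(splitDistance(ape::unroot(sp), ape::unroot(fam)), 0)
})

test_that("duplication without loss keeps every species represented", {
  sp <- simulateSpeciesTree(8, seed = 9)$tree
  set.seed(2)
  for (i in 1:10) {
    fam <- simulateGeneFamily(sp, 0.5, 0)
    species <- unique(sub("@.*$", "", fam$tip.label))
    expect_setequal(species, sp$tip.label)
    expect_gte(length(fam$tip.label), 8)
  }
})

test_that("mean family size matches the branching-process expectation", {
  sp <- simulateSpeciesTree(8, rate = 1, seed = 13)$tree
  set.seed(14)
  sizes <- replicate(400, {
    fam <- simulateGeneFamily(sp, 0.3, 0.2)
    if (is.null(fam)) 0L else length(fam$tip.label)
  })
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expectedFamilySize(sp, 0.3, 0.2)), 3 * se)
})

test_that("unbiased alignments are compositionally homogeneous", {
  sp <- simulateSpeciesTree(10, rate = 8, seed = 21)
  below <- replicate(40, {
    a <- simulateAlignment(sp$tree, 150)$alignment
    rep <- compositionReport(a)
    crit <- qchisq(0.95, (nrow(a) - 1) * 19)
    rep$statistic < crit
  })
  expect_gte(mean(below), 0.85)
})

test_that("small gamma shape lowers column entropy", {
  sp <- simulateSpeciesTree(10, rate = 2, seed = 22)
  eLow <- mean(siteEntropy(scoreSites(
    simulateAlignment(sp$tree, 300, gammaShape = 0.2, seed = 1)$alignment,
    smoothing = FALSE)))
  eHigh <- mean(siteEntropy(scoreSites(
    simulateAlignment(sp$tree, 300, gammaShape = 5, seed = 1)$alignment,
    smoothing = FALSE)))
  expect_lt(eLow, eHigh)
})

test_that("planted biased sites diverge more between clades than others", {
  sp <- simulateSpeciesTree(12, c(bg = 8, shifted = 4), rate = 8, seed = 23)
  sim <- simulateAlignment(sp$tree, 100, cladeMap = sp$cladeMap,
                           biasedClade = "shifted", biasedFraction = 0.3,
                           seed = 24)
  aln <- sim$alignment
  inCl <- rownames(aln) %in% names(sp$cladeMap)[sp$cladeMap == "shifted"]
  divergence <- vapply(seq_len(ncol(aln)), function(j) {
    a <- table(factor(aln[inCl, j], levels = phylomat:::AA20))
    b <- table(factor(aln[!inCl, j], levels = phylomat:::AA20))
    sum(abs(a / sum(a) - b / sum(b))) / 2
  }, numeric(1))
  w <- wilcox.test(divergence[sim$truth$biasedSites],
                   divergence[-sim$truth$biasedSites],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("chain simulation is degenerate at zero scatter and seeded", {
  ref <- simulateSpeciesTree(8, seed = 31)$tree
  ch <- simulateTreeChains(ref, nChains = 2, nSamples = 20, scatterProb = 0,
                           seed = 5)
  for (s in ch)
    for (tr in chainTrees(s))
      expect_equal(splitDistance(tr, ref), 0)
  ch2 <- simulateTreeChains(ref, nChains = 2, nSamples = 20, scatterProb = 0.3,
                            seed = 5)
  ch3 <- simulateTreeChains(ref, nChains = 2, nSamples = 20, scatterProb = 0.3,
                            seed = 5)
  expect_identical(lapply(chainTrees(ch2[[1]]), writeNewick),
                   lapply(chainTrees(ch3[[1]]), writeNewick))
  expect_error(simulateTreeChains(ref, rogueTaxon = "nope"), "not in tree")
})

test_that("a planted rogue reattaches uniformly over branches", {
  ref <- simulateSpeciesTree(12, seed = 33)$tree
  ch <- simulateTreeChains(ref, nChains = 1, nSamples = 1000, scatterProb = 0,
                           rogueTaxon = "t3", seed = 6)
  keys <- vapply(chainTrees(ch[[1]]), writeNewick, character(1),
                 lengths = FALSE)
  nEdges <- 2 * 11 - 3  # branches of the 11-taxon pruned reference
  tab <- table(keys)
  expect_equal(length(tab), nEdges)
  p0 <- 1 / nEdges
  se <- sqrt(p0 * (1 - p0) / 1000)
  expect_true(all(abs(tab / 1000 - p0) < 3 * se + 1e-9))
})
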