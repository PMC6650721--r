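test_that("raw entropy hits the analytic extremes", {
  inv <- matrix("A", 10, 1)
  expect_equal(siteEntropy(scoreSites(inv, smoothing = FALSE, window = 1)), 0)
  uni <- matrix(phylomat:::AA20, 20, 1)
  expect_equal(siteEntropy(scoreSites(uni, smoothing = FALSE, window = 1)), 1)
  allGap <- matrix("-", 10, 1)
  expect_equal(siteEntropy(scoreSites(allGap, window = 1)), 1)
  expect_equal(gapProportion(scoreSites(allGap, window = 1)), 1)
})

test_that("unsmoothed entropy equals the hand formula on arbitrary columns", {
  set.seed(91)
  for (i in 1:20) {
    col <- sample(phylomat:::AA20, 10, TRUE)
    sc <- scoreSites(matrix(col, 10, 1), smoothing = FALSE, window = 1)
    p <- table(col) / 10
    expect_equal(siteEntropy(sc), -sum(p * log(p)) / log(20))
  }
})

test_that("similarity smoothing scores mixtures of similar residues lower", {
  similar <- matrix(rep(c("I", "L", "V", "M"), 5), 20, 1)  # one Dayhoff group
  dissimilar <- matrix(rep(c("I", "D", "W", "K"), 5), 20, 1)
  sSim <- siteEntropy(scoreSites(similar, window = 1))
  sDis <- siteEntropy(scoreSites(dissimilar, window = 1))
  expect_lt(sSim, sDis)
})

test_that("trimming at permissive cutoffs is the identity", {
  set.seed(92)
  aln <- matrix(sample(phylomat:::AA20, 8 * 50, TRUE), 8, 50,
                dimnames = list(paste0("t", 1:8), NULL))
  out <- trimAlignment(aln, entropyCutoff = 1, gapCutoff = 1)
  expect_identical(out$alignment, aln)
})

test_that("gap-rich columns go regardless of entropy", {
  aln <- matrix("A", 10, 5, dimnames = list(paste0("t", 1:10), NULL))
  aln[, 3] <- "-"
  out <- trimAlignment(aln, entropyCutoff = 1, gapCutoff = 0.2)
  expect_equal(ncol(out$alignment), 4)
  expect_false(keepMask(out$scores)[3])
  expect_error(trimAlignment(matrix("-", 4, 3,
                                    dimnames = list(paste0("t", 1:4), NULL)),
                             0.5, 0.2), "relax")
})

test_that("raising the entropy cutoff keeps a superset of sites", {
  set.seed(93)
  sp <- simulateSpeciesTree(10, rate = 2, seed = 93)
  aln <- simulateAlignment(sp$tree, 200, gammaShape = 0.7)$alignment
  kept <- lapply(c(0.3, 0.5, 0.7, 1), function(ec)
    which(keepMask(trimAlignment(aln, ec, gapCutoff = 1)$scores)))
  for (i in 1:3) expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("planted biased sites are trimmed with little collateral", {
  recall <- collateral <- numeric(0)
  for (s in 1:5) {
    sp <- simulateSpeciesTree(16, c(bg = 8, shifted = 8), rate = 8, seed = s)
    sim <- simulateAlignment(sp$tree, 400, cladeMap = sp$cladeMap,
                             biasedClade = "shifted", biasedFraction = 0.2,
                             seed = s + 500)
    keep <- keepMask(trimAlignment(sim$alignment)$scores)
    b <- sim$truth$biasedSites
    recall <- c(recall, mean(!keep[b]))
    collateral <- c(collateral, mean(!keep[-b]))
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(collateral), 0.1)
})

test_that("partition tables shrink consistently with trimming", {
  set.seed(94)
  g1 <- matrix(sample(phylomat:::AA20, 6 * 30, TRUE), 6, 30,
               dimnames = list(paste0("t", 1:6), NULL))
  g2 <- matrix("A", 6, 20, dimnames = list(paste0("t", 1:6), NULL))
  sm <- concatenateGenes(list(g1 = g1, g2 = g2), paste0("t", 1:6))
  out <- trimAlignment(sm, entropyCutoff = 0.3, gapCutoff = 1,
                       smoothing = FALSE, window = 1)
  p <- partitionTable(out$alignment)
  expect_equal(sum(p$end - p$start), ncol(seqMatrix(out$alignment)))
  expect_true("g2" %in% p$gene)  # invariant gene survives whole
  expect_equal(p$end[p$gene == "g2"] - p$start[p$gene == "g2"], 20)
})

test_that("identical rows show zero compositional deviation", {
  aln <- matrix(rep(sample(phylomat:::AA20, 30, TRUE), each = 2), 2, 30,
                dimnames = list(c("a", "b"), NULL))
  rep <- compositionReport(aln)
  expect_equal(rep$perTaxon$deviation, c(0, 0))
  expect_equal(rep$statistic, 0)
})

test_that("a frequency-shifted clade is the most deviant and inflates the statistic", {
  hits <- 0L
  for (s in 1:20) {
    sp <- simulateSpeciesTree(16, c(A = 6, B = 6, shifted = 4), rate = 8,
                              seed = s)
    sim <- simulateAlignment(sp$tree, 300, cladeMap = sp$cladeMap,
                             biasedClade = "shifted", biasedFraction = 1,
                             seed = s + 700)
    rep <- compositionReport(sim$alignment, sp$cladeMap)
    ord <- rep$perClade$clade[which.max(rep$perClade$deviation)]
    hits <- hits + (ord == "shifted")
    ## removing the shifted clade lowers matrix-level heterogeneity even
    ## after accounting for the smaller matrix (per-residue statistic)
    keep <- rownames(sim$alignment)[sp$cladeMap[rownames(sim$alignment)] != "shifted"]
    repSub <- compositionReport(sim$alignment[keep, ], sp$cladeMap[keep])
    expect_lt(repSub$statistic, rep$statistic)
    expect_lt(repSub$statistic / sum(repSub$perTaxon$nResidues),
              rep$statistic / sum(rep$perTaxon$nResidues))
  }
  expect_gte(hits, 19L)
})

test_that("taxa without residues are excluded from the pooled statistic", {
  aln <- matrix("K", 3, 10, dimnames = list(c("a", "b", "empty"), NULL))
  aln["empty", ] <- "?"
  rep <- compositionReport(aln)
  expect_true(is.na(rep$perTaxon$deviation[3]))
  expect_equal(rep$statistic, 0)
})
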