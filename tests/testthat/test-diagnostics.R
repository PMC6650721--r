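test_that("chain loading applies the burn-in and reports bad lines", {
  trees <- replicate(10, randTree(6), simplify = FALSE)
  f <- withr::local_tempfile(fileext = ".trees")
  writeTreeList(trees, f)
  s <- loadChain(f, burninFraction = 0.2)
  expect_length(chainTrees(s), 8)
  expect_length(chainTrees(loadChain(f, burninFraction = 0)), 10)
  expect_error(loadChain(f, burninFraction = 1), "burninFraction")
  lines <- readLines(f)
  lines[7] <- "((a,b,;"
  writeLines(lines, f)
  expect_error(loadChain(f, 0), "line 7")
})

test_that("deviant tip sets within a chain are dropped, not fatal", {
  trees <- replicate(8, randTree(6), simplify = FALSE)
  odd <- pruneTaxa(trees[[1]], trees[[1]]$tip.label[1])
  f <- withr::local_tempfile(fileext = ".trees")
  writeTreeList(c(trees, list(odd)), f)
  expect_message(s <- loadChain(f, 0), "deviant tip sets")
  expect_length(chainTrees(s), 8)
})

test_that("split frequencies match hand counts and the brute-force oracle", {
  ref <- randTree(8)
  alt <- phangorn::rNNI(ref, 1)
  s <- mkSample(c(rep(list(ref), 6), rep(list(alt), 4)))
  bt <- splitFrequencies(list(s))
  refOnly <- setdiff(splitKeys(bipartitions(ref)), splitKeys(bipartitions(alt)))
  shared <- intersect(splitKeys(bipartitions(ref)), splitKeys(bipartitions(alt)))
  expect_true(all(splitFreq(bt)[refOnly, 1] == 0.6))
  expect_true(all(splitFreq(bt)[shared, 1] == 1.0))

  set.seed(111)
  for (i in 1:20) {
    trees <- replicate(15, phangorn::rNNI(ref, sample(0:2, 1)),
                       simplify = FALSE)
    bt <- splitFrequencies(list(mkSample(trees)))
    ## oracle: count each split by enumerating every tree independently
    counts <- table(unlist(lapply(trees, oracleSplitKeys)))
    expect_setequal(rownames(splitFreq(bt)), names(counts))
    expect_equal(splitFreq(bt)[names(counts), 1],
                 as.numeric(counts) / 15, ignore_attr = TRUE)
  }
})

test_that("mismatched chain taxon sets are an error listing the difference", {
  t1 <- randTree(6)
  t2 <- pruneTaxa(t1, t1$tip.label[1])
  expect_error(splitFrequencies(list(mkSample(list(t1)),
                                     mkSample(list(t2), "c2"))),
               t1$tip.label[1])
})

test_that("maxdiff is zero for identical chains and 0.5 for the NNI case", {
  T1 <- parseNewick("((A,B),(C,D),E);")
  T2 <- parseNewick("((A,C),(B,D),E);")
  same <- splitFrequencies(list(mkSample(list(T1, T1)),
                                mkSample(list(T1, T1), "c2")))
  expect_equal(maxdiff(same), 0)
  mixed <- splitFrequencies(list(mkSample(list(T1, T1)),
                                 mkSample(list(T1, T2), "c2")))
  expect_equal(maxdiff(mixed), 0.5)
  expect_error(maxdiff(splitFrequencies(list(mkSample(list(T1))))),
               "single chain")
})

test_that("maxdiff is invariant under chain permutation", {
  set.seed(112)
  ref <- randTree(8)
  ch <- simulateTreeChains(ref, nChains = 3, nSamples = 40, scatterProb = 0.3,
                           seed = 9)
  m1 <- maxdiff(splitFrequencies(ch))
  m2 <- maxdiff(splitFrequencies(rev(ch)))
  expect_equal(m1, m2)
})

test_that("identical samples give zero instability and no flags", {
  ref <- randTree(8)
  s <- mkSample(rep(list(ref), 25))
  rr <- rogueScores(list(s))
  expect_true(all(rogueScoresOf(rr) == 0))
  expect_length(flaggedTaxa(rr), 0)
})

test_that("a planted rogue is the top-scoring, sole flagged taxon", {
  ref <- simulateSpeciesTree(12, rate = 1, seed = 113)$tree
  ch <- simulateTreeChains(ref, nChains = 2, nSamples = 150,
                           scatterProb = 0.1, rogueTaxon = "t5", seed = 114)
  rr <- rogueScores(ch)
  expect_equal(names(which.max(rogueScoresOf(rr))), "t5")
  expect_identical(flaggedTaxa(rr), "t5")
})

test_that("consensus of identical samples is that tree with full support", {
  ref <- randTree(7)
  cons <- maskedConsensus(list(mkSample(rep(list(ref), 10))))
  expect_equal(splitDistance(ape::unroot(consensusPhylo(cons)),
                             ape::unroot(ref)), 0)
  expect_true(all(consensusSupport(cons) == 1))
})

test_that("a 0.6-frequency split enters the consensus with its annotation", {
  ref <- parseNewick("(((A,B),(C,D)),(E,F));")
  alt <- parseNewick("(((A,C),(B,D)),(E,F));")
  s <- mkSample(c(rep(list(ref), 6), rep(list(alt), 4)))
  cons <- maskedConsensus(list(s))
  key <- setdiff(splitKeys(bipartitions(ref)), splitKeys(bipartitions(alt)))
  expect_true(all(key %in% names(consensusSupport(cons))))
  expect_equal(unname(consensusSupport(cons)[key]), rep(0.6, length(key)))
  ## annotations ride along as node labels
  expect_true(any(grepl("0.6", consensusPhylo(cons)$node.label)))
})

test_that("consensus splits equal the pooled-frequency filter (oracle)", {
  set.seed(115)
  for (i in 1:20) {
    ref <- randTree(8)
    trees <- replicate(21, phangorn::rNNI(ref, sample(0:2, 1)),
                       simplify = FALSE)
    cons <- maskedConsensus(list(mkSample(trees)))
    counts <- table(unlist(lapply(trees, oracleSplitKeys)))
    want <- names(counts)[counts / 21 > 0.5]
    expect_setequal(names(consensusSupport(cons)), want)
    ## strict majority splits are mutually compatible, so the consensus
    ## tree itself must carry exactly them
    expect_setequal(splitKeys(bipartitions(consensusPhylo(cons))), want)
  }
})

test_that("consensus errors are specific", {
  ref <- randTree(6)
  s <- mkSample(rep(list(ref), 10))
  expect_error(maskedConsensus(list(s), mask = ref$tip.label[1:3]),
               "fewer than 4")
  expect_error(maskedConsensus(list(s), mask = "zz"), "not in samples")
})

test_that("report writers produce readable tables", {
  ref <- randTree(8)
  ch <- simulateTreeChains(ref, nChains = 2, nSamples = 15, scatterProb = 0.2,
                           seed = 7)
  bt <- splitFrequencies(ch)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeSplitTable(bt, f1)
  tab <- read.delim(f1, check.names = FALSE)
  expect_equal(nrow(tab), nrow(splitFreq(bt)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeConvergenceSummary(bt, character(0), f2)
  expect_equal(read.delim(f2)$maxdiff, maxdiff(bt))
})
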