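Package: phylomat
Title: Phylogenomic Supermatrix Construction and Posterior Convergence Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling partitioned amino-acid supermatrices from
    gene family trees and for diagnosing Bayesian posterior tree samples.
    Implements gene-tree grooming (redundant-isoform masking, divergent-tip
    removal, long-branch subfamily splitting), species-overlap orthology
    extraction from unrooted gene trees, occupancy- and clade-conditioned
    gene selection, entropy/gap-based site trimming targeting saturated and
    compositionally biased sites, Dayhoff-6 amino-acid recoding, and
    posterior diagnostics over MCMC tree samples: bipartition frequency
    tables, across-chain maxdiff, rogue-taxon detection and masking, and
    masked majority-rule consensus trees. A synthetic-data generator
    (species trees, duplication/loss gene families, compositionally biased
    alignments, tree-sample chains with planted rogue taxa) provides ground
    truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    phytools,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
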