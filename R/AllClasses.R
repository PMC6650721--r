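#' @import methods
NULL

#' Canonical set of unrooted bipartitions
#'
#' A set of non-trivial splits of an unrooted tree topology, stored in a
#' canonical encoding: for each split the side *not* containing the
#' lexicographically first taxon of the universe is kept, as a sorted
#' character vector. Splits are only comparable within one taxon universe;
#' trees missing universe taxa carry their own (restricted) universe.
#'
#' @slot universe sorted character vector of taxa the splits are defined over
#' @slot sides list of sorted character vectors, one per split (the canonical
#'   side); names are the split keys (taxa joined by `";"`)
#' @export
setClass("SplitSet", representation(universe = "character", sides = "list"))

setValidity("SplitSet", function(object) {
  u <- object@universe
  if (anyDuplicated(u)) return("duplicated taxa in universe")
  if (is.unsorted(u)) return("universe must be sorted")
  for (s in object@sides) {
    if (length(s) < 2L || length(s) > length(u) - 2L)
      return("trivial split: both sides must contain >= 2 taxa")
    if (!all(s %in% u)) return("split side contains taxa outside the universe")
    if (is.unsorted(s)) return("split side not sorted")
    if (u[1L] %in% s) return("split not canonical: side contains first universe taxon")
  }
  if (anyDuplicated(names(object@sides))) return("duplicated splits")
  TRUE
})

#' Partitioned amino-acid supermatrix
#'
#' A taxa-by-sites character matrix over the amino-acid alphabet plus `"-"`
#' (gap, aligned-but-deleted) and `"?"` (missing/absent), with a partition
#' table mapping gene ids to 0-based half-open site ranges.
#'
#' @slot seqs character matrix, rows = taxa (rownames), columns = sites
#' @slot partitions data.frame with columns `gene` (character), `start`,
#'   `end` (integer, 0-based half-open); ranges disjoint, contiguous and
#'   covering all columns
#' @slot label free-form matrix id (e.g. "M", "E", "S", "N")
#' @export
setClass("Supermatrix", representation(seqs = "matrix",
                                       partitions = "data.frame",
                                       label = "character"))

setValidity("Supermatrix", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxa (rownames) must be present and unique")
  p <- object@partitions
  need <- c("gene", "start", "end")
  if (!all(need %in% names(p))) return("partitions needs gene/start/end columns")
  if (nrow(p)) {
    o <- order(p$start)
    if (p$start[o][1L] != 0L) return("partitions must start at 0")
    if (p$end[o][nrow(p)] != ncol(m)) return("partitions must cover all sites")
    if (nrow(p) > 1L && any(p$end[o][-nrow(p)] != p$start[o][-1L]))
      return("partitions must be contiguous and disjoint")
    if (any(p$end <= p$start)) return("empty partition range")
  } else if (ncol(m) > 0L) return("non-empty matrix needs partitions")
  bad <- setdiff(unique(as.vector(m)), c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "?"))
  if (length(bad)) return(paste("illegal symbols:", paste(bad, collapse = " ")))
  TRUE
})

#' Per-site trimming scores
#'
#' @slot entropy raw per-site normalized entropy-like score in [0,1]
#' @slot smoothed window-smoothed score actually compared to the cutoff
#' @slot gapProp per-site proportion of gap/missing symbols
#' @slot keep logical keep mask
#' @export
setClass("SiteScores", representation(entropy = "numeric", smoothed = "numeric",
                                      gapProp = "numeric", keep = "logical"))

setValidity("SiteScores", function(object) {
  n <- length(object@entropy)
  if (length(object@smoothed) != n || length(object@gapProp) != n ||
      length(object@keep) != n) return("score vectors must share one length")
  if (any(object@gapProp < 0 | object@gapProp > 1)) return("gapProp outside [0,1]")
  TRUE
})

#' One chain of posterior tree samples
#'
#' @slot chain chain identifier
#' @slot trees list of `phylo` trees (post burn-in)
#' @slot burnin burn-in fraction already applied
#' @slot nTotal number of trees in the source before burn-in
#' @slot source source path or label
#' @export
setClass("TreeSample", representation(chain = "character", trees = "list",
                                      burnin = "numeric", nTotal = "integer",
                                      source = "character"))

setValidity("TreeSample", function(object) {
  if (!length(object@trees)) return("no post-burn-in trees")
  if (object@burnin < 0 || object@burnin >= 1) return("burnin must be in [0,1)")
  if (!all(vapply(object@trees, inherits, logical(1), "phylo")))
    return("trees must be phylo objects")
  TRUE
})

#' Per-chain bipartition frequency table
#'
#' @slot universe common taxon set (sorted)
#' @slot sides list of canonical split sides (as in [SplitSet])
#' @slot freq numeric matrix, splits x chains, frequencies in [0,1]; a split
#'   absent from a chain has frequency 0
#' @slot counts integer post-burn-in sample count per chain
#' @export
setClass("BipartitionTable", representation(universe = "character", sides = "list",
                                            freq = "matrix", counts = "integer"))

setValidity("BipartitionTable", function(object) {
  if (nrow(object@freq) != length(object@sides))
    return("freq rows must match splits")
  if (ncol(object@freq) != length(object@counts))
    return("freq columns must match chains")
  if (any(object@freq < 0 | object@freq > 1)) return("frequencies outside [0,1]")
  TRUE
})

#' Rogue-taxon report
#'
#' @slot scores named per-taxon instability score (>= 0)
#' @slot flagged taxa flagged for masking by the greedy resolution-gain search
#' @slot trace data.frame trace of the greedy search (taxon, gain, resolved)
#' @export
setClass("RogueReport", representation(scores = "numeric", flagged = "character",
                                       trace = "data.frame"))

setValidity("RogueReport", function(object) {
  if (any(object@scores < -1e-12)) return("instability scores must be >= 0")
  if (!all(object@flagged %in% names(object@scores)))
    return("flagged taxa outside the scored universe")
  TRUE
})

#' Majority-rule consensus with posterior probabilities
#'
#' @slot tree rooted-for-display `phylo`; internal node labels carry split
#'   frequencies (posterior probabilities)
#' @slot support numeric frequency per retained split, all > threshold
#' @slot masked taxa pruned from every sample before summarizing
#' @export
setClass("ConsensusTree", representation(tree = "ANY", support = "numeric",
                                         masked = "character"))

setValidity("ConsensusTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo")
  TRUE
})

#' @export
setMethod("show", "SplitSet", function(object) {
  cat("SplitSet:", length(object@sides), "non-trivial splits over",
      length(object@universe), "taxa\n")
})

#' @export
setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix '%s': %d taxa x %d sites, %d partitions\n",
              object@label, nrow(object@seqs), ncol(object@seqs),
              nrow(object@partitions)))
})

#' @export
setMethod("show", "TreeSample", function(object) {
  cat(sprintf("TreeSample '%s': %d trees (burn-in %.2f of %d)\n",
              object@chain, length(object@trees), object@burnin, object@nTotal))
})

#' @export
setMethod("show", "BipartitionTable", function(object) {
  cat(sprintf("BipartitionTable: %d splits x %d chains over %d taxa\n",
              nrow(object@freq), ncol(object@freq), length(object@universe)))
})

#' @export
setMethod("show", "RogueReport", function(object) {
  cat("RogueReport:", length(object@scores), "taxa scored;",
      length(object@flagged), "flagged:",
      paste(object@flagged, collapse = ", "), "\n")
})

#' @export
setMethod("show", "ConsensusTree", function(object) {
  cat(sprintf("ConsensusTree: %d taxa, %d supported splits, %d masked taxa\n",
              length(object@tree$tip.label), length(object@support),
              length(object@masked)))
})

## ---- accessors ----

#' Accessors for phylomat S4 containers
#'
#' `taxa()` returns the taxon set; `splitKeys()` the canonical split keys;
#' `splitSides()` the canonical sides; `seqMatrix()` the character matrix of a
#' Supermatrix; `partitionTable()` its partition table (0-based half-open);
#' `chainTrees()` a chain's tree list; `splitFreq()` the frequency matrix;
#' `rogueScoresOf()` / `flaggedTaxa()` the rogue report fields;
#' `consensusPhylo()` / `consensusSupport()` / `maskedTaxa()` the consensus
#' fields.
#'
#' @param x an object of the documented class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setMethod("taxa", "SplitSet", function(x) x@universe)
#' @rdname accessors
#' @export
setMethod("taxa", "Supermatrix", function(x) rownames(x@seqs))
#' @rdname accessors
#' @export
setMethod("taxa", "BipartitionTable", function(x) x@universe)

#' @rdname accessors
#' @export
splitKeys <- function(x) {
  if (is(x, "SplitSet") || is(x, "BipartitionTable")) names(x@sides)
  else stop("no splits in this object")
}

#' @rdname accessors
#' @export
splitSides <- function(x) x@sides

#' @rdname accessors
#' @export
seqMatrix <- function(x) { stopifnot(is(x, "Supermatrix")); x@seqs }

#' @rdname accessors
#' @export
partitionTable <- function(x) { stopifnot(is(x, "Supermatrix")); x@partitions }

#' @rdname accessors
#' @export
matrixLabel <- function(x) { stopifnot(is(x, "Supermatrix")); x@label }

#' @rdname accessors
#' @export
chainTrees <- function(x) { stopifnot(is(x, "TreeSample")); x@trees }

#' @rdname accessors
#' @export
chainId <- function(x) { stopifnot(is(x, "TreeSample")); x@chain }

#' @rdname accessors
#' @export
splitFreq <- function(x) { stopifnot(is(x, "BipartitionTable")); x@freq }

#' @rdname accessors
#' @export
chainCounts <- function(x) { stopifnot(is(x, "BipartitionTable")); x@counts }

#' @rdname accessors
#' @export
rogueScoresOf <- function(x) { stopifnot(is(x, "RogueReport")); x@scores }

#' @rdname accessors
#' @export
flaggedTaxa <- function(x) { stopifnot(is(x, "RogueReport")); x@flagged }

#' @rdname accessors
#' @export
gainTrace <- function(x) { stopifnot(is(x, "RogueReport")); x@trace }

#' @rdname accessors
#' @export
consensusPhylo <- function(x) { stopifnot(is(x, "ConsensusTree")); x@tree }

#' @rdname accessors
#' @export
consensusSupport <- function(x) { stopifnot(is(x, "ConsensusTree")); x@support }

#' @rdname accessors
#' @export
maskedTaxa <- function(x) { stopifnot(is(x, "ConsensusTree")); x@masked }

#' @rdname accessors
#' @export
keepMask <- function(x) { stopifnot(is(x, "SiteScores")); x@keep }

#' @rdname accessors
#' @export
siteEntropy <- function(x) { stopifnot(is(x, "SiteScores")); x@entropy }

#' @rdname accessors
#' @export
smoothedScore <- function(x) { stopifnot(is(x, "SiteScores")); x@smoothed }

#' @rdname accessors
#' @export
gapProportion <- function(x) { stopifnot(is(x, "SiteScores")); x@gapProp }
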