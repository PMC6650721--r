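## Gene-tree grooming: redundant-isoform masking, divergent-tip removal and
## long-branch subfamily splitting. The pipeline applies them in that order.

.speciesOf <- function(labels, delim = "@")
  vapply(strsplit(labels, delim, fixed = TRUE), `[[`, character(1), 1L)

## all candidate "sides" of the unrooted topology: the tip set below each
## edge and its complement (as tip indices)
.edgeSides <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- .cladeTipSetsAll(tree)
  sides <- list()
  for (k in seq_len(nrow(tree$edge))) {
    b <- below[[tree$edge[k, 2L]]]
    sides[[length(sides) + 1L]] <- b
    sides[[length(sides) + 1L]] <- setdiff(seq_len(ntip), b)
  }
  sides[!duplicated(vapply(sides, function(s) paste(sort(s), collapse = ","),
                           character(1)))]
}

#' Collapse redundant same-species isoform clades
#'
#' Every maximal tip set that is monophyletic on the unrooted topology and
#' consists of a single species (candidate redundant isoforms, e.g.
#' transcriptome splice variants) is collapsed to one representative; all
#' other structure is unchanged. The representative is the tip with the
#' longest ungapped sequence when `seqs` is supplied, otherwise the
#' lexicographically smallest sequence id.
#'
#' @param tree a gene family `phylo` with `species@seqid` tip labels
#' @param seqs optional named character vector of sequences (names = tip
#'   labels) used by the longest-sequence keep rule
#' @param delim species/sequence delimiter
#' @return a `phylo`; a family reduced to one sequence is returned as a
#'   degenerate single-tip tree
#' @export
maskRedundantIsoforms <- function(tree, seqs = NULL, delim = "@") {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (length(tips) <= 1L) return(tree)
  sp <- .speciesOf(tips, delim)
  if (length(unique(sp)) == 1L) {
    keep <- .isoformKeeper(tips, seqs)
    return(parseNewick(paste0("(", keep, ");")))
  }
  sides <- c(.edgeSides(tree), list(seq_along(tips)))
  mono <- Filter(function(s) length(s) >= 2L && length(unique(sp[s])) == 1L, sides)
  if (!length(mono)) return(tree)
  ## maximal same-species sides, made disjoint largest-first
  mono <- mono[order(-vapply(mono, length, integer(1)))]
  chosen <- list()
  used <- logical(length(tips))
  for (s in mono) {
    if (any(used[s])) next
    chosen[[length(chosen) + 1L]] <- s
    used[s] <- TRUE
  }
  drop <- character(0)
  for (s in chosen) {
    keep <- .isoformKeeper(tips[s], seqs)
    drop <- c(drop, setdiff(tips[s], keep))
  }
  if (!length(drop)) return(tree)
  if (length(tips) - length(drop) < 2L) {
    keep <- setdiff(tips, drop)
    return(parseNewick(paste0("(", keep[1L], ");")))
  }
  pruneTaxa(tree, drop)
}

.isoformKeeper <- function(labels, seqs) {
  if (!is.null(seqs) && all(labels %in% names(seqs))) {
    ungapped <- nchar(gsub("[-?]", "", seqs[labels]))
    return(labels[order(-ungapped, labels)][1L])
  }
  sort(labels)[1L]
}

#' Remove isolated divergent sequences
#'
#' Drops every tip whose terminal branch length exceeds `factor` times the
#' median terminal branch length (one pass, not iterated to a fixed point;
#' the median is robust to the very outliers being removed).
#'
#' @param tree a gene family `phylo` with branch lengths
#' @param factor multiplier (> 1) of the median terminal branch length
#' @return a `phylo`; if fewer than 4 tips remain it carries
#'   `attr(tree, "tooSmall") = TRUE`
#' @export
removeDivergentTips <- function(tree, factor = 10) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), factor > 1)
  ntip <- length(tree$tip.label)
  if (ntip < 3L) return(tree)
  term <- tree$edge[, 2L] <= ntip
  tlen <- numeric(ntip)
  tlen[tree$edge[term, 2L]] <- tree$edge.length[term]
  med <- stats::median(tlen)
  drop <- tree$tip.label[tlen > factor * med]
  out <- tree
  if (length(drop) && ntip - length(drop) >= 2L) out <- pruneTaxa(tree, drop)
  if (length(out$tip.label) < 4L) attr(out, "tooSmall") <- TRUE
  out
}

#' Split a gene family at long internal branches
#'
#' Cuts every internal edge longer than `cutoff` (absolute,
#' substitutions/site) and returns each resulting connected component as a
#' subfamily tree. Components with fewer than 4 tips are discarded; their
#' count and tips are attached as `attr(result, "discarded")`.
#'
#' @param tree a gene family `phylo` with branch lengths
#' @param cutoff absolute internal-branch-length cutoff (> 0)
#' @return list of `phylo` subfamilies (ordered by smallest tip label), with
#'   a `discarded` attribute
#' @export
splitLongBranches <- function(tree, cutoff = 1.5) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), cutoff > 0)
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > ntip
  cut <- which(internal & tree$edge.length > cutoff)
  if (!length(cut)) {
    out <- list(tree)
    attr(out, "discarded") <- list()
    return(out)
  }
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (k in setdiff(seq_len(nrow(tree$edge)), cut)) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(nn)
  nc <- 0L
  for (v in seq_len(nn)) {
    if (comp[v]) next
    nc <- nc + 1L
    queue <- v
    comp[v] <- nc
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      for (y in adj[[x]]) if (!comp[y]) { comp[y] <- nc; queue <- c(queue, y) }
    }
  }
  subs <- list()
  discarded <- list()
  for (ci in seq_len(nc)) {
    ctips <- tree$tip.label[which(comp[seq_len(ntip)] == ci)]
    if (length(ctips) >= 4L) {
      subs[[length(subs) + 1L]] <- ape::keep.tip(tree, ctips)
    } else if (length(ctips)) {
      discarded[[length(discarded) + 1L]] <- ctips
    }
  }
  subs <- subs[order(vapply(subs, function(t) min(t$tip.label), character(1)))]
  attr(subs, "discarded") <- discarded
  subs
}

#' Groom a gene family tree
#'
#' Applies the full grooming chain in its fixed order: isoform masking,
#' divergent-tip removal, long-branch splitting. Subfamilies flagged too
#' small are dropped.
#'
#' @param tree a gene family `phylo`
#' @param seqs optional sequences for the isoform keep rule
#' @param divergenceFactor see [removeDivergentTips()]
#' @param branchCutoff see [splitLongBranches()]
#' @param delim species/sequence delimiter
#' @return list of groomed subfamily `phylo` trees (possibly empty)
#' @export
groomFamily <- function(tree, seqs = NULL, divergenceFactor = 10,
                        branchCutoff = 1.5, delim = "@") {
  tr <- maskRedundantIsoforms(tree, seqs = seqs, delim = delim)
  if (length(tr$tip.label) < 4L) return(list())
  tr <- removeDivergentTips(tr, factor = divergenceFactor)
  if (isTRUE(attr(tr, "tooSmall"))) return(list())
  subs <- splitLongBranches(tr, cutoff = branchCutoff)
  attributes(subs) <- NULL
  subs
}
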