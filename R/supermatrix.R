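#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes are appended in the given order; a taxon absent from a gene is
#' padded with `"?"` across that gene's range. The partition table records
#' each gene's 0-based half-open site range.
#'
#' @param genes named list of character matrices (rows = taxa)
#' @param universe taxon list defining the supermatrix rows
#' @param label matrix id (e.g. "M", "E", "S", "N")
#' @return a [Supermatrix]
#' @export
concatenateGenes <- function(genes, universe, label = "M") {
  stopifnot(length(genes) > 0L, !is.null(names(genes)))
  lens <- integer(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    dup <- unique(rownames(g)[duplicated(rownames(g))])
    if (length(dup))
      stop(sprintf("gene %s: duplicate taxon %s", names(genes)[i], dup[1L]))
    bad <- setdiff(rownames(g), universe)
    if (length(bad))
      stop(sprintf("gene %s: taxon %s not in universe", names(genes)[i], bad[1L]))
    lens[i] <- ncol(g)
  }
  total <- sum(lens)
  m <- matrix("?", length(universe), total, dimnames = list(universe, NULL))
  end <- cumsum(lens)
  start <- c(0L, end[-length(end)])
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    m[rownames(g), (start[i] + 1L):end[i]] <- g
  }
  new("Supermatrix", seqs = m, label = label,
      partitions = data.frame(gene = names(genes), start = as.integer(start),
                              end = as.integer(end),
                              stringsAsFactors = FALSE))
}

#' Extract one gene's alignment back out of a supermatrix
#'
#' Inverse of [concatenateGenes()]: slices the gene's partition range and
#' drops taxa that are entirely missing (`"?"`) in it.
#'
#' @param sm a [Supermatrix]
#' @param gene gene id from the partition table
#' @return character matrix
#' @export
geneSlice <- function(sm, gene) {
  p <- partitionTable(sm)
  i <- match(gene, p$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  g <- seqMatrix(sm)[, (p$start[i] + 1L):p$end[i], drop = FALSE]
  g[rowSums(g != "?") > 0L, , drop = FALSE]
}

#' Per-taxon and per-gene occupancy
#'
#' A site is occupied for a taxon when its symbol is not `"?"`; gaps `"-"`
#' count as occupied (aligned but deleted), distinguishing gapped from absent
#' data. Per gene, occupancy is the number of taxa with at least one occupied
#' site in the gene's range.
#'
#' @param sm a [Supermatrix]
#' @return list with data.frames `perTaxon` (taxon, occupied, total,
#'   fraction) and `perGene` (gene, nTaxa, nSites)
#' @export
occupancyReport <- function(sm) {
  stopifnot(is(sm, "Supermatrix"))
  m <- seqMatrix(sm)
  occ <- m != "?"
  perTaxon <- data.frame(taxon = rownames(m), occupied = rowSums(occ),
                         total = ncol(m),
                         fraction = rowSums(occ) / max(1L, ncol(m)),
                         row.names = NULL, stringsAsFactors = FALSE)
  p <- partitionTable(sm)
  perGene <- data.frame(
    gene = p$gene,
    nTaxa = vapply(seq_len(nrow(p)), function(i)
      sum(rowSums(occ[, (p$start[i] + 1L):p$end[i], drop = FALSE]) > 0L),
      integer(1)),
    nSites = p$end - p$start, stringsAsFactors = FALSE)
  list(perTaxon = perTaxon, perGene = perGene)
}

#' Build a gene selection rule
#'
#' A conjunction of predicates over a gene's represented taxa ("represented"
#' = at least one occupied, non-`"?"` site): a minimum total taxon count,
#' minimum combined counts from clade sets, and required taxa.
#'
#' @param minTaxa minimum number of represented taxa
#' @param cladeMinima list of `list(clades = c(...), min = n)` entries; the
#'   combined count of taxa from those clades must reach `min`
#' @param requiredTaxa taxa that must all be represented
#' @return a `selectionRule` list
#' @export
selectionRule <- function(minTaxa = 0L, cladeMinima = list(),
                          requiredTaxa = character()) {
  stopifnot(minTaxa >= 0L,
            all(vapply(cladeMinima, function(x)
              is.list(x) && all(c("clades", "min") %in% names(x)) && x$min >= 0,
              logical(1))))
  structure(list(minTaxa = as.integer(minTaxa), cladeMinima = cladeMinima,
                 requiredTaxa = requiredTaxa), class = "selectionRule")
}

.presentTaxa <- function(g) rownames(g)[rowSums(g != "?") > 0L]

#' Select genes by occupancy and clade-conditioned rules
#'
#' Returns the genes satisfying every component of `rule`, preserving input
#' order. Strengthening any component never adds genes.
#'
#' @param genes named list of character matrices
#' @param cladeMap named character vector taxon -> clade
#' @param rule a [selectionRule()]
#' @return the selected subset of `genes`
#' @export
selectGenes <- function(genes, cladeMap, rule) {
  stopifnot(inherits(rule, "selectionRule"))
  for (cm in rule$cladeMinima) {
    unknown <- setdiff(cm$clades, unique(cladeMap))
    if (length(unknown))
      stop("unknown clade label: ", paste(unknown, collapse = ", "))
  }
  ok <- vapply(genes, function(g) {
    present <- .presentTaxa(g)
    if (length(present) < rule$minTaxa) return(FALSE)
    if (!all(rule$requiredTaxa %in% present)) return(FALSE)
    for (cm in rule$cladeMinima) {
      inClades <- sum(cladeMap[present] %in% cm$clades, na.rm = TRUE)
      if (inClades < cm$min) return(FALSE)
    }
    TRUE
  }, logical(1))
  genes[ok]
}

#' Informativeness score of a gene alignment
#'
#' The rank-and-cut proxy used in place of quartet-geometry matrix reduction:
#' `(n_taxa / |universe|) * n_sites * (1 - gap+missing fraction)`, where
#' `n_taxa` counts represented taxa and the gap+missing fraction is taken
#' over the gene's own rows.
#'
#' @param g character matrix
#' @param universe full taxon list
#' @return a single numeric score
#' @export
geneScore <- function(g, universe) {
  present <- .presentTaxa(g)
  gapMiss <- mean(g %in% c("-", "?"))
  (length(present) / length(universe)) * ncol(g) * (1 - gapMiss)
}

#' Rank genes by informativeness and keep the top k
#'
#' Genes are scored with [geneScore()], sorted in descending order (ties
#' broken by gene id) and the top `k` returned.
#'
#' @param genes named list of character matrices
#' @param k number of genes to keep (1 <= k <= length(genes))
#' @param universe full taxon list
#' @return the top-k subset of `genes`, in rank order
#' @export
rankGenes <- function(genes, k, universe) {
  if (k < 1L) stop("k must be >= 1")
  if (k > length(genes)) stop("k exceeds the number of genes")
  sc <- vapply(genes, geneScore, numeric(1), universe = universe)
  ord <- order(-sc, names(genes))
  genes[ord][seq_len(k)]
}

#' Pairwise Poisson-corrected distances from an alignment
#'
#' For each taxon pair, the proportion `p` of differing residues over sites
#' occupied (neither gap nor missing) in both rows, corrected for multiple
#' hits under a 20-state Poisson model: `d = -(19/20) log(1 - 20 p / 19)`.
#' Saturated pairs (`p >= 19/20`) are capped at the maximum finite distance
#' observed plus one. Pairs with no shared sites are an error.
#'
#' @param aln character matrix or [Supermatrix]
#' @param correction `"poisson"` (default) or `"none"` (raw p-distance)
#' @return symmetric numeric distance matrix
#' @export
alignmentDistances <- function(aln, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  n <- nrow(m)
  occ <- !(m %in% c("-", "?"))
  dim(occ) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- occ[i, ] & occ[j, ]
    if (!any(sh))
      stop(sprintf("no shared occupied sites between %s and %s",
                   rownames(m)[i], rownames(m)[j]))
    p <- mean(m[i, sh] != m[j, sh])
    d[i, j] <- d[j, i] <- if (correction == "none") p
      else if (p < 19 / 20) -(19 / 20) * log(1 - 20 * p / 19) else NA_real_
  }
  if (anyNA(d)) {
    cap <- max(d, na.rm = TRUE) + 1
    d[is.na(d)] <- cap
  }
  d
}
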