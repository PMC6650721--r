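#' Extract orthologue groups by unrooted phylogenetic orthology
#'
#' Species-overlap orthology parsing: both sides of every internal edge of
#' the unrooted gene family topology (its non-trivial bipartitions), plus the
#' full tip set, are evaluated; a side qualifies as an orthologue candidate
#' if no species occurs twice among its tips and it contains at least
#' `minTaxa` species. Single tips and their complements are not candidate
#' sides: a lone paralog hanging off a terminal edge does not certify the
#' rest of the family as orthologous. Maximal qualifying
#' sides (not properly contained in another qualifying side) are retained and
#' made mutually disjoint greedily, by descending species count with ties
#' broken lexicographically on the sorted sequence-id list — concatenation
#' needs one sequence per species per gene, so overlapping candidates must be
#' resolved.
#'
#' @param tree a gene family `phylo` with `species@seqid` tip labels
#' @param minTaxa minimum species count per group (>= 3)
#' @param delim species/sequence delimiter
#' @return list of orthologue groups, each a list with `seqIds`, `species`
#'   and `nSpecies`; possibly empty
#' @export
uphoParse <- function(tree, minTaxa = 3L, delim = "@") {
  stopifnot(inherits(tree, "phylo"), minTaxa >= 3L)
  tips <- tree$tip.label
  sp <- .speciesOf(tips, delim)
  if (length(tips) < minTaxa) return(list())
  ntip <- length(tips)
  sides <- Filter(function(s) length(s) >= 2L && length(s) <= ntip - 2L,
                  .edgeSides(tree))
  sides <- c(sides, list(seq_along(tips)))
  qual <- Filter(function(s) !anyDuplicated(sp[s]) && length(unique(sp[s])) >= minTaxa,
                 sides)
  if (!length(qual)) return(list())
  ## maximality: drop sides properly contained in another qualifying side
  keys <- lapply(qual, sort)
  isMax <- vapply(seq_along(qual), function(i) {
    !any(vapply(seq_along(qual), function(j)
      j != i && length(keys[[i]]) < length(keys[[j]]) &&
        all(keys[[i]] %in% keys[[j]]), logical(1)))
  }, logical(1))
  qual <- qual[isMax]
  ## greedy disjoint selection
  ord <- order(-vapply(qual, length, integer(1)),
               vapply(qual, function(s) paste(sort(tips[s]), collapse = ";"),
                      character(1)))
  qual <- qual[ord]
  used <- logical(length(tips))
  groups <- list()
  for (s in qual) {
    if (any(used[s])) next
    used[s] <- TRUE
    ids <- sort(tips[s])
    species <- sort(sp[s])
    stopifnot(!anyDuplicated(species))  # defining invariant
    groups[[length(groups) + 1L]] <-
      list(seqIds = ids, species = species, nSpecies = length(species))
  }
  groups
}

#' Extract per-group species-labelled alignments
#'
#' Subsets a family alignment (rows named by `species@seqid`) to each
#' orthologue group and renames rows to bare species names, yielding the
#' per-gene alignments a supermatrix is concatenated from.
#'
#' @param groups output of [uphoParse()]
#' @param familyAln character matrix with sequence-id rownames
#' @param delim species/sequence delimiter
#' @return named list of character matrices (one per group), rows = species
#' @export
orthologAlignments <- function(groups, familyAln, delim = "@") {
  out <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    missing <- setdiff(g$seqIds, rownames(familyAln))
    if (length(missing))
      stop("sequences absent from family alignment: ",
           paste(missing, collapse = ", "))
    m <- familyAln[g$seqIds, , drop = FALSE]
    rownames(m) <- .speciesOf(g$seqIds, delim)
    out[[paste0("g", i)]] <- m
  }
  out
}

#' Write orthologue groups as a TSV table
#'
#' Columns: `family_id`, `group_id`, `n_species`, `seq_ids`
#' (semicolon-joined).
#'
#' @param groups output of [uphoParse()]
#' @param familyId family identifier
#' @param path output path; appends when the file exists
#' @export
writeOrthologGroups <- function(groups, familyId, path) {
  rows <- lapply(seq_along(groups), function(i)
    data.frame(family_id = familyId, group_id = paste0(familyId, ".g", i),
               n_species = groups[[i]]$nSpecies,
               seq_ids = paste(groups[[i]]$seqIds, collapse = ";")))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
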