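#' Parse a Newick string into a phylo tree
#'
#' Thin, validating front-end to [ape::read.tree()]. Malformed input is
#' rejected with the character offset of the first problem; duplicate tip
#' labels are rejected by name. Internal node labels (e.g. support values)
#' are retained in `node.label`. A degenerate single-tip tree such as
#' `"(A);"` is accepted and flagged with `attr(tree, "degenerate")`.
#'
#' @param text a single Newick string, terminated by `";"`
#' @return an object of class `phylo`
#' @export
parseNewick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("parseNewick() expects a single character string")
  text <- trimws(text)
  if (!nzchar(text)) stop("parse error at offset 0: empty Newick input")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("parse error at offset %d: unbalanced ')'", i - 1L))
    }
  }
  if (depth > 0L)
    stop(sprintf("parse error at offset %d: %d unclosed '('",
                 length(chars) - 1L, depth))
  if (chars[length(chars)] != ";")
    stop(sprintf("parse error at offset %d: missing terminal ';'",
                 length(chars) - 1L))
  ## single-tip degenerate tree: ape cannot represent a 1-tip phylo edge
  ## matrix consistently across versions, so build it directly
  if (!grepl(",", text, fixed = TRUE)) {
    lab <- sub("^\\(*", "", sub("\\)*;$", "", text))
    len <- NA_real_
    if (grepl(":", lab, fixed = TRUE)) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
      lab <- parts[1]
      len <- suppressWarnings(as.numeric(parts[2]))
    }
    if (!nzchar(lab)) stop("parse error at offset 1: empty tip label")
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                         tip.label = lab, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    if (!is.na(len)) tr$edge.length <- len
    attr(tr, "degenerate") <- TRUE
    return(tr)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop(sprintf("parse error at offset 0: not a valid Newick string: %s",
                 substr(text, 1, 40)))
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("parse error: duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("parse error: negative branch length")
  tr
}

.childrenList <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (k in seq_len(nrow(tree$edge)))
    kids[[tree$edge[k, 1L]]] <- c(kids[[tree$edge[k, 1L]]], tree$edge[k, 2L])
  kids
}

.fmtLen <- function(x, digits) {
  s <- sprintf(paste0("%.", digits, "f"), x)
  s <- sub("0+$", "", s)
  ifelse(endsWith(s, "."), paste0(s, "0"), s)
}

#' Write a phylo tree as a canonical Newick string
#'
#' Deterministic output: at every internal node children are ordered by the
#' lexicographically smallest tip label they subtend, so topologically
#' identical trees always serialize to the identical string regardless of
#' their in-memory edge order. Branch lengths are written at `digits` decimal
#' places (trailing zeros trimmed, one decimal kept).
#'
#' @param tree a `phylo`
#' @param digits decimal places for branch lengths
#' @param lengths write branch lengths (if present)?
#' @param labels write internal node labels (if present)?
#' @return a single Newick string ending in `";"`
#' @export
writeNewick <- function(tree, digits = 6L, lengths = TRUE, labels = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    len <- if (lengths && !is.null(tree$edge.length))
      paste0(":", .fmtLen(tree$edge.length[1], digits)) else ""
    return(paste0("(", tree$tip.label, len, ");"))
  }
  kids <- .childrenList(tree)
  lens <- tree$edge.length
  edgeOf <- integer(ntip + tree$Nnode)
  edgeOf[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  nlab <- tree$node.label
  rec <- function(node) {
    if (node <= ntip)
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    parts <- lapply(kids[[node]], function(ch) {
      r <- rec(ch)
      s <- r$str
      if (lengths && !is.null(lens)) {
        e <- edgeOf[ch]
        if (!is.na(lens[e])) s <- paste0(s, ":", .fmtLen(lens[e], digits))
      }
      list(str = s, min = r$min)
    })
    ord <- order(vapply(parts, `[[`, character(1), "min"))
    lab <- ""
    if (labels && !is.null(nlab)) {
      l <- nlab[node - ntip]
      if (!is.na(l) && nzchar(l)) lab <- l
    }
    list(str = paste0("(", paste(vapply(parts[ord], `[[`, character(1), "str"),
                                 collapse = ","), ")", lab),
         min = min(vapply(parts, `[[`, character(1), "min")))
  }
  paste0(rec(ntip + 1L)$str, ";")
}

#' Read a one-tree-per-line Newick tree list
#'
#' The tree-sample dialect written by Bayesian phylogenetic samplers: one
#' Newick tree per line, optionally preceded by header lines to skip. Blank
#' lines are ignored; an unparseable line aborts with its line number.
#'
#' @param path file path
#' @param skip number of header lines to skip
#' @return list of `phylo`
#' @export
readTreeList <- function(path, skip = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (skip > 0L) lines <- lines[-seq_len(min(skip, length(lines)))]
  keep <- which(nzchar(trimws(lines)))
  trees <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    trees[[i]] <- tryCatch(parseNewick(lines[keep[i]]), error = function(e)
      stop(sprintf("line %d of %s: %s", keep[i] + skip, path, conditionMessage(e)),
           call. = FALSE))
  }
  trees
}

#' Write a list of trees as a one-tree-per-line Newick file
#'
#' @param trees list of `phylo`
#' @param path file path
#' @param digits decimal places for branch lengths
#' @export
writeTreeList <- function(trees, path, digits = 6L) {
  writeLines(vapply(trees, writeNewick, character(1), digits = digits), path)
  invisible(path)
}
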