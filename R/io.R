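## Readers/writers for the plain-text formats the pipeline exchanges:
## FASTA alignments (via Biostrings), clade-map TSV, relaxed PHYLIP and
## Nexus-style charset partition blocks.

#' Read an aligned FASTA file as a character matrix
#'
#' @param path FASTA path
#' @return character matrix, rows = sequences (names), columns = sites
#' @export
readFastaAlignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rows <- strsplit(toupper(as.character(ss)), "", fixed = TRUE)
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("sequences in ", path, " differ in length")
  m <- do.call(rbind, rows)
  rownames(m) <- sub("\\s.*$", "", names(ss))
  m
}

#' Write a character-matrix alignment as FASTA
#'
#' @param aln character matrix or [Supermatrix]
#' @param path output path
#' @export
writeFastaAlignment <- function(aln, path) {
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  ss <- Biostrings::BStringSet(apply(m, 1L, paste, collapse = ""))
  names(ss) <- rownames(m)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a taxon-to-clade map
#'
#' Two-column TSV (`taxon<TAB>clade`, no header). Every taxon must map to
#' exactly one clade.
#'
#' @param path TSV path
#' @return named character vector taxon -> clade
#' @export
readCladeMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("taxon", "clade"),
                          colClasses = "character")
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in clade map")
  stats::setNames(df$clade, df$taxon)
}

#' Write a taxon-to-clade map as TSV
#'
#' @param cladeMap named character vector taxon -> clade
#' @param path output path
#' @export
writeCladeMap <- function(cladeMap, path) {
  utils::write.table(data.frame(names(cladeMap), unname(cladeMap)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Sequential (default) or interleaved (the Bayesian MCMC tool's input
#' dialect). For reduced-alphabet data a `#NSTATES n` comment line can be
#' prepended to declare the state count of a generic multistate matrix.
#'
#' @param aln character matrix or [Supermatrix]
#' @param path output path
#' @param interleaved interleave in blocks of `blockWidth` sites?
#' @param blockWidth sites per interleaved block
#' @param nstates optional state count declared in a header comment
#' @export
writePhylip <- function(aln, path, interleaved = FALSE, blockWidth = 60L,
                        nstates = NULL) {
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(nstates)) writeLines(paste0("#NSTATES ", nstates), con)
  writeLines(paste(nrow(m), ncol(m)), con)
  pad <- formatC(rownames(m), width = max(nchar(rownames(m))) + 2L,
                 flag = "-")
  if (!interleaved) {
    writeLines(paste0(pad, apply(m, 1L, paste, collapse = "")), con)
  } else {
    starts <- seq(1L, ncol(m), by = blockWidth)
    for (b in seq_along(starts)) {
      cols <- starts[b]:min(starts[b] + blockWidth - 1L, ncol(m))
      block <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      writeLines(if (b == 1L) paste0(pad, block)
                 else paste0(strrep(" ", nchar(pad[1L])), block), con)
      if (b < length(starts)) writeLines("", con)
    }
  }
  invisible(path)
}

#' Write a Nexus-style charset partition block
#'
#' Site ranges are converted from the internal 0-based half-open convention
#' to the 1-based inclusive convention of Nexus output
#' (`charset gene = start+1 - end;`).
#'
#' @param sm a [Supermatrix]
#' @param path output path
#' @export
writeNexusCharsets <- function(sm, path) {
  stopifnot(is(sm, "Supermatrix"))
  p <- partitionTable(sm)
  lines <- c("#NEXUS", "begin sets;",
             sprintf("  charset %s = %d-%d;", p$gene, p$start + 1L, p$end),
             "end;")
  writeLines(lines, path)
  invisible(path)
}
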