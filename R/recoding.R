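#' The Dayhoff-6 recoding scheme
#'
#' Collapses the 20 amino acids into the six classical Dayhoff groups —
#' AGPST, C, DENQ, FWY, HKR, ILMV — to mask compositional and substitutional
#' heterogeneity. Each group is written as its alphabetically first member,
#' keeping recoded data inside the amino-acid alphabet. Ambiguity codes
#' (B, Z, J, X, U, O) map to `"?"`; `"-"` and `"?"` are preserved.
#'
#' @return a `recodingScheme` list with `name`, `map` and `nGroups`
#' @export
dayhoff6Scheme <- function() {
  groups <- list(A = c("A", "G", "P", "S", "T"), C = "C",
                 D = c("D", "E", "N", "Q"), F = c("F", "W", "Y"),
                 H = c("H", "K", "R"), I = c("I", "L", "M", "V"))
  map <- character(0)
  for (g in names(groups)) map[groups[[g]]] <- g
  map[c("B", "Z", "J", "X", "U", "O")] <- "?"
  map["-"] <- "-"; map["?"] <- "?"
  structure(list(name = "dayhoff6", map = map, nGroups = 6L),
            class = "recodingScheme")
}

#' Recode an alignment into a reduced alphabet
#'
#' Replaces every residue by its group symbol under `scheme`; `"-"` and
#' `"?"` are unchanged and dimensions are preserved, so a keep mask computed
#' on the original alphabet applies unchanged to the recoded alignment. A
#' symbol outside the scheme (and not an ambiguity or gap) is an error naming
#' the row, column and symbol.
#'
#' @param aln character matrix or [Supermatrix]
#' @param scheme a recoding scheme, default [dayhoff6Scheme()]
#' @return recoded object of the same class as the input
#' @export
recodeAlignment <- function(aln, scheme = dayhoff6Scheme()) {
  stopifnot(inherits(scheme, "recodingScheme"))
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  out <- scheme$map[m]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    rc <- arrayInd(bad, dim(m))
    stop(sprintf("symbol '%s' at row %s, column %d is outside scheme '%s'",
                 m[bad], rownames(m)[rc[1L]], rc[2L], scheme$name))
  }
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  if (is(aln, "Supermatrix"))
    return(new("Supermatrix", seqs = out, partitions = partitionTable(aln),
               label = matrixLabel(aln)))
  out
}
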