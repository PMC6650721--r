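## Entropy/gap site trimming targeting saturated and compositionally biased
## columns, in the spirit of block-mapping entropy trimmers: a normalized,
## similarity-aware column entropy smoothed over a window, combined with a
## gap/missing proportion cutoff.

.AA_IDX <- stats::setNames(seq_along(AA20), AA20)

## similarity kernel: convex combination of the identity and the
## row-normalized non-negative part of BLOSUM62 (diagonal included), so
## columns mixing biochemically similar residues score lower than columns
## mixing dissimilar ones
.blosumKernel <- function(weight = 0.3) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA20, AA20]
  K <- pmax(B, 0)
  K <- K / rowSums(K)
  (1 - weight) * diag(20) + weight * K
}

#' Score alignment columns for trimming
#'
#' Per column, the amino-acid frequency vector over informative (non-gap,
#' non-missing) symbols gives a raw score: Shannon entropy normalized by
#' `log(20)`, optionally computed on BLOSUM62-similarity-smoothed
#' frequencies. Raw scores are then smoothed by a centred moving average of
#' width `window` (shrinking at the edges); the gap proportion is the
#' fraction of `"-"`/`"?"` symbols. A column with no informative symbol
#' scores 1 (maximally uninformative).
#'
#' @param aln character matrix or [Supermatrix]
#' @param smoothing apply BLOSUM62 similarity smoothing to the frequencies?
#' @param window odd moving-average width (>= 1)
#' @param similarityWeight weight of the similarity kernel in [0,1]
#' @return a [SiteScores] (keep mask all-TRUE; set by [trimAlignment()])
#' @export
scoreSites <- function(aln, smoothing = TRUE, window = 3L,
                       similarityWeight = 0.3) {
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  if (!nrow(m) || !ncol(m)) stop("empty alignment")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  K <- if (smoothing) .blosumKernel(similarityWeight) else diag(20)
  ns <- ncol(m)
  idx <- .AA_IDX[m]
  dim(idx) <- dim(m)
  gap <- colMeans(is.na(idx))
  counts <- vapply(seq_len(20L), function(s)
    colSums(idx == s, na.rm = TRUE), numeric(ns))  # ns x 20
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = ns)
  ninf <- rowSums(counts)
  P <- counts / ifelse(ninf > 0, ninf, 1)
  Q <- P %*% K
  H <- -rowSums(ifelse(Q > 0, Q * log(Q), 0)) / log(20)
  raw <- ifelse(ninf > 0, H, 1)
  half <- (window - 1L) %/% 2L
  smoothed <- raw
  if (half > 0L) {
    cs <- cumsum(c(0, raw))
    lo <- pmax(seq_len(ns) - half, 1L)
    hi <- pmin(seq_len(ns) + half, ns)
    smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  new("SiteScores", entropy = raw, smoothed = smoothed, gapProp = gap,
      keep = rep(TRUE, ns))
}

#' Trim saturated/biased and gap-rich sites
#'
#' Keeps the sites whose smoothed entropy score is at most `entropyCutoff`
#' and whose gap/missing proportion is at most `gapCutoff`. A [Supermatrix]
#' input has its partition table updated consistently (empty partitions
#' dropped). Raising `entropyCutoff` always keeps a superset of sites.
#'
#' @param aln character matrix or [Supermatrix]
#' @param entropyCutoff smoothed-score cutoff in [0,1]
#' @param gapCutoff gap-proportion cutoff in [0,1]
#' @param smoothing,window,similarityWeight passed to [scoreSites()]
#' @return list with `alignment` (same class as input) and `scores`
#'   ([SiteScores] with the keep mask filled in)
#' @export
trimAlignment <- function(aln, entropyCutoff = 0.5, gapCutoff = 0.2,
                          smoothing = TRUE, window = 3L,
                          similarityWeight = 0.3) {
  stopifnot(entropyCutoff >= 0, entropyCutoff <= 1,
            gapCutoff >= 0, gapCutoff <= 1)
  sc <- scoreSites(aln, smoothing = smoothing, window = window,
                   similarityWeight = similarityWeight)
  keep <- sc@smoothed <= entropyCutoff & sc@gapProp <= gapCutoff
  if (!any(keep))
    stop("all sites removed; relax entropyCutoff/gapCutoff")
  sc@keep <- keep
  if (is(aln, "Supermatrix")) {
    p <- partitionTable(aln)
    kept <- vapply(seq_len(nrow(p)), function(i)
      sum(keep[(p$start[i] + 1L):p$end[i]]), integer(1))
    nz <- kept > 0L
    end <- cumsum(kept[nz])
    newP <- data.frame(gene = p$gene[nz],
                       start = as.integer(c(0L, end[-length(end)])),
                       end = as.integer(end), stringsAsFactors = FALSE)
    out <- new("Supermatrix", seqs = seqMatrix(aln)[, keep, drop = FALSE],
               partitions = newP, label = matrixLabel(aln))
  } else {
    out <- aln[, keep, drop = FALSE]
  }
  list(alignment = out, scores = sc)
}

#' Amino-acid composition heterogeneity report
#'
#' Per taxon: residue frequencies over its occupied sites and the mean
#' absolute deviation of those frequencies from the pooled (grand-mean)
#' frequencies. Per clade (when `cladeMap` is given): pooled equivalents.
#' The matrix-level statistic is chi-square-style: over taxa with data,
#' `sum((n_ts - N_t p_s)^2 / (N_t p_s))` for observed residue counts
#' `n_ts`, per-taxon totals `N_t` and pooled frequencies `p_s`. Taxa with
#' zero occupied sites get `NA` frequencies and are excluded from the
#' statistic.
#'
#' @param aln character matrix or [Supermatrix]
#' @param cladeMap optional named character vector taxon -> clade
#' @return list with `perTaxon` (data.frame), `perClade` (or NULL),
#'   `frequencies` (taxa x 20), and `statistic`
#' @export
compositionReport <- function(aln, cladeMap = NULL) {
  m <- if (is(aln, "Supermatrix")) seqMatrix(aln) else aln
  if (!nrow(m) || !ncol(m)) stop("empty alignment")
  counts <- t(apply(m, 1L, function(row)
    tabulate(.AA_IDX[row][!is.na(.AA_IDX[row])], 20L)))
  colnames(counts) <- AA20
  N <- rowSums(counts)
  pbar <- colSums(counts) / sum(counts)
  freqs <- counts / ifelse(N > 0, N, NA)
  dev <- rowMeans(abs(sweep(freqs, 2L, pbar)))
  has <- N > 0
  seen <- pbar > 0  # chi-square cells need non-zero expectation
  expct <- outer(N[has], pbar[seen])
  statistic <- sum((counts[has, seen, drop = FALSE] - expct)^2 / expct)
  perTaxon <- data.frame(taxon = rownames(m), nResidues = N,
                         deviation = dev, row.names = NULL,
                         stringsAsFactors = FALSE)
  perClade <- NULL
  if (!is.null(cladeMap)) {
    cl <- cladeMap[rownames(m)]
    agg <- rowsum(counts, cl, na.rm = TRUE)
    Nc <- rowSums(agg)
    fc <- agg / ifelse(Nc > 0, Nc, NA)
    perClade <- data.frame(clade = rownames(agg), nResidues = Nc,
                           deviation = rowMeans(abs(sweep(fc, 2L, pbar))),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  list(perTaxon = perTaxon, perClade = perClade, frequencies = freqs,
       statistic = statistic)
}
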