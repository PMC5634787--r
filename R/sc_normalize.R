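#' Sum transcript-level abundances to gene level
#'
#' @param transcript_matrix Transcripts × cells non-negative matrix with
#'   transcript IDs as rownames.
#' @param tx2gene Named character vector (or two-column data.frame
#'   `transcript`, `gene`) mapping every transcript to its gene.
#' @return Genes × cells matrix of summed abundances.
#' @export
sum_to_gene_level <- function(transcript_matrix, tx2gene) {
  if (is.data.frame(tx2gene)) {
    map <- stats::setNames(as.character(tx2gene[[2]]), as.character(tx2gene[[1]]))
  } else map <- tx2gene
  tx <- rownames(transcript_matrix)
  if (is.null(tx)) stop("transcript matrix needs rownames")
  missing <- setdiff(tx, names(map))
  if (length(missing))
    stop("unmapped transcripts: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  rowsum(transcript_matrix, group = map[tx])
}

#' Median-of-ratios size factors
#'
#' For every gene with a non-zero value in all cells, the per-cell ratio to
#' the gene's geometric mean is formed; a cell's size factor is the median
#' of these ratios.  Dividing each column by its factor yields normalized
#' TPM (nTPM).
#'
#' @param matrix Genes × cells non-negative matrix.
#' @param pseudocount Value added to every entry before the ratios are
#'   formed (default 0).  With heavy dropout no gene may be non-zero in
#'   every cell; a pseudocount of 1 makes all genes usable.
#' @return Per-cell numeric size factors.
#' @export
size_factors <- function(matrix, pseudocount = 0) {
  if (any(matrix < 0)) stop("expression values must be non-negative")
  if (pseudocount > 0) matrix <- matrix + pseudocount
  allpos <- rowSums(matrix == 0) == 0
  if (!any(allpos))
    stop("no gene is non-zero in every cell; consider adding a pseudocount (size_factors(..., pseudocount = 1))")
  lm <- log(matrix[allpos, , drop = FALSE])
  loggeo <- rowMeans(lm)
  apply(lm, 2, function(col) exp(stats::median(col - loggeo)))
}

#' Normalize an expression matrix by its size factors
#'
#' @param matrix Genes × cells non-negative matrix.
#' @param pseudocount Passed to [size_factors()].
#' @param factors Optional precomputed [size_factors()].
#' @return nTPM matrix (columns divided by their size factor).
#' @export
normalize_ntpm <- function(matrix, pseudocount = 0,
                           factors = size_factors(matrix, pseudocount)) {
  sweep(matrix, 2, factors, `/`)
}

#' Log transform with the nTPM < 1 zeroing rule
#'
#' Values below 1 are set to zero; values at or above 1 become
#' `log2(value)` (the boundary value 1 maps to 0 under either branch).
#'
#' @param ntpm Genes × cells nTPM matrix, non-negative.
#' @return log2-nTPM matrix.
#' @export
to_log2_ntpm <- function(ntpm) {
  if (any(ntpm < 0)) stop("nTPM values must be non-negative")
  out <- ntpm
  lo <- ntpm < 1
  out[lo] <- 0
  out[!lo] <- log2(ntpm[!lo])
  out
}

#' Variable-gene filter
#'
#' Keeps genes expressed (nTPM > 1) in strictly more than `min_cells` cells
#' whose cell-to-cell coefficient of variation of nTPM (zeros included)
#' strictly exceeds `cv_min`.
#'
#' @param ntpm Genes × cells nTPM matrix.
#' @param min_cells Expression-cell count threshold (strict `>`), default 2.
#' @param cv_min CV threshold (strict `>`), default 0.5.
#' @return Character vector of retained gene IDs (or integer indices when
#'   the matrix has no rownames).
#' @export
filter_variable_genes <- function(ntpm, min_cells = 2, cv_min = 0.5) {
  if (ncol(ntpm) < 3) stop("need at least 3 cells")
  ncell <- rowSums(ntpm > 1)
  mu <- rowMeans(ntpm)
  s <- apply(ntpm, 1, stats::sd)
  cv <- ifelse(mu > 0, s / mu, 0)
  keep <- ncell > min_cells & cv > cv_min
  if (is.null(rownames(ntpm))) which(keep) else rownames(ntpm)[keep]
}
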