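#' Principal component analysis of cells
#'
#' Genes are standardized (centered, unit variance) across cells before the
#' decomposition; zero-variance genes are dropped with a warning.  Each
#' component is oriented so that its largest-magnitude gene loading is
#' positive, making score signs reproducible.
#'
#' @param matrix Genes × cells log2-nTPM matrix.
#' @param genes Genes to use (IDs or indices); default all.
#' @return A list of class `sc_pca` with `scores` (cells × PCs),
#'   `loadings` (genes × PCs) and `variance_explained`.
#' @export
sc_pca <- function(matrix, genes = rownames(matrix)) {
  if (is.null(genes)) genes <- seq_len(nrow(matrix))
  x <- t(matrix[genes, , drop = FALSE])
  if (ncol(x) < 2 || nrow(x) < 3) stop("need at least 2 genes and 3 cells")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped before PCA")
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 genes with variance")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  structure(list(scores = p$x, loadings = p$rotation,
                 variance_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "sc_pca")
}

#' @export
print.sc_pca <- function(x, ...) {
  cat(sprintf("sc_pca: %d cells x %d components\n", nrow(x$scores), ncol(x$scores)))
  ve <- x$variance_explained[seq_len(min(5, length(x$variance_explained)))]
  cat("  variance explained:", paste(sprintf("%.1f%%", 100 * ve), collapse = ", "), "\n")
  invisible(x)
}

#' Genes most correlated with a principal component
#'
#' Pearson correlation of each gene's expression with the component score;
#' the `n_pos` most positively and `n_neg` most negatively correlated genes
#' are returned.  Ties break by gene ID (lexicographic).
#'
#' @param matrix Genes × cells log2-nTPM matrix.
#' @param pc_scores Per-cell component scores (finite).
#' @param n_pos,n_neg Number of genes from each tail, default 300 each.
#' @return Character vector of gene IDs (positive tail first).
#' @export
top_pc_correlated_genes <- function(matrix, pc_scores, n_pos = 300, n_neg = 300) {
  if (!all(is.finite(pc_scores))) stop("pc_scores must be finite")
  if (length(pc_scores) != ncol(matrix))
    stop("pc_scores length must equal the number of cells")
  if (n_pos + n_neg > nrow(matrix)) {
    warning("n_pos + n_neg exceeds the gene count; returning all genes")
    return(rownames(matrix))
  }
  s <- apply(matrix, 1, stats::sd)
  r <- rep(0, nrow(matrix))
  r[s > 0] <- suppressWarnings(
    as.numeric(stats::cor(t(matrix[s > 0, , drop = FALSE]), pc_scores)))
  ids <- rownames(matrix)
  pos <- ids[order(-r, ids)][seq_len(n_pos)]
  neg <- ids[order(r, ids)][seq_len(n_neg)]
  c(pos, neg)
}

#' Hierarchical clustering of cells (and genes)
#'
#' Cells: Euclidean distance on the selected genes' log2-nTPM profiles with
#' Ward linkage, tree cut at `k`.  Genes: correlation distance (1 - Pearson)
#' with average linkage, returned as a dendrogram for heatmap ordering.
#'
#' @param matrix Genes × cells log2-nTPM matrix.
#' @param genes Genes used for the cell distance; default all.
#' @param k Number of cell clusters, `2 <= k <= n_cells`.
#' @return A list of class `cluster_assignment` with `labels` (named
#'   integer vector in `1..k`), `k`, `cell_tree` and `gene_tree` (hclust).
#' @export
hierarchical_cluster <- function(matrix, genes = rownames(matrix), k = 2) {
  if (k < 2) stop("k must be at least 2")
  if (k > ncol(matrix)) stop("k cannot exceed the number of cells")
  if (is.null(genes)) genes <- seq_len(nrow(matrix))
  x <- t(matrix[genes, , drop = FALSE])
  cell_tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(cell_tree, k = k)
  gs <- apply(matrix[genes, , drop = FALSE], 1, stats::sd)
  gx <- matrix[genes, , drop = FALSE][gs > 0, , drop = FALSE]
  gene_tree <- if (nrow(gx) >= 3) {
    stats::hclust(stats::as.dist(1 - stats::cor(t(gx))), method = "average")
  } else NULL
  structure(list(labels = labels, k = k, cell_tree = cell_tree,
                 gene_tree = gene_tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Adjusted-free Rand index between two partitions
#'
#' Fraction of cell pairs on which two partitions agree; used to score
#' recovery of planted classes.
#'
#' @param a,b Two label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ta <- outer(a, a, `==`)
  tb <- outer(b, b, `==`)
  up <- upper.tri(ta)
  mean(ta[up] == tb[up])
}
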