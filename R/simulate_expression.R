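#' Simulate a TPM-like single-cell expression matrix with planted classes
#'
#' Cells belong to differentiated classes (by default two, emulating the
#' mitochondria-rich / ribosome-rich split of the embryonic endolymphatic
#' sac; a third, proliferating, subset may be added via
#' `class_proportions`).  Every gene has a lognormal baseline; each class
#' has a disjoint planted marker set whose values are multiplied by
#' `fold` in that class.  Per-cell lognormal scale factors emulate library
#' size differences and independent Bernoulli dropout zeroes entries.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param class_proportions Named numeric vector summing to 1 (class sizes).
#' @param n_markers Planted marker genes per class.
#' @param fold Marker fold change in its class (`>= 1`; 1 plants nothing).
#' @param dropout_rate Bernoulli dropout probability in `[0, 1)`.
#' @param bio_sdlog Cell-to-cell lognormal biological noise (sdlog).
#' @param scale_sdlog Per-cell scale-factor spread (sdlog).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A list with `matrix` (genes × cells, TPM-like) and `truth`
#'   (`cell_labels`, `marker_sets`, `fold_change`, `dropout_rate`,
#'   `scale_factors`).
#' @export
simulate_expression_matrix <- function(n_genes = 2000, n_cells = 100,
                                       class_proportions = c(MRC = 0.45, RRC = 0.55),
                                       n_markers = 50, fold = 8,
                                       dropout_rate = 0.1,
                                       bio_sdlog = 0.5, scale_sdlog = 0.3,
                                       seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (fold < 1) stop("marker fold change must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  k <- length(class_proportions)
  if (is.null(names(class_proportions)))
    names(class_proportions) <- paste0("class", seq_len(k))
  if (n_markers * k > n_genes)
    stop("more marker genes than genes in the matrix")
  rng <- local_rng(seed)
  counts <- floor(class_proportions * n_cells)
  counts[1] <- counts[1] + (n_cells - sum(counts))
  labels <- rng(sample(rep(names(class_proportions), counts)))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))
  marker_idx <- rng(sample(n_genes, n_markers * k))
  marker_sets <- split(gene_ids[marker_idx],
                       rep(names(class_proportions), each = n_markers))
  base <- rng(stats::rlnorm(n_genes, meanlog = log(5), sdlog = 1.2))
  base[marker_idx] <- rng(stats::runif(n_markers * k, 5, 50))
  fold_mat <- matrix(1, n_genes, n_cells)
  for (cl in names(class_proportions))
    fold_mat[match(marker_sets[[cl]], gene_ids), labels == cl] <- fold
  scale_factors <- rng(stats::rlnorm(n_cells, 0, scale_sdlog))
  noise <- rng(matrix(stats::rlnorm(n_genes * n_cells, 0, bio_sdlog),
                      n_genes, n_cells))
  m <- base * fold_mat * noise
  m <- sweep(m, 2, scale_factors, `*`)
  if (dropout_rate > 0) {
    drop <- rng(matrix(stats::runif(n_genes * n_cells) < dropout_rate,
                       n_genes, n_cells))
    m[drop] <- 0
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  names(labels) <- cell_ids
  names(scale_factors) <- cell_ids
  list(matrix = m,
       truth = list(cell_labels = labels, marker_sets = marker_sets,
                    fold_change = fold, dropout_rate = dropout_rate,
                    scale_factors = scale_factors))
}
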