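#' Cluster specificity scores for a gene
#'
#' The gene's cluster mean profile is normalized to a probability vector
#' `p`; the score for cluster `c` is `1 - JSdist(p, e_c)`, where `e_c` is
#' the indicator profile of cluster `c` and `JSdist` is the square root of
#' the Jensen-Shannon divergence with base-2 logarithms.  Scores lie in
#' `[0, 1]`: 1 means expression confined to that cluster, 0 means
#' expression confined elsewhere.
#'
#' @param cluster_means Non-negative per-cluster mean expression of one
#'   gene (not all zero), or a genes × clusters matrix.
#' @return Per-cluster scores (vector, or matrix matching the input).
#' @export
specificity_score <- function(cluster_means) {
  if (is.matrix(cluster_means))
    return(t(apply(cluster_means, 1, specificity_score)))
  if (any(cluster_means < 0)) stop("cluster means must be non-negative")
  tot <- sum(cluster_means)
  if (tot == 0) stop("all-zero gene: specificity undefined")
  p <- cluster_means / tot
  k <- length(p)
  vapply(seq_len(k), function(c) {
    e <- replace(numeric(k), c, 1)
    1 - sqrt(js_divergence(p, e))
  }, numeric(1))
}

# Jensen-Shannon divergence, base-2 logs (0 log 0 := 0); bounded by 1
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Differential expression between cell clusters
#'
#' Per gene, a two-sided rank-sum test between the two clusters (Kruskal-
#' Wallis for more than two), Benjamini-Hochberg correction across tested
#' genes, detection fractions (share of a cluster's cells with nTPM > 1)
#' and cluster specificity scores from the cluster mean nTPM profile.  A
#' gene is called for the cluster with the highest specificity when all
#' three criteria hold strictly: `q < fdr`, detection in the called cluster
#' `> detection_min`, and specificity `> specificity_min`.
#'
#' @param ntpm Genes × cells nTPM matrix.
#' @param labels Per-cell cluster labels (every cluster needs >= 3 cells).
#' @param fdr FDR threshold, default 0.05.
#' @param detection_min Detection-fraction threshold, default 0.5.
#' @param specificity_min Specificity threshold, default 0.5 (use 0.65 for
#'   four-group comparisons).
#' @return An object of class `de_result`: a data.frame per gene with mean
#'   log2 expression and detection per cluster, `p`, `q`, per-cluster
#'   specificity and `call` (`"none"` or a cluster label).
#' @export
differential_expression <- function(ntpm, labels, fdr = 0.05,
                                    detection_min = 0.5,
                                    specificity_min = 0.5) {
  labels <- as.character(labels)
  if (length(labels) != ncol(ntpm))
    stop("labels length must equal the number of cells")
  sizes <- table(labels)
  if (any(sizes < 3)) stop("every cluster needs at least 3 cells")
  cls <- names(sizes)
  glab <- factor(labels, levels = cls)
  testable <- rowSums(ntpm) > 0 & apply(ntpm, 1, stats::sd) > 0
  p <- rep(NA_real_, nrow(ntpm))
  if (length(cls) == 2) {
    i1 <- which(glab == cls[1]); i2 <- which(glab == cls[2])
    p[testable] <- apply(ntpm[testable, , drop = FALSE], 1, function(v)
      suppressWarnings(stats::wilcox.test(v[i1], v[i2], exact = FALSE)$p.value))
  } else {
    p[testable] <- apply(ntpm[testable, , drop = FALSE], 1, function(v)
      stats::kruskal.test(v, glab)$p.value)
  }
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  mean_log2 <- sapply(cls, function(cl)
    rowMeans(to_log2_ntpm(ntpm[, glab == cl, drop = FALSE])))
  detection <- sapply(cls, function(cl)
    rowMeans(ntpm[, glab == cl, drop = FALSE] > 1))
  cm <- sapply(cls, function(cl) rowMeans(ntpm[, glab == cl, drop = FALSE]))
  spec <- matrix(NA_real_, nrow(ntpm), length(cls),
                 dimnames = list(rownames(ntpm), cls))
  nz <- rowSums(cm) > 0
  spec[nz, ] <- specificity_score(cm[nz, , drop = FALSE])
  best <- cls[max.col(replace(spec, is.na(spec), -Inf), ties.method = "first")]
  called <- !is.na(q) & q < fdr &
    detection[cbind(seq_len(nrow(ntpm)), match(best, cls))] > detection_min &
    spec[cbind(seq_len(nrow(ntpm)), match(best, cls))] > specificity_min
  res <- data.frame(gene = rownames(ntpm) %||% seq_len(nrow(ntpm)),
                    p = p, q = q,
                    call = ifelse(called, best, "none"),
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(mean_log2) <- paste0("mean_log2.", cls)
  colnames(detection) <- paste0("detection.", cls)
  colnames(spec) <- paste0("specificity.", cls)
  out <- cbind(res, mean_log2, detection, spec)
  class(out) <- c("de_result", "data.frame")
  attr(out, "criteria") <- c(fdr = fdr, detection_min = detection_min,
                             specificity_min = specificity_min)
  out
}

#' @export
print.de_result <- function(x, ...) {
  cr <- attr(x, "criteria")
  cat(sprintf("de_result: %d genes tested, %d called (FDR < %g, detection > %g, specificity > %g)\n",
              sum(!is.na(x$q)), sum(x$call != "none"),
              cr["fdr"], cr["detection_min"], cr["specificity_min"]))
  print.data.frame(utils::head(x[x$call != "none", c("gene", "p", "q", "call")], 10),
                   digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher's exact enrichment of a gene set against an annotation table
#'
#' For each category, a one-sided hypergeometric test of the overlap
#' between the query set and the category within a reference gene universe,
#' with `fold_enrichment = (overlap / set size) / (category size /
#' reference size)` and Bonferroni correction over tested categories.
#'
#' @param gene_set Non-empty character vector of query genes.
#' @param annotation Two-column data.frame (`category`, `gene`).
#' @param reference_size Size of the reference gene universe (e.g. 22320
#'   for the mouse reference set).
#' @return A data.frame: `category`, `category_size`, `overlap`,
#'   `fold_enrichment`, `p`, `p_bonferroni`.
#' @export
enrichment_fisher <- function(gene_set, annotation, reference_size) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  gene_set <- unique(gene_set)
  cats <- split(as.character(annotation[[2]]), as.character(annotation[[1]]))
  n <- length(gene_set)
  res <- do.call(rbind, lapply(names(cats), function(cat) {
    K <- length(unique(cats[[cat]]))
    x <- length(intersect(gene_set, cats[[cat]]))
    data.frame(category = cat, category_size = K, overlap = x,
               fold_enrichment = (x / n) / (K / reference_size),
               p = stats::phyper(x - 1, K, reference_size - K, n,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res[order(res$p), ]
}

#' Single-cell qPCR cycle threshold to log2 expression
#'
#' `log2 expression = LOD - Ct`, floored at 0, with the limit of detection
#' set at Ct = 28 cycles.
#'
#' @param ct Positive Ct values.
#' @param lod Limit of detection in cycles, default 28.
#' @return log2 expression values in `[0, lod]`.
#' @export
ct_to_log2 <- function(ct, lod = 28) {
  if (any(ct <= 0)) stop("Ct values must be positive")
  pmax(lod - ct, 0)
}
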