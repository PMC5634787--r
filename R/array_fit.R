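#' Quantile normalization of an intensity matrix
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values; ties receive the mean of their ranks' values, and the
#' within-column rank order is preserved.  Delegates to
#' [limma::normalizeQuantiles()] with tie handling enabled.
#'
#' @param matrix Probes × samples numeric matrix without missing values.
#' @return Quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  if (anyNA(matrix)) stop("missing values: impute upstream")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Probe retention filter
#'
#' A probe is retained when it is called present in every one of the
#' required samples and when the sum of its mean intensities over the
#' required sample groups reaches `min_sum` (inclusive).
#'
#' @param matrix Probes × samples intensity matrix (linear scale for the
#'   intensity-sum rule).
#' @param present Logical probes × samples present-call matrix.
#' @param present_in Sample IDs (column names) over which the present rule
#'   applies; default all samples.
#' @param min_sum Intensity-sum threshold (`>=`), default 600.
#' @param sum_groups Optional factor/list grouping `present_in` samples;
#'   the rule sums the per-group mean intensities.  Default: one group
#'   (plain mean-sum over `present_in`).
#' @return Character vector of retained probe IDs.
#' @export
filter_probes <- function(matrix, present, present_in = colnames(matrix),
                          min_sum = 600, sum_groups = NULL) {
  unknown <- setdiff(present_in, colnames(matrix))
  if (length(unknown))
    stop("unknown samples in rule: ", paste(unknown, collapse = ", "))
  pres_ok <- rowSums(!present[, present_in, drop = FALSE]) == 0
  sub <- matrix[, present_in, drop = FALSE]
  if (is.null(sum_groups)) {
    isum <- rowMeans(sub)
  } else {
    gm <- sapply(split(seq_along(present_in), sum_groups), function(ix)
      rowMeans(sub[, ix, drop = FALSE]))
    isum <- rowSums(gm)
  }
  keep <- pres_ok & isum >= min_sum
  rownames(matrix)[keep]
}

#' Genotype-by-time polynomial regression for one probe
#'
#' Ordinary least squares of the probe's log2 intensity on
#' `[1, t, t^2, g, g*t, g*t^2]` with time centered at its mean and genotype
#' coded 0/1.  Reports the global F-test of all non-intercept terms and
#' the F-test of the genotype-involving terms against the time-only model.
#'
#' @param y Per-sample intensities (log2).
#' @param time Per-sample continuous time (e.g. embryonic day).
#' @param genotype Per-sample genotype with two levels (first level codes 0).
#' @return An object of class `probe_fit` with `coefficients` (named
#'   `intercept`, `t`, `t2`, `g`, `gt`, `gt2`), `global_p`, `genotype_p`,
#'   `r_squared`, `df_residual`.
#' @export
fit_probe_regression <- function(y, time, genotype) {
  n <- length(y)
  if (length(time) != n || length(genotype) != n)
    stop("y, time and genotype must have equal length")
  g <- if (is.numeric(genotype)) genotype else
    as.numeric(factor(genotype)) - 1
  if (length(unique(g)) != 2) stop("both genotypes must be present")
  if (length(unique(time)) < 3) stop("need at least 3 distinct times")
  if (n <= 6) stop("model has 6 parameters; need more than 6 samples")
  tc <- time - mean(time)
  X <- cbind(intercept = 1, t = tc, t2 = tc^2, g = g, gt = g * tc,
             gt2 = g * tc^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df_res <- n - ncol(X)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  # global F: all 5 non-intercept terms vs intercept-only
  global_p <- f_test_nested(tss, rss, 5, df_res)
  # genotype F: g, gt, gt2 vs time-only model
  rss_time <- sum(stats::lm.fit(X[, 1:3, drop = FALSE], y)$residuals^2)
  genotype_p <- f_test_nested(rss_time, rss, 3, df_res)
  structure(list(coefficients = fit$coefficients,
                 global_p = global_p, genotype_p = genotype_p,
                 r_squared = r2, df_residual = df_res,
                 time_center = mean(time)),
            class = "probe_fit")
}

f_test_nested <- function(rss0, rss1, df_num, df_den) {
  if (rss1 <= 0) return(if (rss0 > rss1) 0 else 1)
  f <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  stats::pf(f, df_num, df_den, lower.tail = FALSE)
}

#' @export
print.probe_fit <- function(x, ...) {
  cat("probe_fit: log2 intensity ~ time (linear+quadratic) x genotype\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  global p = %.3g, genotype p = %.3g, R^2 = %.3f\n",
              x$global_p, x$genotype_p, x$r_squared))
  invisible(x)
}

#' Fit the polynomial genotype-by-time model to every probe
#'
#' @param matrix Probes × samples log2 intensity matrix.
#' @param meta Sample metadata data.frame with `sample_id`, `genotype`,
#'   `time` matching the matrix columns.
#' @return A data.frame with one row per probe: the six coefficients,
#'   `global_p`, `genotype_p`, `r_squared`.
#' @export
fit_array_regression <- function(matrix, meta) {
  stopifnot(all(colnames(matrix) %in% meta$sample_id))
  meta <- meta[match(colnames(matrix), meta$sample_id), ]
  tc <- meta$time - mean(meta$time)
  g <- as.numeric(factor(meta$genotype)) - 1
  X <- cbind(intercept = 1, t = tc, t2 = tc^2, g = g, gt = g * tc,
             gt2 = g * tc^2)
  n <- ncol(matrix)
  df_res <- n - ncol(X)
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)
  B <- matrix %*% t(H)                       # probes x 6 coefficients
  fitted <- B %*% t(X)
  rss <- rowSums((matrix - fitted)^2)
  tss <- rowSums((matrix - rowMeans(matrix))^2)
  Xt <- X[, 1:3, drop = FALSE]
  Ht <- solve(crossprod(Xt)) %*% t(Xt)
  rss_time <- rowSums((matrix - (matrix %*% t(Ht)) %*% t(Xt))^2)
  global_p <- stats::pf(((tss - rss) / 5) / (rss / df_res), 5, df_res,
                        lower.tail = FALSE)
  genotype_p <- stats::pf(((rss_time - rss) / 3) / (rss / df_res), 3, df_res,
                          lower.tail = FALSE)
  out <- data.frame(probe = rownames(matrix), B,
                    global_p = global_p, genotype_p = genotype_p,
                    r_squared = ifelse(tss > 0, 1 - rss / tss, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "time_center") <- mean(meta$time)
  out
}

#' Select probes with significant time or genotype effects
#'
#' Benjamini-Hochberg correction is applied separately to the global and
#' the genotype F-test p-values.  Probes significant for both are the
#' genotype-by-time set; probes significant globally but not for genotype
#' are the time-only set.
#'
#' @param fits A [fit_array_regression()] data.frame.
#' @param fdr FDR threshold, default 0.05.
#' @return A list with `genotype_significant` and `time_significant`
#'   (probe ID vectors) plus the per-probe q-values.
#' @export
select_significant <- function(fits, fdr = 0.05) {
  if (nrow(fits) == 0)
    return(list(genotype_significant = character(0),
                time_significant = character(0),
                q_global = numeric(0), q_genotype = numeric(0)))
  qg <- stats::p.adjust(fits$global_p, "BH")
  qx <- stats::p.adjust(fits$genotype_p, "BH")
  sig_global <- qg < fdr
  sig_geno <- sig_global & qx < fdr
  list(genotype_significant = fits$probe[sig_geno],
       time_significant = fits$probe[sig_global & !sig_geno],
       q_global = qg, q_genotype = qx)
}

#' Cluster temporal expression profiles
#'
#' Per-probe mean profile over (genotype, time) cells, standardized to zero
#' mean and unit variance, hierarchically clustered (Euclidean, Ward) and
#' cut at `k`.  Clusters are renumbered 1..k by decreasing size so that the
#' gene-resolution rule ("a gene with probes in several clusters goes to
#' the smallest-numbered one") is well defined.
#'
#' @param matrix Probes × samples log2 intensity matrix.
#' @param probes Probe IDs to cluster.
#' @param meta Sample metadata (`sample_id`, `genotype`, `time`).
#' @param k Number of clusters, `1 <= k <= length(probes)`.
#' @param probe2gene Optional named vector mapping probes to genes; when
#'   given, gene clusters are resolved with the smallest-number rule.
#' @return A list of class `profile_clusters` with `probe_cluster` (named
#'   integer), `gene_cluster` (if mapped) and the `tree`.
#' @export
cluster_profiles <- function(matrix, probes, meta, k, probe2gene = NULL) {
  if (k < 1) stop("k must be at least 1")
  if (k > length(probes)) stop("k cannot exceed the number of probes")
  stopifnot(all(probes %in% rownames(matrix)))
  meta <- meta[match(colnames(matrix), meta$sample_id), ]
  cell <- interaction(meta$genotype, meta$time, drop = TRUE)
  prof <- t(apply(matrix[probes, , drop = FALSE], 1, function(v)
    tapply(v, cell, mean)))
  sds <- apply(prof, 1, stats::sd)
  std <- (prof - rowMeans(prof)) / ifelse(sds > 0, sds, 1)
  if (k == 1) {
    pc <- stats::setNames(rep(1L, length(probes)), probes)
    tree <- NULL
  } else {
    tree <- stats::hclust(stats::dist(std), method = "ward.D2")
    raw <- stats::cutree(tree, k = k)
    sizes <- tabulate(raw, k)
    renum <- match(seq_len(k), order(sizes, decreasing = TRUE))
    pc <- stats::setNames(renum[raw], probes)
  }
  gc <- NULL
  if (!is.null(probe2gene)) {
    gene <- probe2gene[probes]
    gc <- tapply(pc, gene, min)
    gc <- stats::setNames(as.integer(gc), names(gc))
  }
  structure(list(probe_cluster = pc, gene_cluster = gc, k = k, tree = tree),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: %d probes in %d clusters (sizes %s)\n",
              length(x$probe_cluster), x$k,
              paste(tabulate(x$probe_cluster, x$k), collapse = ", ")))
  if (!is.null(x$gene_cluster))
    cat(sprintf("  %d genes resolved by the smallest-number rule\n",
                length(x$gene_cluster)))
  invisible(x)
}
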