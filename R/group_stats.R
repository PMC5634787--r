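#' Grubbs' test for a single outlier
#'
#' Two-sided single-outlier Grubbs test: `G = max |x - mean| / sd` is
#' compared with the t-based critical value
#' `(n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))`, `t = qt(1 - alpha/(2n), n-2)`.
#' A single pass flags at most one observation; set `iterate = TRUE` to
#' re-test after removal.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level, default 0.05.
#' @param iterate Repeat until no further outlier is flagged.
#' @return Integer indices of flagged values (possibly empty).
#' @export
grubbs_test <- function(values, alpha = 0.05, iterate = FALSE) {
  n <- length(values)
  if (n < 3) stop("Grubbs' test needs at least 3 values")
  if (stats::sd(values) == 0) {
    warning("zero variance: no outlier can be flagged")
    return(integer(0))
  }
  flag_one <- function(idx) {
    x <- values[idx]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0) return(NA_integer_)
    g <- abs(x - mean(x)) / stats::sd(x)
    tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
    crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (max(g) > crit) idx[which.max(g)] else NA_integer_
  }
  out <- integer(0)
  keep <- seq_len(n)
  repeat {
    i <- flag_one(keep)
    if (is.na(i)) break
    out <- c(out, i)
    keep <- setdiff(keep, i)
    if (!iterate) break
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the `W` statistic
#' and p-value; constant input is signalled as an error.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return A list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("W is undefined for constant input")
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Cohen's d with pooled SD
#'
#' `d = (mean1 - mean2) / s_pooled`, `s_pooled^2 = ((n1-1) s1^2 +
#' (n2-1) s2^2) / (n1 + n2 - 2)`.  Accepts either two raw samples or two
#' summary triplets `c(mean, sd, n)`.
#'
#' @param g1,g2 Numeric vectors of raw values, or length-3 vectors
#'   `c(mean, sd, n)` when `summary = TRUE`.
#' @param summary Interpret `g1`, `g2` as summary statistics.
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(g1, g2, summary = FALSE) {
  if (summary) {
    stopifnot(length(g1) == 3, length(g2) == 3)
    m1 <- g1[1]; s1 <- g1[2]; n1 <- g1[3]
    m2 <- g2[1]; s2 <- g2[2]; n2 <- g2[3]
  } else {
    if (length(g1) < 2 || length(g2) < 2) stop("both groups need n >= 2")
    m1 <- mean(g1); s1 <- stats::sd(g1); n1 <- length(g1)
    m2 <- mean(g2); s2 <- stats::sd(g2); n2 <- length(g2)
  }
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero: d is undefined")
  unname((m1 - m2) / sqrt(sp2))
}

#' One-way ANOVA with all-pairwise Bonferroni t-tests
#'
#' Reproduces the study's group comparison: per-group Grubbs outlier screen
#' (optional), Shapiro-Wilk normality per group, one-way ANOVA F-test,
#' pairwise t-tests using the pooled within-group variance (the ANOVA mean
#' square error) with Bonferroni multiplication by the number of pairs, and
#' Cohen's d per pair.  A normality failure is reported, not fatal.
#'
#' @param groups Named list of numeric vectors, each `n >= 2`.
#' @param remove_outliers Apply [grubbs_test()] to each group first.
#' @param alpha Grubbs significance level.
#' @return An object of class `group_stats`; see Details.
#' @details The returned object carries `summary` (per-group n, mean, sd),
#' `outliers_removed`, `shapiro_p`, `anova_F`, `anova_df`, `anova_p`, a
#' `pairwise` data.frame (group_i, group_j, t, raw_p, bonferroni_p,
#' cohens_d) and the cleaned data.
#' @export
one_way_anova_bonferroni <- function(groups, remove_outliers = FALSE,
                                     alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  removed <- lapply(groups, function(x) integer(0))
  if (remove_outliers) {
    removed <- lapply(groups, function(x)
      if (length(x) >= 3) suppressWarnings(grubbs_test(x, alpha)) else integer(0))
    groups <- Map(function(x, idx) if (length(idx)) x[-idx] else x,
                  groups, removed)
    if (any(vapply(groups, length, 1L) < 2))
      stop("outlier removal left a group with n < 2")
  }
  k <- length(groups)
  nn <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  sds <- vapply(groups, stats::sd, 1)
  shapiro_p <- vapply(groups, function(x)
    if (length(x) >= 3 && stats::sd(x) > 0) shapiro_wilk(x)$p else NA_real_, 1)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), nn), levels = names(groups))
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  pairs <- utils::combn(names(groups), 2)
  npairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(npairs), function(i) {
    gi <- pairs[1, i]; gj <- pairs[2, i]
    se <- sqrt(mse * (1 / nn[gi] + 1 / nn[gj]))
    tval <- (means[gi] - means[gj]) / se
    raw <- 2 * stats::pt(abs(tval), df_err, lower.tail = FALSE)
    data.frame(group_i = gi, group_j = gj, t = tval, raw_p = raw,
               bonferroni_p = min(1, raw * npairs),
               cohens_d = cohens_d(groups[[gi]], groups[[gj]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(
    summary = data.frame(group = names(groups), n = nn, mean = means,
                         sd = sds, shapiro_p = shapiro_p,
                         row.names = NULL, stringsAsFactors = FALSE),
    outliers_removed = removed,
    anova_F = an["g", "F value"], anova_df = c(an["g", "Df"], df_err),
    anova_p = an["g", "Pr(>F)"],
    pairwise = pw, groups = groups),
    class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("One-way ANOVA with Bonferroni pairwise t-tests\n")
  print(x$summary, digits = 4)
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n",
              x$anova_df[1], x$anova_df[2], x$anova_F, x$anova_p))
  print(x$pairwise, digits = 4)
  invisible(x)
}
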