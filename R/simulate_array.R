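#' Simulate a genotype-by-time expression array matrix
#'
#' Probes × samples log2-scale intensities over a factorial design of
#' embryonic ages and two genotypes with replicates.  Each probe is `null`
#' (intercept only), `time_only` (linear and quadratic time terms) or
#' `genotype_by_time` (additionally a genotype offset and genotype × time
#' interactions); Gaussian noise is added and all present flags are true.
#' Time is centered before the polynomial is evaluated, matching the
#' fitting convention.
#'
#' @param n_probes Number of probes.
#' @param times Embryonic ages, default `c(13.5, 14.5, 16.5, 17.5)`.
#' @param n_reps Replicates per genotype × time, default 3.
#' @param prop Named proportions of probe classes
#'   (`null`, `time_only`, `genotype_by_time`), summing to 1.
#' @param effect_size Scale of non-null coefficients (log2 units).
#' @param noise_sd Gaussian noise SD (log2 units), `>= 0`.
#' @param seed Integer seed.
#' @return A list with `matrix` (probes × samples), `meta` (data.frame
#'   `sample_id`, `genotype`, `time`, `replicate`), `present` (logical
#'   matrix) and `truth` (`probe_class`, `coefficients`, `noise_sd`).
#' @export
simulate_array_timecourse <- function(n_probes = 2000,
                                      times = c(13.5, 14.5, 16.5, 17.5),
                                      n_reps = 3,
                                      prop = c(null = 1, time_only = 0,
                                               genotype_by_time = 0),
                                      effect_size = 1,
                                      noise_sd = 0.25,
                                      seed = 1L) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (abs(sum(prop) - 1) > 1e-8) stop("probe-class proportions must sum to 1")
  rng <- local_rng(seed)
  meta <- expand.grid(replicate = seq_len(n_reps), time = times,
                      genotype = c("het", "homo"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_E%.1f_r%d", meta$genotype, meta$time,
                            meta$replicate)
  meta <- meta[, c("sample_id", "genotype", "time", "replicate")]
  n_s <- nrow(meta)
  cls <- rng(sample(names(prop), n_probes, replace = TRUE, prob = prop))
  tc <- meta$time - mean(unique(times))
  g <- as.numeric(meta$genotype == "homo")
  coefs <- matrix(0, n_probes, 6,
                  dimnames = list(NULL, c("intercept", "t", "t2", "g", "gt", "gt2")))
  coefs[, "intercept"] <- rng(stats::rnorm(n_probes, 8, 1.5))
  nt <- cls != "null"
  coefs[nt, "t"]  <- rng(stats::rnorm(sum(nt), 0, effect_size))
  coefs[nt, "t2"] <- rng(stats::rnorm(sum(nt), 0, effect_size / 2))
  gb <- cls == "genotype_by_time"
  coefs[gb, "g"]   <- rng(stats::rnorm(sum(gb), 0, effect_size))
  coefs[gb, "gt"]  <- rng(stats::rnorm(sum(gb), 0, effect_size))
  coefs[gb, "gt2"] <- rng(stats::rnorm(sum(gb), 0, effect_size / 2))
  X <- cbind(1, tc, tc^2, g, g * tc, g * tc^2)
  signal <- coefs %*% t(X)
  m <- signal + rng(matrix(stats::rnorm(n_probes * n_s, 0, noise_sd),
                           n_probes, n_s))
  rownames(m) <- sprintf("probe%05d", seq_len(n_probes))
  colnames(m) <- meta$sample_id
  present <- matrix(TRUE, n_probes, n_s, dimnames = dimnames(m))
  rownames(coefs) <- rownames(m)
  list(matrix = m, meta = meta, present = present,
       truth = list(probe_class = stats::setNames(cls, rownames(m)),
                    coefficients = coefs, noise_sd = noise_sd))
}
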