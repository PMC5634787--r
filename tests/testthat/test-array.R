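test_that("quantile normalization matches the hand-computed example", {
  m <- cbind(s1 = c(1, 3), s2 = c(4, 2))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(1.5, 3.5), c(3.5, 1.5)))
  # identical columns unchanged
  m2 <- cbind(a = c(2, 5, 9), b = c(2, 5, 9))
  expect_equal(unname(quantile_normalize(m2)), unname(m2))
  # post-normalization all columns share the same sorted values
  set.seed(13)
  m3 <- matrix(rnorm(300), 100, 3)
  qn3 <- quantile_normalize(m3)
  expect_equal(sort(qn3[, 1]), sort(qn3[, 2]))
  expect_equal(order(qn3[, 3]), order(m3[, 3]))   # ranks preserved
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("probe filter applies present and intensity-sum rules", {
  m <- matrix(800, 10, 4, dimnames = list(sprintf("p%02d", 1:10),
                                          c("a1", "a2", "b1", "b2")))
  pres <- matrix(TRUE, 10, 4, dimnames = dimnames(m))
  pres["p03", "a2"] <- FALSE          # fails the present rule
  m["p07", ] <- 100                   # mean 100 < 600
  m["p08", ] <- 600                   # exactly at the threshold: kept
  kept <- filter_probes(m, pres, min_sum = 600)
  expect_false("p03" %in% kept)
  expect_false("p07" %in% kept)
  expect_true("p08" %in% kept)
  expect_length(kept, 8)
  expect_error(filter_probes(m, pres, present_in = c("a1", "zz")), "unknown")
})

test_that("single-probe regression recovers exact signals", {
  meta <- expand.grid(replicate = 1:3, time = c(13.5, 14.5, 16.5, 17.5),
                      genotype = c("het", "homo"), stringsAsFactors = FALSE)
  tc <- meta$time - mean(c(13.5, 14.5, 16.5, 17.5))
  g <- as.numeric(meta$genotype == "homo")
  # y = 2 t exactly
  f <- fit_probe_regression(2 * tc, meta$time, meta$genotype)
  expect_equal(unname(f$coefficients["t"]), 2, tolerance = 1e-10)
  expect_equal(unname(f$coefficients[c("g", "gt", "gt2")]), rep(0, 3),
               tolerance = 1e-10)
  expect_lt(f$global_p, 1e-12)
  # y = genotype offset exactly
  f2 <- fit_probe_regression(1 * g, meta$time, meta$genotype)
  expect_equal(unname(f2$coefficients["g"]), 1, tolerance = 1e-10)
  expect_lt(f2$genotype_p, 1e-12)
  # polynomial recovered to machine precision
  y <- 3 + tc - 0.5 * tc^2
  f3 <- fit_probe_regression(y, meta$time, meta$genotype)
  expect_equal(unname(f3$coefficients[1:3]), c(3, 1, -0.5), tolerance = 1e-8)
  expect_error(fit_probe_regression(y, meta$time, rep("het", 24)),
               "both genotypes")
  expect_error(fit_probe_regression(y, rep(c(1, 2), 12), meta$genotype),
               "collinear|distinct")
})

test_that("matrix regression agrees with per-probe lm fits", {
  sim <- simulate_array_timecourse(n_probes = 50,
                                   prop = c(null = 0.5, time_only = 0.3,
                                            genotype_by_time = 0.2),
                                   seed = 14)
  fits <- fit_array_regression(sim$matrix, sim$meta)
  i <- 7
  ref <- fit_probe_regression(sim$matrix[i, ], sim$meta$time,
                              sim$meta$genotype)
  expect_equal(as.numeric(fits[i, names(ref$coefficients)]),
               unname(ref$coefficients), tolerance = 1e-10)
  expect_equal(fits$global_p[i], ref$global_p, tolerance = 1e-12)
  expect_equal(fits$genotype_p[i], ref$genotype_p, tolerance = 1e-12)
})

test_that("noise-free probes recover their true coefficients", {
  sim <- simulate_array_timecourse(n_probes = 40,
                                   prop = c(null = 0, time_only = 0.5,
                                            genotype_by_time = 0.5),
                                   noise_sd = 0, seed = 15)
  fits <- fit_array_regression(sim$matrix, sim$meta)
  B <- as.matrix(fits[, c("intercept", "t", "t2", "g", "gt", "gt2")])
  expect_equal(unname(B), unname(sim$truth$coefficients), tolerance = 1e-8)
})

test_that("null F-test p-values are uniform", {
  sim <- simulate_array_timecourse(n_probes = 2000, seed = 16)
  fits <- fit_array_regression(sim$matrix, sim$meta)
  ks <- suppressWarnings(ks.test(fits$global_p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH selection controls the null and finds strong genotype effects", {
  # all-null: expected false selections <= 0.05 * n
  sim0 <- simulate_array_timecourse(n_probes = 2000, seed = 17)
  sel0 <- select_significant(fit_array_regression(sim0$matrix, sim0$meta))
  expect_lte(length(sel0$genotype_significant) +
               length(sel0$time_significant), 0.05 * 2000)
  # strong planted effects: high recall, split into the two reported sets
  sim1 <- simulate_array_timecourse(
    n_probes = 600, prop = c(null = 0.6, time_only = 0.2,
                             genotype_by_time = 0.2),
    effect_size = 1.5, noise_sd = 0.3, seed = 18)
  sel1 <- select_significant(fit_array_regression(sim1$matrix, sim1$meta))
  truth <- sim1$truth$probe_class
  gb <- names(truth)[truth == "genotype_by_time"]
  expect_gte(mean(gb %in% sel1$genotype_significant), 0.9)
  expect_length(intersect(sel1$genotype_significant, sel1$time_significant), 0)
  # empty input
  empty <- select_significant(fit_array_regression(
    sim1$matrix, sim1$meta)[0, ])
  expect_length(empty$genotype_significant, 0)
})

test_that("profile clustering separates rising from falling probes", {
  sim <- simulate_array_timecourse(n_probes = 80, noise_sd = 0.1, seed = 19)
  m <- sim$matrix
  rising <- 1:40; falling <- 41:80
  tc <- sim$meta$time - mean(sim$meta$time)
  m[rising, ] <- 8 + rep(tc, each = 40) + m[rising, ] * 0.01
  m[falling, ] <- 8 - rep(tc, each = 40) + m[falling, ] * 0.01
  cl <- cluster_profiles(m, rownames(m), sim$meta, k = 2)
  truth <- rep(1:2, each = 40)
  expect_gte(rand_index(cl$probe_cluster, truth), 0.95)
  # clusters are numbered by decreasing size
  cl3 <- cluster_profiles(m, rownames(m)[1:50], sim$meta, k = 2)
  sizes <- tabulate(cl3$probe_cluster, 2)
  expect_true(sizes[1] >= sizes[2])
  # k = 1 puts everything in cluster 1
  cl1 <- cluster_profiles(m, rownames(m), sim$meta, k = 1)
  expect_true(all(cl1$probe_cluster == 1))
  expect_error(cluster_profiles(m, rownames(m)[1:3], sim$meta, k = 5),
               "exceed")
})

test_that("gene resolution picks the smallest-numbered cluster, order-independently", {
  sim <- simulate_array_timecourse(n_probes = 60, noise_sd = 0.1, seed = 20)
  m <- sim$matrix
  tc <- sim$meta$time - mean(sim$meta$time)
  m[1:20, ] <- 8 + rep(tc, each = 20)
  m[21:40, ] <- 8 - rep(tc, each = 20)
  m[41:60, ] <- 8 + rep(tc^2, each = 20)
  p2g <- setNames(rep(sprintf("gene%02d", 1:20), 3), rownames(m))
  cl <- cluster_profiles(m, rownames(m), sim$meta, k = 3, probe2gene = p2g)
  for (g in names(cl$gene_cluster)) {
    probes <- names(p2g)[p2g == g]
    expect_equal(cl$gene_cluster[[g]], min(cl$probe_cluster[probes]))
  }
  # permuting probe order leaves the gene map unchanged
  perm <- sample(rownames(m))
  cl2 <- cluster_profiles(m, perm, sim$meta, k = 3, probe2gene = p2g)
  expect_equal(cl$gene_cluster[sort(names(cl$gene_cluster))],
               cl2$gene_cluster[sort(names(cl2$gene_cluster))])
})

test_that("array generator is deterministic and validates inputs", {
  a <- simulate_array_timecourse(n_probes = 30, seed = 9)
  b <- simulate_array_timecourse(n_probes = 30, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_true(all(a$present))
  expect_true(all(a$truth$coefficients[a$truth$probe_class == "null",
                                       -1] == 0))
  expect_error(simulate_array_timecourse(noise_sd = -1), "non-negative")
  expect_error(simulate_array_timecourse(times = 13.5), "2 time points")
})
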