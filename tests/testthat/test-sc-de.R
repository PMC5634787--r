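test_that("specificity scores match hand-computed JS distances", {
  # expressed only in the target cluster
  expect_equal(specificity_score(c(5, 0))[1], 1)
  expect_equal(specificity_score(c(0, 0, 9))[3], 1)
  # uniform across two clusters: 1 - sqrt(0.3113) (KL terms 0.2075, 0.4150)
  s <- specificity_score(c(3, 3))
  expect_equal(s[1], 0.442, tolerance = 1e-3)
  expect_equal(s[1], s[2])
  # expressed only in the other cluster
  expect_equal(specificity_score(c(0, 7))[1], 0)
  expect_error(specificity_score(c(0, 0)), "all-zero")
})

test_that("specificity is bounded and monotone in concentration", {
  for (w in seq(0.5, 1, by = 0.1)) {
    s <- specificity_score(c(w, 1 - w))
    expect_gte(s[1], 0); expect_lte(s[1], 1)
  }
  conc <- sapply(seq(0.5, 0.99, by = 0.07),
                 function(w) specificity_score(c(w, 1 - w))[1])
  expect_true(all(diff(conc) > 0))
  # matrix interface
  m <- rbind(a = c(1, 0), b = c(1, 1))
  sm <- specificity_score(m)
  expect_equal(dim(sm), c(2, 2))
  expect_equal(unname(sm["a", 1]), 1)
})

test_that("differential expression recovers planted markers", {
  sim <- simulate_expression_matrix(n_genes = 1000, n_cells = 100,
                                    n_markers = 50, fold = 8,
                                    dropout_rate = 0.1, seed = 51)
  ntpm <- normalize_ntpm(sim$matrix, pseudocount = 1)
  de <- differential_expression(ntpm, sim$truth$cell_labels)
  called <- de$gene[de$call != "none"]
  markers <- unlist(sim$truth$marker_sets)
  recall <- mean(markers %in% called)
  precision <- mean(called %in% markers)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # calls point at the class whose markers they are
  mrc <- de$gene[de$call == "MRC"]
  expect_gt(mean(mrc %in% sim$truth$marker_sets$MRC), 0.9)
  expect_true(all(de$q >= de$p - 1e-12, na.rm = TRUE))
})

test_that("a null matrix yields essentially no calls", {
  sim <- simulate_expression_matrix(n_genes = 2000, n_cells = 60,
                                    fold = 1, dropout_rate = 0, seed = 52)
  ntpm <- normalize_ntpm(sim$matrix, pseudocount = 1)
  de <- differential_expression(ntpm, sim$truth$cell_labels)
  expect_lte(sum(de$call != "none"), 0.05 * 2000)
})

test_that("detection at exactly 50% blocks a call (strict threshold)", {
  set.seed(53)
  n1 <- 10; n2 <- 10
  labels <- rep(c("A", "B"), c(n1, n2))
  m <- matrix(rlnorm(200 * 20, 2, 0.5), 200, 20,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  # plant a strong gene detected in exactly half of cluster A
  m["g001", ] <- 0
  m["g001", 1:5] <- 1000
  de <- differential_expression(m, labels)
  row <- de[de$gene == "g001", ]
  expect_equal(row$detection.A, 0.5)
  expect_identical(row$call, "none")
  expect_error(differential_expression(m, rep(c("A", "B"), c(18, 2))),
               "at least 3")
})

test_that("more than two clusters use a Kruskal-Wallis test", {
  sim <- simulate_expression_matrix(
    n_genes = 500, n_cells = 90,
    class_proportions = c(MRC = 0.4, RRC = 0.4, ProlC = 0.2),
    n_markers = 30, fold = 8, dropout_rate = 0.1, seed = 54)
  ntpm <- normalize_ntpm(sim$matrix, pseudocount = 1)
  de <- differential_expression(ntpm, sim$truth$cell_labels,
                                specificity_min = 0.65)
  markers <- unlist(sim$truth$marker_sets)
  called <- de$gene[de$call != "none"]
  expect_gte(mean(called %in% markers), 0.8)
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  ann <- data.frame(category = rep(c("catA", "catB"), c(10, 20)),
                    gene = c(sprintf("g%03d", 1:10), sprintf("g%03d", 51:70)))
  # all five query genes inside catA (reference 100)
  res <- enrichment_fisher(sprintf("g%03d", 1:5), ann, reference_size = 100)
  ra <- res[res$category == "catA", ]
  expect_equal(ra$fold_enrichment, 10)
  expect_equal(ra$p, choose(10, 5) / choose(100, 5), tolerance = 1e-10)
  # category absent from the set: fold 0, one-sided p = 1
  rb <- res[res$category == "catB", ]
  expect_equal(rb$fold_enrichment, 0)
  expect_equal(rb$p, 1)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 2))
  # two of three query genes in a 20/100 category: fold (2/3)/(1/5) = 10/3
  res2 <- enrichment_fisher(sprintf("g%03d", c(1, 51, 52)), ann, 100)
  expect_equal(res2[res2$category == "catB", "fold_enrichment"], 10 / 3,
               tolerance = 1e-10)
  expect_error(enrichment_fisher(character(0), ann, 100), "non-empty")
})

test_that("Ct to log2 expression uses LOD = 28 with a floor at zero", {
  expect_equal(ct_to_log2(28), 0)
  expect_equal(ct_to_log2(27), 1)
  expect_equal(ct_to_log2(30), 0)
  expect_equal(ct_to_log2(c(20, 28, 35)), c(8, 0, 0))
  expect_error(ct_to_log2(0), "positive")
})
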