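prop_mat <- function(m, genes = sprintf("g%02d", seq_len(nrow(m))),
                     tissues = paste0("t", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, tissues)
  m
}

test_that("spearman handles ties, monotone transforms and constants", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40)), 1.0)
  expect_equal(spearman(1:4, 4:1), -1.0)
  expect_equal(spearman(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_true(is.na(spearman(c(1, 1, 1), c(1, 2, 3))))
  # invariance under strictly monotone transforms
  set.seed(5)
  x <- runif(20); y <- runif(20)
  expect_equal(spearman(x, y), spearman(exp(3 * x), y))
  expect_equal(spearman(x, y), spearman(x, y^3))
})

test_that("profile_correlations flags r strictly above the cutoff", {
  m <- prop_mat(matrix(runif(30), 10, 3))
  pc <- profile_correlations(m, m)
  expect_true(all(pc$correlated))
  expect_equal(pc$r, rep(1, 10))

  # r exactly 0.5 is not flagged
  f <- prop_mat(matrix(c(1, 2, 3), 5, 3, byrow = TRUE) + 0,
                genes = paste0("g", 1:5))
  o <- prop_mat(matrix(c(2, 1, 3), 5, 3, byrow = TRUE) + 0,
                genes = paste0("g", 1:5))
  pc2 <- profile_correlations(f, o, proportions = FALSE)
  expect_equal(pc2$r, rep(0.5, 5))
  expect_false(any(pc2$correlated))

  # genes missing in one species are skipped with a message
  expect_message(pc3 <- profile_correlations(m[1:8, ], m[3:10, ]),
                 "skipped")
  expect_equal(nrow(pc3), 6)

  # transcribed-in-both restriction
  tf <- setNames(rep(c(TRUE, FALSE), 5), rownames(m))
  pc4 <- profile_correlations(m, m, transcribed_focal = tf,
                              transcribed_outgroup = tf)
  expect_equal(nrow(pc4), 5)
})

test_that("power on strongly correlated synthetic data", {
  sim <- simulate_expression(100, paste0("t", 1:7), rho = 0.9, lambda = 1,
                             dispersion = 0.05, seed = 77)
  pc <- profile_correlations(sim$focal, sim$outgroup)
  expect_gte(mean(pc$correlated), 0.8)
})

test_that("ortholog_shuffle_null: degenerate exchangeable case gives p = 1", {
  m <- prop_mat(matrix(rep(c(0.5, 0.3, 0.2), each = 3), 3, 3),
                genes = paste0("g", 1:3))
  nr <- ortholog_shuffle_null(m, m, n_sim = 200, seed = 4,
                              proportions = FALSE)
  expect_equal(nr$p_value, 1.0)
  expect_true(all(nr$null_counts == nr$observed_count))
})

test_that("ortholog_shuffle_null matches the exhaustive permutation oracle", {
  # 4 genes with mutually orthogonal (peaked) profiles, perfect matching:
  # each permutation's count is its number of fixed points
  eye <- prop_mat(diag(4) * 0.7 + 0.1, genes = paste0("g", 1:4))
  nr <- ortholog_shuffle_null(eye, eye, n_sim = 4000, seed = 10,
                              proportions = FALSE)
  expect_equal(nr$observed_count, 4)
  # exhaustive distribution of fixed points over S4:
  # P(0)=9/24, P(1)=8/24, P(2)=6/24, P(3)=0, P(4)=1/24
  exact <- c(`0` = 9, `1` = 8, `2` = 6, `3` = 0, `4` = 1) / 24
  for (k in 0:4) {
    obs <- mean(nr$null_counts == k)
    tol <- 3 * sqrt(exact[[as.character(k)]] *
                      (1 - exact[[as.character(k)]]) / 4000) + 1e-9
    expect_lt(abs(obs - exact[[as.character(k)]]), tol + 0.005)
  }
  expect_equal(nr$p_value, (1 + sum(nr$null_counts >= 4)) / 4001)
})

test_that("shuffle null is reproducible and matches per-pair spearman", {
  sim <- simulate_expression(12, paste0("t", 1:5), rho = 0.5, lambda = 1,
                             dispersion = 0.1, seed = 31)
  a <- ortholog_shuffle_null(sim$focal, sim$outgroup, n_sim = 300, seed = 9)
  b <- ortholog_shuffle_null(sim$focal, sim$outgroup, n_sim = 300, seed = 9)
  expect_identical(a, b)
  pc <- profile_correlations(sim$focal, sim$outgroup)
  expect_equal(a$observed_count, sum(pc$correlated))
})

test_that("cluster_tissues pairs same tissues across species", {
  sim <- simulate_expression(80, paste0("t", 1:7), rho = 0.95, lambda = 1,
                             dispersion = 0.02, seed = 12)
  pf <- tissue_proportions(sim$focal$rpkm)
  po <- tissue_proportions(sim$outgroup$rpkm)
  hc <- cluster_tissues(list(human = pf, rhesus = po))
  # mutual nearest neighbours: same-tissue cross-species pairs
  m <- cbind(pf, po)
  colnames(m) <- c(paste0("human.t", 1:7), paste0("rhesus.t", 1:7))
  d <- as.matrix(dist(t(m)))
  diag(d) <- Inf
  nn <- setNames(colnames(d)[apply(d, 1, which.min)], rownames(d))
  same_tissue <- sum(vapply(seq_len(7), function(i) {
    nn[paste0("human.t", i)] == paste0("rhesus.t", i) &&
      nn[paste0("rhesus.t", i)] == paste0("human.t", i)
  }, logical(1)))
  expect_gte(same_tissue, 6)

  # identical matrices merge same-tissue pairs at height 0 first
  hc0 <- cluster_tissues(list(a = pf, b = pf))
  groups <- cutree(hc0, h = 1e-12)
  for (i in 1:7)
    expect_equal(groups[[paste0("a.t", i)]], groups[[paste0("b.t", i)]])

  # single species: plain dendrogram
  expect_s3_class(cluster_tissues(list(human = pf)), "hclust")
})

test_that("tissue_pair_matrix has unit diagonal and block symmetry", {
  sim <- simulate_expression(60, paste0("t", 1:5), rho = 0.9, lambda = 1,
                             dispersion = 0.05, seed = 13)
  pf <- tissue_proportions(sim$focal$rpkm)
  tm_self <- tissue_pair_matrix(pf, pf)
  expect_true(all(abs(diag(tm_self) - 1) < 1e-12))
  expect_equal(tm_self, t(tm_self))

  tm <- tissue_pair_matrix(tissue_proportions(sim$focal$rpkm),
                           tissue_proportions(sim$outgroup$rpkm))
  cross <- tm[1:5, 6:10]
  expect_gt(mean(diag(cross)), mean(cross[row(cross) != col(cross)]))

  sim0 <- simulate_expression(200, paste0("t", 1:5), rho = 0, lambda = 1,
                              dispersion = 0.05, seed = 14)
  tm0 <- tissue_pair_matrix(tissue_proportions(sim0$focal$rpkm),
                            tissue_proportions(sim0$outgroup$rpkm))
  cross0 <- tm0[1:5, 6:10]
  expect_lt(abs(mean(cross0)), 0.12)
})

test_that("orf_expansion_test returns correlations and the exact Fisher p", {
  set.seed(6)
  n <- 12
  lr <- runif(n, 0.2, 0.8)
  res <- orf_expansion_test(lr, runif(n), runif(n, -1, 1),
                            exon_counts = rep(c(1, 2), 6),
                            transcribed_flags = rep(c(TRUE, FALSE), 6))
  expect_true(abs(res$rho_length_vs_expression) < 0.6)

  # frozen exhaustive hypergeometric value for the (3,3;3,3) table
  res2 <- orf_expansion_test(lr, runif(n), runif(n, -1, 1),
                             exon_counts = rep(c(1, 1, 2, 2), 3),
                             transcribed_flags = rep(c(TRUE, FALSE), 6))
  tab_multi <- rep(c(1, 1, 2, 2), 3) > 1
  tab_tx <- rep(c(TRUE, FALSE), 6)
  expect_equal(sum(tab_multi & tab_tx), 3)   # the table really is 3,3;3,3
  expect_equal(res2$fisher_one_sided_p, 0.7164502, tolerance = 1e-6)

  # constant length ratio: correlation undefined
  res3 <- orf_expansion_test(rep(0.5, n), runif(n), runif(n),
                             exon_counts = rep(1, n),
                             transcribed_flags = rep(TRUE, n))
  expect_true(is.na(res3$rho_length_vs_expression))
  expect_true(res3$degenerate)
  expect_equal(res3$fisher_one_sided_p, 1)
})
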