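test_that("orthologue mapping filters on score and resolves multi-mappings", {
  map <- tibble::tibble(fly_gene = c("f1", "f2", "f3", "f3", "f4"),
                        human_gene = c("hA", "hB", "hA", "hB", "hC"),
                        score = c(5L, 4L, 6L, 9L, 7L))
  out <- map_orthologs(c("f1", "f2", "f3", "f5"), map, min_score = 5)
  expect_equal(out$mapped[out$gene == "f1"], "hA")   # score 5 retained
  expect_false("f2" %in% out$gene)                   # score 4 dropped
  expect_equal(out$mapped[out$gene == "f3"], "hB")   # best score wins
  expect_equal(attr(out, "n_unmapped"), 2)           # f2 and f5
  # equal scores: lexicographic target
  map2 <- tibble::tibble(fly_gene = c("f1", "f1"), human_gene = c("hZ", "hA"),
                         score = c(6L, 6L))
  expect_equal(map_orthologs("f1", map2)$mapped, "hA")
})

test_that("hypergeometric overlap matches exhaustive enumeration for small universes", {
  universe <- paste0("u", 1:10)
  ov <- overlap_stats(universe[1:5], universe[c(1:4)], universe)
  # N=10, K=4, n=5, k=4 -> 6/252
  expect_equal(ov$k, 4)
  expect_equal(ov$p_upper, 6 / 252, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:15) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    u <- paste0("u", seq_len(N))
    A <- sample(u, n); B <- sample(u, K)
    ov <- overlap_stats(A, B, u)
    expect_equal(ov$p_upper, enum_hyper_p(N, K, n, ov$k), tolerance = 1e-10)
  }
})

test_that("overlap fraction and p behave at the boundaries and monotonically in k", {
  u <- paste0("u", 1:20)
  ov0 <- overlap_stats(u[11:15], u[1:5], u)
  expect_equal(ov0$k, 0)
  expect_equal(ov0$p_upper, 1)
  ovall <- overlap_stats(u, u, u)
  expect_equal(ovall$fraction, 1)
  expect_equal(ovall$p_upper, 1)
  # p_upper non-increasing in k at fixed N, K, n
  B <- u[1:5]
  ps <- sapply(0:5, function(k) {
    A <- c(u[seq_len(k)], u[5 + seq_len(5 - k)])
    overlap_stats(A, B, u)$p_upper
  })
  expect_true(all(diff(ps) <= 0))
  expect_error(overlap_stats(c("zzz"), u[1:2], u), "subsets")
})

test_that("AUC scores hit their extremes and are rank-invariant", {
  set.seed(2)
  expr <- matrix(rnorm(1000 * 3), nrow = 1000,
                 dimnames = list(paste0("g", 1:1000), paste0("c", 1:3)))
  top_set <- paste0("g", order(-expr[, 1])[1:10])
  a <- aucell_scores(expr, top_set, top_fraction = 0.05, seed = 1)
  expect_equal(a$auc[1], 1)
  bottom_set <- paste0("g", order(expr[, 2])[1:10])
  b <- aucell_scores(expr, bottom_set, top_fraction = 0.05, seed = 1)
  expect_equal(b$auc[2], 0)
  # monotone transform of one cell's expression leaves its score unchanged
  expr2 <- expr
  expr2[, 3] <- exp(expr2[, 3] / 2)
  s1 <- aucell_scores(expr, top_set, seed = 9)$auc[3]
  s2 <- aucell_scores(expr2, top_set, seed = 9)$auc[3]
  expect_equal(s1, s2)
  expect_error(aucell_scores(expr, "absent"), "intersect")
})

test_that("random gene sets score near the permutation expectation", {
  set.seed(3)
  n_genes <- 2000
  expr <- matrix(rnorm(n_genes * 500), nrow = n_genes,
                 dimnames = list(paste0("g", seq_len(n_genes)), NULL))
  gs <- sample(rownames(expr), 50)
  obs <- aucell_scores(expr, gs, top_fraction = 0.05, seed = 4)$auc
  # permutation oracle: the same statistic on uniformly random rankings
  W <- ceiling(0.05 * n_genes)
  max_auc <- sum(pmin(seq_len(W), 50))
  perm <- replicate(2000, {
    rk <- sample.int(n_genes, 50)
    sum(pmax(W - rk + 1, 0)) / max_auc
  })
  se <- sqrt(stats::var(obs) / length(obs) + stats::var(perm) / length(perm))
  expect_lt(abs(mean(obs) - mean(perm)), 3 * se)
})

test_that("two-sample enrichment test reproduces the textbook case", {
  out <- enrichment_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4)
  expect_equal(out$p, 0.0213, tolerance = 1e-2)
  # symmetry and the degenerate equal-constant case
  swapped <- enrichment_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -out$t)
  expect_equal(swapped$p, out$p)
  same <- enrichment_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- enrichment_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})
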