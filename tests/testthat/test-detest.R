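make_two_group_cohort <- function(vals_a, vals_b, n_genes = 1) {
  # one gene per row of vals; groups become genotypes mut/control in cluster 1
  m <- rbind(matrix(c(vals_a, vals_b), nrow = 1),
             matrix(10, nrow = 1, ncol = length(c(vals_a, vals_b))))
  n <- ncol(m)
  cohort(m,
         tibble::tibble(cell_id = paste0("c", 1:n),
                        genotype = rep(c("mut", "control"),
                                       c(length(vals_a), length(vals_b))),
                        run = "r1", cluster = 1),
         tibble::tibble(gene = c("target", "filler"), mito = FALSE))
}

test_that("rank-sum p-values match the exhaustive-permutation oracle for small untied groups", {
  # canonical separated case: p = 0.1 (2 of 20 orderings as extreme)
  expect_equal(enum_wilcox_p(1:3, 4:6), 0.1)
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    vals <- sample(seq_len(50), n1 + n2) # distinct -> no ties
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    m <- matrix(c(a, b), nrow = 1)
    p_impl <- vulnscan:::ranksum_rows(m, c(rep(TRUE, n1), rep(FALSE, n2)))
    expect_equal(p_impl, enum_wilcox_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 and lfc = 0", {
  x <- make_two_group_cohort(c(5, 5, 5, 5), c(5, 5, 5, 5))
  de <- ranksum_de(x, 1, "mut", "control")
  expect_equal(de$p, c(1, 1))
  expect_equal(de$lfc, c(0, 0))
})

test_that("too-small arms are skipped with a warning", {
  x <- make_two_group_cohort(c(1, 2), c(3, 4, 5))
  expect_warning(out <- ranksum_de(x, 1, "mut", "control"), "skipped")
  expect_null(out)
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  gen <- small_gen()
  de <- ranksum_de(gen$cohort, 3, "mut1")
  expect_equal(de$p_adj, stepup_bh(de$p), tolerance = 1e-12)
  expect_true(all(de$p_adj >= de$p))
})

test_that("pseudobulk construction drops small runs and conserves counts", {
  m <- matrix(rpois(5 * 31, 10), nrow = 5)
  cells <- tibble::tibble(cell_id = paste0("c", 1:31),
                          genotype = "control",
                          run = rep(c("r1", "r2", "r3"), c(12, 10, 9)),
                          cluster = 1)
  x <- cohort(m, cells, tibble::tibble(gene = paste0("g", 1:5), mito = FALSE))
  pb <- make_pseudobulks(x, 1)
  expect_equal(nrow(pb), 2)
  expect_setequal(pb$run, c("r1", "r2"))
  kept <- cells$run %in% c("r1", "r2")
  expect_equal(Reduce(`+`, pb$counts),
               stats::setNames(rowSums(m[, kept]), paste0("g", 1:5)))
  # one cell per run -> nothing retained
  cells2 <- dplyr::mutate(cells, run = cell_id)
  x2 <- cohort(m, cells2, x$genes)
  expect_equal(nrow(make_pseudobulks(x2, 1)), 0)
})

test_that("pseudobulk NB test is calibrated under the null", {
  set.seed(42)
  rej <- 0; tot <- 0
  for (r in 1:500) {
    Y <- matrix(stats::rnbinom(20 * 8, mu = 50, size = 1 / 0.3), nrow = 20)
    rownames(Y) <- paste0("g", 1:20)
    pb <- tibble::tibble(run = paste0("r", 1:8),
                         genotype = rep(c("control", "m"), each = 4),
                         cluster = 1, n_cells = 10,
                         counts = lapply(1:8, function(j) {
                           stats::setNames(Y[, j], rownames(Y))
                         }))
    pd <- pseudobulk_de(pb, "m")
    rej <- rej + sum(pd$p < 0.05, na.rm = TRUE)
    tot <- tot + sum(!is.na(pd$p))
  }
  expect_gt(rej / tot, 0.03)
  expect_lt(rej / tot, 0.08)
})

test_that("a constant gene with equal offsets has coefficient 0 and p near 1", {
  Y <- matrix(50, nrow = 2, ncol = 6)
  Y[2, ] <- 100 # second gene keeps offsets equal without being degenerate
  rownames(Y) <- c("flat", "flat2")
  pb <- tibble::tibble(run = paste0("r", 1:6),
                       genotype = rep(c("control", "m"), each = 3),
                       cluster = 1, n_cells = 10,
                       counts = lapply(1:6, function(j) Y[, j]))
  pd <- pseudobulk_de(pb, "m")
  expect_equal(pd$lfc, c(0, 0), tolerance = 1e-6)
  expect_gt(min(pd$p), 0.99)
})

test_that("pseudobulk NB recovers planted signs and concords with a reference NB implementation", {
  gen <- small_gen()
  pb <- make_pseudobulks(gen$cohort, 1)
  pd <- pseudobulk_de(pb, "mut1")
  truth <- gen$truth$planted_deg
  tr <- truth[truth$genotype == "mut1" & truth$cluster == 1, ]
  est <- pd$lfc[match(tr$gene, pd$gene)]
  expect_gte(mean(sign(est) == tr$sign), 0.95)

  # independent cross-check: DESeq2 Wald on the same pseudobulks
  sub <- pb[pb$genotype %in% c("mut1", "control"), ]
  Y <- do.call(cbind, sub$counts)
  colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  cd <- data.frame(genotype = factor(sub$genotype, levels = c("control", "mut1")))
  dds <- DESeq2::DESeqDataSetFromMatrix(round(Y), cd, ~genotype)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ref <- tibble::tibble(gene = rownames(res), lfc = res$log2FoldChange, p = res$pvalue)
  rho <- method_concordance(pd, ref)
  expect_gt(rho, 0.8)
})

test_that("signed significance follows lfc times -log10 p with a p floor", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        lfc = c(2, 0, -1.5, 1),
                        p = c(1e-4, 1e-10, 1e-2, 0))
  s <- signed_significance(tab)
  expect_equal(s$signed_score[1], 8)
  expect_equal(s$signed_score[2], 0)
  expect_equal(s$signed_score[3], -3)
  expect_equal(s$signed_score[4], 300) # p floored at 1e-300
})

test_that("method concordance reproduces closed-form Spearman values", {
  mk <- function(scores) {
    tibble::tibble(gene = paste0("g", seq_along(scores)), lfc = scores, p = 0.1)
  }
  a <- mk(c(1, 2, 3, 4))
  expect_equal(method_concordance(a, a), 1)
  expect_equal(method_concordance(a, mk(-c(1, 2, 3, 4))), -1)
  expect_equal(method_concordance(a, mk(c(1, 3, 2, 4))), 0.8)
  expect_error(method_concordance(a[1:2, ], mk(c(1, 2))[1:2, ]), "3 shared genes")
})

test_that("cluster downsampling is seeded, bounded, and monotone in nDEG", {
  gen <- small_gen()
  x <- gen$cohort
  d1 <- downsample_cluster(x, 1, 20, seed = 3)
  d2 <- downsample_cluster(x, 1, 20, seed = 3)
  expect_identical(d1$cells, d2$cells)
  for (g in unique(x$cells$genotype)) {
    expect_equal(sum(d1$cells$cluster == 1 & d1$cells$genotype == g), 20)
  }
  # full-size downsample is the identity up to ordering
  n_min <- min(table(x$cells$genotype[x$cells$cluster == 1]))
  expect_error(downsample_cluster(x, 1, n_min + 1000, seed = 1), "cells")

  # planted data: mean nDEG over seeds does not decrease with depth
  sizes <- round(n_min * c(0.3, 0.6, 0.95))
  ndeg <- sapply(sizes, function(n) {
    mean(sapply(1:10, function(s) {
      ds <- downsample_cluster(x, 1, n, seed = s)
      de <- ranksum_de(ds, 1, "mut1")
      sum(de$p_adj < 0.05)
    }))
  })
  expect_true(all(diff(ndeg) >= 0))
})
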