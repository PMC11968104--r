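make_qc_cohort <- function() {
  # 4 genes (1 mito) x 5 hand-built cells covering the threshold boundaries
  counts <- cbind(
    c(100, 200, 200, 0),   # 3 genes, 500 counts, 20% mito
    c(10, 30, 10, 0),      # 3 genes, 50 counts, 20% mito
    c(0, 450, 100, 50),    # 3 genes, 600 counts, 0% mito
    c(30, 500, 100, 0),    # 3 genes, 630 counts, ~4.8% mito
    c(0, 0, 600, 0)        # 1 gene, 600 counts, 0% mito
  )
  cohort(counts,
         tibble::tibble(cell_id = paste0("c", 1:5), genotype = "control",
                        run = "r1", cluster = 1),
         tibble::tibble(gene = c("mt:a", "b", "c", "d"),
                        mito = c(TRUE, FALSE, FALSE, FALSE)))
}

test_that("filter_cells applies inclusive count/gene bounds and strict mito cut", {
  x <- make_qc_cohort()
  thr <- qc_thresholds(min_genes = 2, max_genes = 10, min_counts = 500,
                       max_counts = 30000, max_mito_pct = 15)
  f <- filter_cells(x, thr)
  # c1: 20% mito >= 15 -> removed; c2: too few counts; c5: 1 gene
  expect_equal(f$cohort$cells$cell_id, c("c3", "c4"))
  expect_equal(f$report$n_in, 5)
  expect_equal(f$report$n_out, 2)
  expect_equal(f$report$removed_counts, 1)
  expect_equal(f$report$removed_genes, 1)
  expect_equal(f$report$removed_mito, 1)
  # gene set untouched
  expect_equal(f$cohort$genes, x$genes)
  # exactly at min_counts is kept (inclusive bound)
  thr2 <- qc_thresholds(min_counts = 500, max_mito_pct = 100)
  expect_true("c1" %in% filter_cells(x, thr2)$cohort$cells$cell_id)
})

test_that("a 20%-mito cell passes neither species preset and a cell under 200 genes fails the fly preset", {
  x <- make_qc_cohort()
  fly <- filter_cells(x, qc_preset("fly"))
  expect_false("c1" %in% fly$cohort$cells$cell_id)
  hum <- filter_cells(x, qc_preset("human"))
  expect_false("c1" %in% hum$cohort$cells$cell_id)
  # fly min_genes = 200: a real cohort cell expressing 150 genes is removed
  gen <- small_gen()
  counts <- gen$cohort$counts
  qm <- cell_metrics(gen$cohort)
  expect_true(all(filter_cells(gen$cohort, qc_preset("fly"))$report$removed_genes >=
                    sum(qm$n_genes < 200)))
})

test_that("identity thresholds keep every cell and filtering is idempotent", {
  gen <- small_gen()
  f0 <- filter_cells(gen$cohort, qc_thresholds())
  expect_equal(f0$report$n_out, f0$report$n_in)
  thr <- qc_thresholds(min_genes = 10, min_counts = 50, max_mito_pct = 50)
  f1 <- filter_cells(gen$cohort, thr)
  f2 <- filter_cells(f1$cohort, thr)
  expect_equal(f2$report$n_out, f2$report$n_in)
  expect_identical(as.matrix(f1$cohort$counts), as.matrix(f2$cohort$counts))
})

test_that("normalization scales cells, regresses covariates, and clips", {
  # proportional cells coincide after library-size scaling
  counts <- cbind(c(1, 1, 2), c(2, 2, 4), c(5, 0, 5))
  x <- cohort(counts,
              tibble::tibble(cell_id = paste0("c", 1:3), genotype = "g",
                             run = "r", cluster = 1),
              tibble::tibble(gene = c("a", "b", "c"), mito = FALSE))
  pre <- vulnscan:::lognormalize(x, 1e4, log = FALSE)
  expect_equal(pre[, 1], pre[, 2])
  expect_equal(unname(pre[, 1]), c(2500, 2500, 5000))

  # a gene exactly linear in total counts vanishes after regression
  set.seed(1)
  n <- 60
  counts2 <- rbind(matrix(rpois(5 * n, 20), nrow = 5),
                   round(seq(10, 50, length.out = n)))
  x2 <- cohort(counts2,
               tibble::tibble(cell_id = paste0("c", 1:n), genotype = "g",
                              run = "r", cluster = 1),
               tibble::tibble(gene = paste0("g", 1:6), mito = FALSE))
  tot <- Matrix::colSums(x2$counts)
  # replace the last gene with an exact linear function of total counts on
  # the log-normalized scale by construction: use the covariate directly
  m <- vulnscan:::lognormalize(x2, 1e4)
  m[6, ] <- 2 + 3 * tot
  qm <- cell_metrics(x2)
  X <- cbind(1, qm$total_counts, qm$mito_pct)
  res <- t(stats::lm.fit(X, t(m))$residuals)
  expect_lt(max(abs(res[6, ])), 1e-8)

  # full normalize: orthogonality to covariates pre-clipping, and clipping
  norm <- normalize_cells(x2, clip_max = Inf)
  for (cov in list(qm$total_counts, qm$mito_pct)) {
    dots <- abs(norm %*% (cov - mean(cov)))
    expect_lt(max(dots / (sqrt(rowSums(norm^2)) * sqrt(sum((cov - mean(cov))^2)) + 1e-12)), 1e-8)
  }
  norm_clipped <- normalize_cells(x2, clip_max = 1.5)
  expect_lte(max(norm_clipped), 1.5)
})

test_that("cells with zero counts are rejected at normalization", {
  counts <- cbind(c(1, 2), c(0, 0))
  x <- cohort(counts,
              tibble::tibble(cell_id = c("a", "b"), genotype = "g",
                             run = "r", cluster = 1),
              tibble::tibble(gene = c("g1", "g2"), mito = FALSE))
  expect_error(normalize_cells(x), "zero total counts")
})
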