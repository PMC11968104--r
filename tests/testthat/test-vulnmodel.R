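make_stats <- function(n, intercept = 1, b1 = 0.8, alpha = 0, seed = 1) {
  set.seed(seed)
  x1 <- sample(50:500, n, replace = TRUE)
  x2 <- sample(50:500, n, replace = TRUE)
  mu <- exp(intercept + b1 * log(pmin(x1, x2)))
  y <- if (alpha > 0) stats::rnbinom(n, mu = mu, size = 1 / alpha) else round(mu)
  tibble::tibble(cluster = seq_len(n), y = y, x1 = x1, x2 = x2)
}

test_that("NB fit recovers noiseless parameters and matches an independent NB fitter", {
  d <- make_stats(50)
  fit <- fit_ndeg_model(d)
  expect_lt(abs(fit$intercept - 1), 0.05)
  expect_lt(abs(fit$b1 - 0.8), 0.05)
  expect_true(fit$converged)

  # independent route: MASS::glm.nb on noisy data
  d2 <- make_stats(200, alpha = 0.4, seed = 5)
  fit2 <- fit_ndeg_model(d2)
  ref <- MASS::glm.nb(y ~ log(pmin(x1, x2)), data = d2)
  expect_equal(fit2$intercept, unname(coef(ref)[1]), tolerance = 0.02)
  expect_equal(fit2$b1, unname(coef(ref)[2]), tolerance = 0.02)
  expect_equal(fit2$alpha, 1 / ref$theta, tolerance = 0.1)
  expect_equal(fit2$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-3)
})

test_that("fitted likelihood dominates the Poisson submodel", {
  d <- make_stats(100, alpha = 0.5, seed = 3)
  fit <- fit_ndeg_model(d)
  pois <- stats::glm(y ~ log(pmin(x1, x2)), data = d, family = stats::poisson())
  expect_gte(fit$loglik, as.numeric(stats::logLik(pois)) - 1e-6)
})

test_that("degenerate inputs are rejected", {
  d <- make_stats(10)
  expect_error(fit_ndeg_model(d[1:4, ]), "at least 5")
  expect_error(fit_ndeg_model(dplyr::mutate(d, y = 0)), "degenerate")
  expect_error(fit_ndeg_model(dplyr::mutate(d, x1 = 0)), ">= 1")
})

test_that("a constant design is fitted exactly and residuals vanish", {
  d <- tibble::tibble(cluster = 1:6, y = 12, x1 = 100, x2 = 80)
  fit <- suppressWarnings(fit_ndeg_model(d))
  res <- cluster_residuals(fit)
  expect_equal(res$mu_hat, rep(12, 6), tolerance = 1e-4)
  expect_equal(res$r, rep(0, 6), tolerance = 1e-3)
})

test_that("residuals follow y - mu_hat with the documented sign convention", {
  fit <- structure(list(intercept = log(20), b1 = 0, alpha = 0.1,
                        data = NULL), class = "ndeg_fit")
  d <- tibble::tibble(cluster = 1:2, y = c(50, 5), x1 = c(100, 100), x2 = c(90, 90))
  res <- cluster_residuals(fit, d)
  expect_equal(res$mu_hat, c(20, 20))
  expect_equal(res$r, c(30, -15))
  # mu_hat monotone in min(x1, x2) when b1 > 0
  fit2 <- structure(list(intercept = 0, b1 = 0.5, alpha = 0.1, data = NULL),
                    class = "ndeg_fit")
  d2 <- tibble::tibble(cluster = 1:5, y = 1, x1 = c(10, 20, 40, 80, 160), x2 = 1e6)
  expect_true(all(diff(cluster_residuals(fit2, d2)$mu_hat) > 0))
})

test_that("Pearson residuals center near zero under the fitted model", {
  set.seed(8)
  d <- make_stats(200, alpha = 0.3, seed = 8)
  fit <- fit_ndeg_model(d)
  sim <- dplyr::mutate(d, y = stats::rnbinom(dplyr::n(),
                                             mu = exp(fit$intercept + fit$b1 * log(pmin(x1, x2))),
                                             size = 1 / fit$alpha))
  res <- cluster_residuals(fit, sim)
  se <- stats::sd(res$pearson) / sqrt(nrow(res))
  expect_lt(abs(mean(res$pearson)), 2 * se + 0.05)
})

test_that("consensus ranking respects identity, symmetry, and relabeling", {
  r1 <- tibble::tibble(cluster = 1:5, y = 1, mu_hat = 1,
                       r = c(10, 5, 0, -5, -10), pearson = c(10, 5, 0, -5, -10))
  # identical tables across genotypes reproduce the single-genotype order
  cons <- rank_vulnerable(list(a = r1, b = r1), top_k = 2)
  expect_equal(cons$cluster, 1:5)
  expect_equal(cons$top, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # one genotype reversed: all consensus ranks tie
  r2 <- dplyr::mutate(r1, r = rev(r))
  cons2 <- rank_vulnerable(list(a = r1, b = r2), top_k = 2)
  expect_true(all(cons2$mean_rank == 3))
  # relabeling clusters permutes but does not change the consensus
  perm <- c(3, 1, 4, 5, 2)
  r1p <- dplyr::mutate(r1, cluster = perm)
  consp <- rank_vulnerable(list(a = r1p, b = r1p), top_k = 2)
  expect_equal(consp$mean_rank[match(perm, consp$cluster)], cons$mean_rank)
  # missing cluster gets the worst rank
  r3 <- r1[1:4, ]
  cons3 <- rank_vulnerable(list(a = r1, b = r3), top_k = 2)
  expect_equal(cons3$mean_rank[cons3$cluster == 5], (5 + 5) / 2)
})
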