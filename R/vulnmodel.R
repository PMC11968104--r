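# Negative-binomial model of DEG counts against cluster size. The number
# of differential genes detected in a cluster grows with the number of
# cells available to the test, so raw nDEG cannot be compared across
# clusters; clusters "more affected than expected" are found as positive
# residuals from an NB2 regression of nDEG on the size of the smaller arm:
#
#   E[y_i] = mu_i,  Var[y_i] = mu_i + alpha mu_i^2,
#   log(mu_i) = intercept + b1 * log(min(x1_i, x2_i)).

nb2_negll <- function(par, y, logm) {
  mu <- exp(pmin(par[1] + par[2] * logm, 30))
  alpha <- exp(par[3])
  -sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

#' Fit the DEG-count vulnerability model
#'
#' Maximum-likelihood NB2 regression of nDEG on the log number of cells in
#' the smaller arm of each contrast, with intercept. Dispersion is profiled
#' on the log scale with a floor of 1e-8 (the near-Poisson limit).
#'
#' @param stats_tbl tibble with columns `cluster`, `y`, `x1`, `x2` (see
#'   [cluster_stats()]); at least 5 clusters with observed `y`.
#' @return An object of class `ndeg_fit`: list with `intercept`, `b1`,
#'   `alpha`, `loglik`, `converged`, `n`, and the input table.
#' @export
fit_ndeg_model <- function(stats_tbl) {
  stats_tbl <- tibble::as_tibble(stats_tbl)
  assert_that(all(c("cluster", "y", "x1", "x2") %in% names(stats_tbl)),
              "need columns cluster, y, x1, x2")
  stats_tbl <- stats_tbl[is.finite(stats_tbl$y), , drop = FALSE]
  assert_that(nrow(stats_tbl) >= 5, "need at least 5 clusters with observed y")
  assert_that(all(stats_tbl$x1 >= 1 & stats_tbl$x2 >= 1), "cell counts must be >= 1")
  assert_that(all(stats_tbl$y >= 0), "nDEG must be non-negative")
  if (all(stats_tbl$y == 0)) {
    stop("all nDEG are zero; the vulnerability model is degenerate", call. = FALSE)
  }
  y <- stats_tbl$y
  logm <- log(pmin(stats_tbl$x1, stats_tbl$x2))
  # Poisson GLM start + method-of-moments dispersion
  pois <- stats::glm(y ~ logm, family = stats::poisson())
  mu0 <- stats::fitted(pois)
  a0 <- max(mean((y - mu0)^2 - mu0) / mean(mu0^2), 1e-4)
  start <- c(stats::coef(pois), log(a0))
  start[is.na(start)] <- 0 # constant covariate: slope unidentified, start at 0
  opt <- stats::optim(start, nb2_negll, y = y, logm = logm,
                      method = "L-BFGS-B",
                      lower = c(-50, -50, log(1e-8)),
                      upper = c(50, 50, log(1e4)),
                      control = list(maxit = 500))
  if (opt$convergence != 0) {
    warning("NB fit did not converge (code ", opt$convergence, "): ", opt$message)
  }
  structure(list(intercept = unname(opt$par[1]),
                 b1 = unname(opt$par[2]),
                 alpha = unname(exp(opt$par[3])),
                 loglik = -opt$value,
                 converged = opt$convergence == 0,
                 n = length(y),
                 data = stats_tbl),
            class = "ndeg_fit")
}

#' @export
print.ndeg_fit <- function(x, ...) {
  cat(sprintf("<ndeg_fit> log(mu) = %.3f + %.3f * log(min cells); alpha = %.3g; logLik = %.2f (n = %d)\n",
              x$intercept, x$b1, x$alpha, x$loglik, x$n))
  invisible(x)
}

#' @method tidy ndeg_fit
#' @export
tidy.ndeg_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "b1", "alpha"),
                 estimate = c(x$intercept, x$b1, x$alpha))
}

#' @method glance ndeg_fit
#' @export
glance.ndeg_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, logLik = x$loglik, nobs = x$n,
                 converged = x$converged)
}

#' Per-cluster residuals from the vulnerability model
#'
#' `mu_hat = exp(intercept + b1 * log(min(x1, x2)))`; the raw residual is
#' `r = y - mu_hat`, so positive means more differential genes than the
#' cluster's size predicts. Pearson residuals
#' `r / sqrt(mu_hat + alpha mu_hat^2)` are reported alongside.
#'
#' @param fit an [fit_ndeg_model()] result.
#' @param stats_tbl optionally a new `cluster`, `y`, `x1`, `x2` table
#'   (defaults to the fitting data).
#' @return A tibble `cluster`, `y`, `mu_hat`, `r`, `pearson`.
#' @export
cluster_residuals <- function(fit, stats_tbl = NULL) {
  stopifnot(inherits(fit, "ndeg_fit"))
  d <- tibble::as_tibble(stats_tbl %||% fit$data)
  mu_hat <- exp(fit$intercept + fit$b1 * log(pmin(d$x1, d$x2)))
  tibble::tibble(cluster = d$cluster, y = d$y, mu_hat = mu_hat,
                 r = d$y - mu_hat,
                 pearson = (d$y - mu_hat) / sqrt(mu_hat + fit$alpha * mu_hat^2))
}

#' Consensus ranking of vulnerable clusters across genotypes
#'
#' Within each genotype, clusters are ranked by residual (most positive =
#' rank 1, average-rank ties; clusters missing from a genotype get that
#' genotype's worst rank). The consensus is the mean rank across genotypes;
#' the `top_k` clusters are flagged as commonly affected.
#'
#' @param residual_tables list of [cluster_residuals()] tibbles, one per
#'   genotype, or one tibble with a `genotype` column.
#' @param top_k how many top consensus clusters to flag.
#' @param use_pearson rank on Pearson instead of raw residuals.
#' @return A tibble `cluster`, `mean_rank`, `n_genotypes`, `top`, sorted by
#'   consensus rank.
#' @export
rank_vulnerable <- function(residual_tables, top_k = 3, use_pearson = FALSE) {
  if (is.data.frame(residual_tables)) {
    assert_that("genotype" %in% names(residual_tables),
                "single-table input needs a genotype column")
    residual_tables <- split(residual_tables, residual_tables$genotype)
  }
  col <- if (use_pearson) "pearson" else "r"
  universe <- sort(unique(unlist(lapply(residual_tables, function(d) d$cluster))))
  n <- length(universe)
  ranks <- vapply(residual_tables, function(d) {
    rk <- rep(NA_real_, n)
    pos <- match(d$cluster, universe)
    rk[pos] <- rank(-d[[col]])
    rk[is.na(rk)] <- n # missing = worst rank
    rk
  }, numeric(n))
  ranks <- matrix(ranks, nrow = n)
  out <- tibble::tibble(cluster = universe,
                        mean_rank = rowMeans(ranks),
                        n_genotypes = ncol(ranks))
  out <- dplyr::arrange(out, .data$mean_rank, .data$cluster)
  dplyr::mutate(out, top = dplyr::row_number() <= top_k)
}
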