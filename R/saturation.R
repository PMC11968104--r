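# How many cells must be sequenced to see every cell type? Repeated
# subsampling of an annotated cell population, counting the types detected
# at each depth, and a Michaelis-Menten fit whose Vmax estimates the
# asymptotic number of discoverable types and Km the half-saturation depth.

#' Cell-type discovery curve by repeated subsampling
#'
#' For each sample size from 0 to `max_n` in steps of `step`, draws `reps`
#' independent subsamples without replacement from the labeled population;
#' a cell type counts as detected when at least `threshold` of its cells
#' are in the draw. Means and SDs across replicates are recorded.
#'
#' @param cell_labels character/factor vector of per-cell type labels.
#' @param max_n largest sample size (truncated to the population size with
#'   a warning).
#' @param step size increment.
#' @param reps replicates per size.
#' @param threshold minimum cells of a type for detection (>= 1).
#' @param seed integer seed.
#' @param nested draw nested subsamples (each size extends the previous
#'   draw) instead of independent ones; guarantees monotone detection
#'   within a replicate.
#' @return A tibble of class `saturation_curve`: `size`, `mean_detected`,
#'   `sd_detected`, with `reps` and `threshold` as attributes.
#' @export
subsample_curve <- function(cell_labels, max_n = 50000, step = 100,
                            reps = 50, threshold = 1, seed = 1L,
                            nested = FALSE) {
  assert_that(length(cell_labels) > 0, "`cell_labels` must be nonempty")
  assert_that(threshold >= 1, "`threshold` must be >= 1")
  n_pop <- length(cell_labels)
  if (max_n > n_pop) {
    warning("max_n exceeds the population size; truncated to ", n_pop)
    max_n <- n_pop
  }
  sizes <- seq(0, max_n, by = step)
  labs <- as.integer(factor(cell_labels))
  n_types <- max(labs)
  with_seed(seed, {
    det <- matrix(0L, nrow = length(sizes), ncol = reps)
    for (r in seq_len(reps)) {
      if (nested) perm <- sample.int(n_pop)
      for (i in seq_along(sizes)) {
        n <- sizes[i]
        if (n == 0) next
        draw <- if (nested) perm[seq_len(n)] else sample.int(n_pop, n)
        det[i, r] <- sum(tabulate(labs[draw], nbins = n_types) >= threshold)
      }
    }
    out <- tibble::tibble(size = sizes,
                          mean_detected = rowMeans(det),
                          sd_detected = apply(det, 1, stats::sd))
    attr(out, "reps") <- reps
    attr(out, "threshold") <- threshold
    class(out) <- c("saturation_curve", class(out))
    out
  })
}

#' Closed-form expected detection under the hypergeometric law
#'
#' The expectation the subsampling estimates:
#' `sum_t P(at least threshold cells of type t in a draw of n)`.
#'
#' @param cell_labels per-cell type labels.
#' @param sizes draw sizes.
#' @param threshold detection threshold.
#' @return A tibble `size`, `expected_detected`.
#' @export
expected_detection <- function(cell_labels, sizes, threshold = 1) {
  counts <- table(cell_labels)
  N <- length(cell_labels)
  exp_det <- vapply(sizes, function(n) {
    sum(stats::phyper(threshold - 1, counts, N - counts, n, lower.tail = FALSE))
  }, numeric(1))
  tibble::tibble(size = sizes, expected_detected = exp_det)
}

#' Fit Michaelis-Menten saturation kinetics to a discovery curve
#'
#' Nonlinear least squares of `mean_detected = Vmax * size / (Km + size)`,
#' initialized at `Vmax` = the largest observed mean and `Km` = the size
#' whose mean is nearest to half of it.
#'
#' @param curve a [subsample_curve()] tibble (or any tibble with `size`
#'   and `mean_detected`).
#' @return An object of class `mm_fit`: `vmax`, `km`, `rss`, `n`, plus the
#'   fitted [stats::nls] object.
#' @export
fit_michaelis_menten <- function(curve) {
  d <- tibble::as_tibble(curve)[, c("size", "mean_detected")]
  d <- d[is.finite(d$mean_detected), , drop = FALSE]
  assert_that(sum(d$mean_detected > 0) >= 3,
              "need at least 3 sizes with nonzero mean detection")
  vmax0 <- max(d$mean_detected)
  km0 <- d$size[which.min(abs(d$mean_detected - vmax0 / 2))]
  km0 <- max(km0, min(d$size[d$size > 0]))
  # fall back over a ladder of Km starts: a curve that saturates within the
  # first step has a near-zero Km and a singular gradient at coarse starts
  starts <- unique(c(km0, max(d$size) / 10, min(d$size[d$size > 0]) / 10, 1))
  fit <- NULL
  err <- NULL
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mean_detected ~ vmax * size / (km + size), data = d,
                        start = list(vmax = vmax0, km = k0),
                        lower = c(vmax = 0, km = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14)),
      error = function(e) { err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # degenerate curves (e.g. saturation inside the first step) can defeat
    # the NLS Jacobian; fall back to direct least squares on log parameters
    rss_fn <- function(p) {
      pred <- exp(p[1]) * d$size / (exp(p[2]) + d$size)
      sum((d$mean_detected - pred)^2)
    }
    opt <- stats::optim(c(log(vmax0), log(km0)), rss_fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (!is.finite(opt$value)) {
      stop(sprintf("Michaelis-Menten fit failed (start vmax = %.3g, km = %.3g): %s",
                   vmax0, km0, conditionMessage(err)), call. = FALSE)
    }
    return(structure(list(vmax = exp(opt$par[1]), km = exp(opt$par[2]),
                          rss = opt$value, n = nrow(d), nls = NULL, data = d),
                     class = "mm_fit"))
  }
  co <- stats::coef(fit)
  structure(list(vmax = unname(co["vmax"]), km = unname(co["km"]),
                 rss = sum(stats::residuals(fit)^2), n = nrow(d),
                 nls = fit, data = d),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.2f types, Km = %.0f cells (rss = %.3g, n = %d)\n",
              x$vmax, x$km, x$rss, x$n))
  invisible(x)
}

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("vmax", "km"), estimate = c(x$vmax, x$km))
}

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, nobs = x$n)
}
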