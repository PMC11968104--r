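# Cluster annotation by lasso decomposition: each single-cell cluster
# profile is modeled as a sparse weighted sum of bulk reference profiles;
# profiles with weight above a threshold are the cluster's labels.

#' Counts-per-million scaling on a common gene set
#'
#' Restricts a gene x profile table to `common_genes` and rescales every
#' profile column to sum to 1e6.
#'
#' @param profiles tibble with a `gene` column and numeric profile columns,
#'   or a numeric matrix with gene rownames.
#' @param common_genes gene symbols shared across the datasets being
#'   compared; defaults to all genes present.
#' @return A tibble `gene` + scaled profile columns.
#' @export
cpm_scale <- function(profiles, common_genes = NULL) {
  if (is.matrix(profiles)) {
    profiles <- dplyr::bind_cols(tibble::tibble(gene = rownames(profiles)),
                                 tibble::as_tibble(profiles))
  }
  profiles <- tibble::as_tibble(profiles)
  assert_that("gene" %in% names(profiles), "profiles need a `gene` column")
  common_genes <- common_genes %||% profiles$gene
  assert_that(length(common_genes) > 0, "`common_genes` must be nonempty")
  keep <- profiles$gene %in% common_genes
  assert_that(any(keep), "no common genes present in profiles")
  out <- profiles[keep, , drop = FALSE]
  for (cn in setdiff(names(out), "gene")) {
    s <- sum(out[[cn]])
    if (s <= 0) stop("profile `", cn, "` sums to zero on the common genes", call. = FALSE)
    out[[cn]] <- out[[cn]] / s * 1e6
  }
  out
}

#' Decompose a cluster profile over a bulk reference panel by lasso
#'
#' Coordinate-descent lasso (glmnet) of the CPM-scaled cluster profile on
#' the CPM-scaled panel columns, predictors standardized internally for the
#' penalty, coefficients reported on the CPM scale. When `penalty` is
#' `NULL` it is chosen by 5-fold cross-validation over glmnet's log grid.
#'
#' @param cluster_profile named numeric vector (CPM per gene), or a tibble
#'   `gene` + one value column.
#' @param panel tibble `gene` + one column per reference profile (CPM).
#' @param penalty lasso lambda (>= 0), or `NULL` for cross-validation.
#' @param nonneg constrain weights to be non-negative.
#' @param seed seed for the cross-validation folds.
#' @return A list of class `decomposition`: `weights` (tibble `profile`,
#'   `weight`), `penalty`, `n_genes`.
#' @export
lasso_decompose <- function(cluster_profile, panel, penalty = NULL,
                            nonneg = FALSE, seed = 1L) {
  panel <- tibble::as_tibble(panel)
  assert_that("gene" %in% names(panel), "panel needs a `gene` column")
  if (is.data.frame(cluster_profile)) {
    y <- stats::setNames(cluster_profile[[setdiff(names(cluster_profile), "gene")[1]]],
                         cluster_profile$gene)
  } else {
    y <- cluster_profile
  }
  assert_that(!is.null(names(y)), "cluster profile needs gene names")
  genes <- intersect(panel$gene, names(y))
  assert_that(length(genes) >= 2, "profile and panel share too few genes")
  X <- as.matrix(panel[match(genes, panel$gene), setdiff(names(panel), "gene")])
  yv <- as.numeric(y[genes])
  if (!is.null(penalty)) {
    assert_that(penalty >= 0, "`penalty` must be >= 0")
  }
  lower <- if (nonneg) 0 else -Inf
  with_seed(seed, {
    if (is.null(penalty)) {
      cv <- glmnet::cv.glmnet(X, yv, nfolds = 5, lower.limits = lower,
                              standardize = TRUE)
      penalty <- cv$lambda.min
    }
    # descending lambda path ending at the target improves warm-start accuracy
    lambdas <- sort(unique(c(penalty, penalty * c(1000, 100, 10))), decreasing = TRUE)
    fit <- glmnet::glmnet(X, yv, lambda = lambdas, lower.limits = lower,
                          standardize = TRUE, thresh = 1e-14)
    w <- as.numeric(glmnet::coef.glmnet(fit, s = penalty, exact = TRUE,
                                        x = X, y = yv,
                                        lower.limits = lower)[-1])
  })
  structure(list(weights = tibble::tibble(profile = colnames(X), weight = w),
                 penalty = penalty, n_genes = length(genes)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d profiles, penalty = %.4g, %d genes\n",
              nrow(x$weights), x$penalty, x$n_genes))
  print(dplyr::arrange(x$weights, dplyr::desc(.data$weight)), n = 5)
  invisible(x)
}

#' Assign labels from a decomposition
#'
#' Profiles whose weight exceeds `threshold` become the cluster's labels,
#' sorted by weight descending. An empty label set (no clear match) is
#' allowed.
#'
#' @param result a [lasso_decompose()] result.
#' @param threshold minimum weight for a match.
#' @return A tibble `profile`, `weight`, largest first.
#' @export
assign_labels <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "decomposition"))
  w <- result$weights[result$weights$weight > threshold, , drop = FALSE]
  dplyr::arrange(w, dplyr::desc(.data$weight))
}

#' Annotate every cluster of a cohort against a reference panel
#'
#' Forms each cluster's profile as the mean CPM over its member cells,
#' CPM-scales panel and profiles on the common genes, and runs
#' [lasso_decompose()] + [assign_labels()] per cluster.
#'
#' @param x a [cohort()].
#' @param panel tibble `gene` + reference profile columns (raw or CPM).
#' @param penalty lasso lambda; `NULL` for per-cluster cross-validation.
#' @param threshold label weight cutoff.
#' @param seed seed passed to the decompositions.
#' @return A tibble `cluster`, `profile`, `weight`, `rank` of all matches
#'   above threshold.
#' @export
annotate_clusters <- function(x, panel, penalty = NULL, threshold = 0.1, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  common <- intersect(x$genes$gene, panel$gene)
  panel_cpm <- cpm_scale(panel, common)
  clusters <- sort(unique(x$cells$cluster))
  rows <- purrr::map(clusters, function(cl) {
    prof <- Matrix::rowMeans(x$counts[, x$cells$cluster == cl, drop = FALSE])
    prof <- stats::setNames(as.numeric(prof), x$genes$gene)[common]
    prof <- prof / sum(prof) * 1e6
    dec <- lasso_decompose(prof, panel_cpm, penalty = penalty,
                           seed = derive_seed(seed, cl))
    lab <- assign_labels(dec, threshold)
    if (nrow(lab) == 0) return(NULL)
    dplyr::mutate(lab, cluster = cl, rank = dplyr::row_number(),
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}
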