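#' QC thresholds and species presets
#'
#' `qc_thresholds()` builds a threshold set; `qc_preset()` returns the two
#' shipped presets: `"fly"` (200--7000 genes, 500--30000 counts, mito < 15%)
#' and `"human"` (500--7000 genes, 1000--30000 counts, mito < 5%, the
#' stricter mitochondrial cut appropriate for single-nucleus data).
#'
#' @param min_genes,max_genes inclusive bounds on genes detected per cell.
#' @param min_counts,max_counts inclusive bounds on total counts per cell.
#' @param max_mito_pct cells with mitochondrial percentage `>=` this value
#'   are removed (strictly-below semantics).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 0, max_genes = Inf,
                          min_counts = 0, max_counts = Inf,
                          max_mito_pct = 100) {
  assert_that(min_genes <= max_genes, "min_genes must be <= max_genes")
  assert_that(min_counts <= max_counts, "min_counts must be <= max_counts")
  assert_that(max_mito_pct >= 0 && max_mito_pct <= 100,
              "max_mito_pct must lie in [0, 100]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito_pct = max_mito_pct),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param preset `"fly"`, `"human"`, or `"none"` (identity filter).
#' @export
qc_preset <- function(preset = c("fly", "human", "none")) {
  preset <- match.arg(preset)
  switch(preset,
         fly = qc_thresholds(200, 7000, 500, 30000, 15),
         human = qc_thresholds(500, 7000, 1000, 30000, 5),
         none = qc_thresholds())
}

#' Filter cells on QC thresholds
#'
#' Retains cells whose detected-gene count and total count fall inside the
#' inclusive threshold bounds and whose mitochondrial percentage (computed
#' on raw counts) is strictly below `max_mito_pct`. The gene set is never
#' changed. The report attributes each removed cell to the first failing
#' rule, checked in the order genes, counts, mito.
#'
#' @param x a [cohort()].
#' @param thresholds a [qc_thresholds()] or preset name.
#' @return A list with `cohort` (filtered) and `report`, a tibble with
#'   `n_in`, `n_out` and one removal count per rule.
#' @export
filter_cells <- function(x, thresholds = qc_preset("fly")) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(thresholds)) thresholds <- qc_preset(thresholds)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (thresholds$max_mito_pct < 100 && !any(x$genes$mito) && nrow(x$genes) > 0) {
    if (!("mito" %in% names(x$genes))) {
      stop("mitochondrial flags required when filtering on mito percentage", call. = FALSE)
    }
  }
  qm <- cell_metrics(x)
  fail_genes <- qm$n_genes < thresholds$min_genes | qm$n_genes > thresholds$max_genes
  fail_counts <- qm$total_counts < thresholds$min_counts | qm$total_counts > thresholds$max_counts
  fail_mito <- qm$mito_pct >= thresholds$max_mito_pct
  first_fail <- dplyr::case_when(fail_genes ~ "genes",
                                 fail_counts ~ "counts",
                                 fail_mito ~ "mito",
                                 TRUE ~ "pass")
  keep <- first_fail == "pass"
  report <- tibble::tibble(n_in = nrow(qm),
                           n_out = sum(keep),
                           removed_genes = sum(first_fail == "genes"),
                           removed_counts = sum(first_fail == "counts"),
                           removed_mito = sum(first_fail == "mito"))
  list(cohort = subset_cells(x, keep), report = report)
}

# Library-size normalization to `scale_factor` counts per cell, then
# log(1 + x). Dense genes x cells matrix out.
lognormalize <- function(x, scale_factor = 1e4, log = TRUE) {
  stopifnot(inherits(x, "cohort"))
  tot <- Matrix::colSums(x$counts)
  if (any(tot == 0)) stop("cell with zero total counts; filter first", call. = FALSE)
  m <- as.matrix(x$counts %*% Matrix::Diagonal(x = scale_factor / tot))
  dimnames(m) <- dimnames(x$counts)
  if (log) log1p(m) else m
}

#' Log-normalize, regress out covariates, and scale
#'
#' Per cell: counts scaled to `scale_factor` total and `log(1 + x)`
#' transformed. Per gene: ordinary-least-squares residuals against the
#' covariates (total counts and mitochondrial percentage by default), then
#' z-scored and clipped from above at `clip_max`.
#'
#' @param x a filtered [cohort()].
#' @param scale_factor per-cell target total before the log.
#' @param clip_max upper clip applied to the z-scored values.
#' @param covariates character subset of `c("total_counts", "mito_pct")`,
#'   or `NULL` to skip the regression step.
#' @return A dense genes x cells matrix of scaled expression.
#' @export
normalize_cells <- function(x, scale_factor = 1e4, clip_max = 10,
                            covariates = c("total_counts", "mito_pct")) {
  m <- lognormalize(x, scale_factor)
  if (length(covariates) > 0) {
    qm <- cell_metrics(x)
    covariates <- match.arg(covariates, c("total_counts", "mito_pct"), several.ok = TRUE)
    X <- cbind(1, as.matrix(qm[, covariates, drop = FALSE]))
    # one QR solve covers every gene: residuals of t(m) on X
    fit <- stats::lm.fit(X, t(m))
    m <- t(fit$residuals)
    dimnames(m) <- dimnames(x$counts)
  }
  sds <- apply(m, 1, stats::sd)
  mu <- rowMeans(m)
  m <- (m - mu) / ifelse(sds > 0, sds, 1)
  m[m > clip_max] <- clip_max
  m
}
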