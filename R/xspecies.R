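# Cross-species comparison: orthologue mapping with a confidence cutoff,
# hypergeometric overlap of deregulated gene sets, and per-cell gene-set
# activity (AUC) scoring compared between groups by t-test.

#' Map genes across species through an orthologue table
#'
#' Keeps pairs with confidence `score >= min_score`; genes with several
#' surviving partners resolve to the best score, then lexicographically.
#' Unmapped genes are dropped and counted.
#'
#' @param genes character vector of source-species genes.
#' @param map tibble `fly_gene`, `human_gene`, `score` (or any
#'   source/target naming in the first two columns).
#' @param min_score minimum confidence score retained.
#' @return A tibble `gene`, `mapped`; the number of genes without any
#'   surviving pair is attached as attribute `n_unmapped`.
#' @export
map_orthologs <- function(genes, map, min_score = 5) {
  map <- tibble::as_tibble(map)
  assert_that(ncol(map) >= 3, "map needs source, target and score columns")
  names(map)[1:3] <- c("source", "target", "score")
  map <- map[map$score >= min_score & map$source %in% genes, , drop = FALSE]
  best <- map |>
    dplyr::arrange(.data$source, dplyr::desc(.data$score), .data$target) |>
    dplyr::distinct(.data$source, .keep_all = TRUE)
  out <- tibble::tibble(gene = best$source, mapped = best$target)
  attr(out, "n_unmapped") <- length(setdiff(genes, best$source))
  out
}

#' Overlap of two gene sets with a hypergeometric test
#'
#' With universe size `N`, `K = |B|` flagged genes, a draw of `n = |A|`
#' genes and `k = |A intersect B|` observed hits, reports the overlap
#' fraction `k / n` and the upper-tail hypergeometric p-value
#' `P(X >= k)`.
#'
#' @param set_a,set_b character gene sets, subsets of `universe`.
#' @param universe character gene universe.
#' @return A one-row tibble `N`, `K`, `n`, `k`, `fraction`, `p_upper`.
#'   `fraction` is `NA` when `set_a` is empty.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  assert_that(all(set_a %in% universe) && all(set_b %in% universe),
              "both sets must be subsets of the universe")
  N <- length(universe); K <- length(set_b); n <- length(set_a)
  k <- length(intersect(set_a, set_b))
  tibble::tibble(N = N, K = K, n = n, k = k,
                 fraction = if (n > 0) k / n else NA_real_,
                 p_upper = if (n > 0) {
                   stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
                 } else NA_real_)
}

#' Per-cell gene-set activity scores (recovery-curve AUC)
#'
#' For every cell, genes are ranked by expression in decreasing order
#' (ties broken at random under `seed`); the score is the area under the
#' gene-set recovery curve within the top `ceil(top_fraction * n_genes)`
#' ranks, normalized by the maximum achievable area, so scores live in
#' [0, 1].
#'
#' @param expr genes x cells expression matrix with gene rownames.
#' @param gene_set character vector of gene symbols.
#' @param top_fraction fraction of the ranking forming the scoring window.
#' @param seed integer seed for the random tie-break.
#' @return A tibble `cell`, `auc`.
#' @export
aucell_scores <- function(expr, gene_set, top_fraction = 0.05, seed = 1L) {
  expr <- as.matrix(expr)
  assert_that(!is.null(rownames(expr)), "expression matrix needs gene rownames")
  hits <- rownames(expr) %in% gene_set
  assert_that(any(hits), "gene set does not intersect the expression matrix")
  n_genes <- nrow(expr)
  W <- ceiling(top_fraction * n_genes)
  m <- sum(hits)
  max_auc <- sum(pmin(seq_len(W), m))
  with_seed(seed, {
    auc <- apply(expr, 2, function(v) {
      rk <- rank(-v, ties.method = "random")
      in_window <- rk[hits]
      in_window <- in_window[in_window <= W]
      if (length(in_window) == 0) return(0)
      # recovery curve: cumulative hits at each rank 1..W
      sum(W - in_window + 1) / max_auc
    })
    cells <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
    tibble::tibble(cell = cells, auc = as.numeric(auc))
  })
}

#' Compare gene-set activity between two groups
#'
#' Classical two-sample t-test (pooled variance by default, Welch behind
#' the flag), two-tailed.
#'
#' @param scores_a,scores_b numeric vectors (>= 2 values each).
#' @param welch use the Welch unequal-variance form.
#' @return A one-row tibble `t`, `df`, `p`.
#' @export
enrichment_test <- function(scores_a, scores_b, welch = FALSE) {
  assert_that(length(scores_a) >= 2 && length(scores_b) >= 2,
              "need at least 2 values per group")
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    if (mean(scores_a) == mean(scores_b)) {
      return(tibble::tibble(t = 0, df = length(scores_a) + length(scores_b) - 2, p = 1))
    }
    return(tibble::tibble(t = ifelse(mean(scores_a) > mean(scores_b), Inf, -Inf),
                          df = length(scores_a) + length(scores_b) - 2, p = 0))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = !welch)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}
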