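# Cross-genotype convergence: rank genes by signed differential expression
# within each genotype, sum the ranks, and keep the extreme tails as the
# commonly up- / downregulated gene sets.

#' Signed rank matrix across genotypes
#'
#' For each genotype's DE table, genes are ranked by signed significance
#' (`lfc * -log10 p`) in descending order -- rank 1 is the most strongly
#' upregulated gene -- with average ranks for ties. The gene universe is
#' the intersection across genotypes.
#'
#' @param tables named list of DE tibbles (one per genotype) with `gene`,
#'   `lfc`, `p`; or a single tibble with a `genotype` column.
#' @return A tibble with `gene` and one rank column per genotype.
#' @export
rank_genes_signed <- function(tables) {
  if (is.data.frame(tables)) {
    assert_that("genotype" %in% names(tables), "single-table input needs a genotype column")
    tables <- split(tables, tables$genotype)
  }
  assert_that(length(tables) >= 1, "need at least one table")
  scored <- lapply(tables, signed_significance)
  universe <- Reduce(intersect, lapply(scored, function(d) d$gene))
  assert_that(length(universe) > 0, "gene universes do not intersect")
  universe <- sort(universe)
  ranks <- lapply(scored, function(d) {
    s <- d$signed_score[match(universe, d$gene)]
    rank(-s)
  })
  names(ranks) <- names(tables) %||% paste0("genotype", seq_along(ranks))
  dplyr::bind_cols(tibble::tibble(gene = universe), tibble::as_tibble(ranks))
}

#' Aggregate signed ranks and retain the extreme tails
#'
#' Sums each gene's rank across genotypes and keeps the first
#' `ceil(tail_fraction * n)` genes (smallest summed rank: commonly
#' upregulated) and the last as commonly downregulated. Ties at tail
#' boundaries break by summed rank then gene id.
#'
#' @param rank_matrix output of [rank_genes_signed()] (>= 2 genotype columns).
#' @param tail_fraction tail size as a fraction of the ranked universe;
#'   must be <= 0.5 so the tails cannot overlap.
#' @return A list of class `convergence_result`: `summed` (tibble `gene`,
#'   `summed_rank`, sorted ascending), `common_up`, `common_down`,
#'   `tail_fraction`.
#' @export
aggregate_ranks <- function(rank_matrix, tail_fraction = 0.05) {
  gcols <- setdiff(names(rank_matrix), "gene")
  assert_that(length(gcols) >= 2, "need ranks from at least 2 genotypes")
  assert_that(tail_fraction > 0 && tail_fraction <= 0.5,
              "`tail_fraction` must lie in (0, 0.5] so the tails cannot overlap")
  summed <- tibble::tibble(gene = rank_matrix$gene,
                           summed_rank = rowSums(as.matrix(rank_matrix[gcols])))
  summed <- dplyr::arrange(summed, .data$summed_rank, .data$gene)
  n <- nrow(summed)
  k <- ceiling(tail_fraction * n)
  structure(list(summed = summed,
                 common_up = summed$gene[seq_len(k)],
                 common_down = summed$gene[seq(n - k + 1, n)],
                 tail_fraction = tail_fraction),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("<convergence_result> %d genes ranked; %d%% tails: %d up, %d down\n",
              nrow(x$summed), round(100 * x$tail_fraction),
              length(x$common_up), length(x$common_down)))
  invisible(x)
}
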