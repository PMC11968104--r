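# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small planted cohort: 2 mutants + control, 6 clusters (1-2 vulnerable),
# 300 genes, strong planted effects. Used wherever a recoverable signal is
# needed without paying for a full-size cohort.
small_gen <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- cohort_config(n_genotypes = 2, n_clusters = 6,
                         cluster_size_median = 60, n_genes = 300,
                         vulnerable_clusters = 1:2, n_deg_per_vulnerable = 30,
                         lfc_magnitude = 2, shared_fraction = 0.5, seed = 7)
    .fixtures$small <- generate_cohort(cfg)
  }
  .fixtures$small
}

# Exhaustive-enumeration oracle for the two-sided Wilcoxon rank-sum test:
# every C(n1+n2, n1) assignment of the pooled observations to the first
# group, p = 2 * min(P(U <= u), P(U >= u)) capped at 1. Valid without ties.
enum_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  r <- rank(vals)
  splits <- utils::combn(length(vals), n1)
  U_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_lo <- mean(U_all <= u_obs)
  p_hi <- mean(U_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from
# the universe and count those with >= k hits in the flagged set.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  flagged <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% flagged))
  mean(hits >= k)
}

# Reference Benjamini-Hochberg step-up, written independently of p.adjust.
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
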