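# Per-cluster mutant-vs-control differential expression, two routes:
# Wilcoxon rank-sum on normalized expression, and a pseudobulk NB GLM.

# Vectorized two-sided Wilcoxon rank-sum p-values across the rows of a
# matrix. Uses the exact null distribution (stats::pwilcox) for small
# untied samples and the tie-corrected normal approximation with
# continuity correction otherwise -- the same switch stats::wilcox.test
# makes, applied row-wise.
ranksum_rows <- function(m, grp1) {
  n1 <- sum(grp1); n2 <- sum(!grp1); N <- n1 + n2
  ranks <- t(apply(m, 1, rank))
  r1 <- rowSums(ranks[, grp1, drop = FALSE])
  U <- r1 - n1 * (n1 + 1) / 2
  # tie correction term per gene
  tie_term <- apply(m, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t * t * t) - N
  })
  has_ties <- tie_term > 0
  p <- numeric(nrow(m))
  exact_ok <- !has_ties & N < 50
  if (any(exact_ok)) {
    u <- U[exact_ok]
    lo <- stats::pwilcox(u, n1, n2)
    hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p[exact_ok] <- pmin(1, 2 * pmin(lo, hi))
  }
  if (any(!exact_ok)) {
    u <- U[!exact_ok]
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term[!exact_ok] / (N * (N - 1)))
    z <- u - n1 * n2 / 2
    z <- sign(z) * pmax(0, abs(z) - 0.5) / sqrt(pmax(sigma2, 0))
    z[!is.finite(z)] <- 0
    p[!exact_ok] <- 2 * stats::pnorm(-abs(z))
  }
  pmin(p, 1)
}

#' Rank-sum differential expression for one cluster
#'
#' Compares normalized expression of mutant vs. control cells within one
#' cluster, gene by gene, with a two-sided Wilcoxon rank-sum test. Log2
#' fold changes are computed on the linear normalized scale with a small
#' pseudo-count; p-values are BH-adjusted over genes.
#'
#' @param x a [cohort()].
#' @param cluster cluster id.
#' @param mutant,control genotype labels.
#' @param scale_factor per-cell normalization target.
#' @param min_cells below this many cells in either arm the cluster is
#'   skipped (returns `NULL` with a warning).
#' @return A tibble `gene`, `lfc`, `p`, `p_adj`, `method = "ranksum"`.
#' @export
ranksum_de <- function(x, cluster, mutant, control = "control",
                       scale_factor = 1e4, min_cells = 3) {
  stopifnot(inherits(x, "cohort"))
  idx <- x$cells$cluster == cluster & x$cells$genotype %in% c(mutant, control)
  sub <- subset_cells(x, idx)
  grp1 <- sub$cells$genotype == mutant
  if (sum(grp1) < min_cells || sum(!grp1) < min_cells) {
    warning(sprintf("cluster %s: fewer than %d cells in one arm; skipped",
                    as.character(cluster), min_cells))
    return(NULL)
  }
  norm <- lognormalize(sub, scale_factor, log = FALSE)
  logn <- log1p(norm)
  p <- ranksum_rows(logn, grp1)
  eps <- 1e-9 * scale_factor
  lfc <- unname(log2((rowMeans(norm[, grp1, drop = FALSE]) + eps) /
                     (rowMeans(norm[, !grp1, drop = FALSE]) + eps)))
  tibble::tibble(gene = sub$genes$gene, lfc = lfc, p = p,
                 p_adj = stats::p.adjust(p, method = "BH"),
                 method = "ranksum")
}

#' Group cells of a cluster into per-run pseudobulks
#'
#' Sums gene counts of all cells sharing an experimental run (within one
#' cluster and genotype). Pseudobulks with fewer than `min_cells` cells are
#' dropped.
#'
#' @param x a [cohort()].
#' @param cluster cluster id.
#' @param min_cells minimum cells per retained pseudobulk.
#' @return A tibble with `run`, `genotype`, `cluster`, `n_cells`, and a
#'   list-column `counts` of named gene-count vectors; zero rows when
#'   nothing passes the size filter.
#' @export
make_pseudobulks <- function(x, cluster, min_cells = 10) {
  stopifnot(inherits(x, "cohort"))
  idx <- which(x$cells$cluster == cluster)
  if (length(idx) == 0) {
    return(tibble::tibble(run = character(0), genotype = character(0),
                          cluster = integer(0), n_cells = integer(0),
                          counts = list()))
  }
  key <- paste(x$cells$run[idx], x$cells$genotype[idx], sep = "\r")
  groups <- split(idx, key)
  rows <- purrr::map(groups, function(ii) {
    tibble::tibble(run = x$cells$run[ii[1]],
                   genotype = x$cells$genotype[ii[1]],
                   cluster = cluster,
                   n_cells = length(ii),
                   counts = list(stats::setNames(
                     as.numeric(Matrix::rowSums(x$counts[, ii, drop = FALSE])),
                     x$genes$gene)))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  dplyr::arrange(out, .data$genotype, .data$run)
}

# Negative-binomial GLM fit, vectorized across genes.
# Y: genes x samples counts; g: 0/1 genotype indicator per sample;
# offset: per-sample log size factor. Model log mu = b0 + b1 g + offset.
# Per gene: Fisher-scoring for (b0, b1) given alpha, ML update of alpha
# given the means, alternated. Returns b0, b1, se_b1, alpha.
nbglm_fit <- function(Y, g, offset, n_outer = 4, floor_alpha = 1e-8) {
  G <- nrow(Y); S <- ncol(Y)
  X2 <- matrix(g, nrow = 1)
  off <- matrix(offset, nrow = G, ncol = S, byrow = TRUE)
  # init: group log means relative to offset
  b0 <- b1 <- numeric(G)
  mean0 <- rowSums(Y[, g == 0, drop = FALSE]) / sum(exp(offset[g == 0]))
  mean1 <- rowSums(Y[, g == 1, drop = FALSE]) / sum(exp(offset[g == 1]))
  b0 <- log(pmax(mean0, 1e-8))
  b1 <- log(pmax(mean1, 1e-8)) - b0
  alpha <- rep(0.1, G)
  gv <- matrix(g, nrow = G, ncol = S, byrow = TRUE)
  for (outer in seq_len(n_outer)) {
    # Fisher scoring on (b0, b1), all genes at once
    for (it in 1:50) {
      eta <- matrix(b0, G, S) + matrix(b1, G, S) * gv + off
      mu <- exp(pmin(eta, 30))
      W <- mu / (1 + alpha * mu)
      resid <- (Y - mu) / (1 + alpha * mu)
      U0 <- rowSums(resid)
      U1 <- rowSums(resid * gv)
      I00 <- rowSums(W)
      I01 <- rowSums(W * gv)
      I11 <- I01 # gv is 0/1 so W*g^2 = W*g
      det <- I00 * I11 - I01^2
      det[det < 1e-12] <- 1e-12
      d0 <- (I11 * U0 - I01 * U1) / det
      d1 <- (I00 * U1 - I01 * U0) / det
      d0[!is.finite(d0)] <- 0; d1[!is.finite(d1)] <- 0
      d0 <- pmin(pmax(d0, -5), 5); d1 <- pmin(pmax(d1, -5), 5)
      b0 <- b0 + d0; b1 <- b1 + d1
      if (max(abs(c(d0, d1))) < 1e-10) break
    }
    eta <- matrix(b0, G, S) + matrix(b1, G, S) * gv + off
    mu <- exp(pmin(eta, 30))
    # Cox-Reid adjusted profile likelihood for the dispersion: the plain
    # profile ML underestimates alpha badly at pseudobulk sample sizes,
    # inflating the Wald test; the CR term corrects for estimating the
    # two mean parameters.
    alpha <- vapply(seq_len(G), function(i) {
      y <- Y[i, ]; m <- mu[i, ]
      if (all(y == 0)) return(floor_alpha)
      nll <- function(la) {
        a <- exp(la)
        w <- m / (1 + a * m)
        i00 <- sum(w); i01 <- sum(w * g)
        cr <- 0.5 * log(max(i00 * i01 - i01^2, 1e-12))
        -(sum(stats::dnbinom(y, mu = m, size = 1 / a, log = TRUE)) - cr)
      }
      opt <- stats::optimize(nll, interval = c(log(floor_alpha), log(100)))
      exp(opt$minimum)
    }, numeric(1))
    alpha <- pmax(alpha, floor_alpha)
  }
  eta <- matrix(b0, G, S) + matrix(b1, G, S) * gv + off
  mu <- exp(pmin(eta, 30))
  W <- mu / (1 + alpha * mu)
  I00 <- rowSums(W); I01 <- rowSums(W * gv); I11 <- I01
  det <- pmax(I00 * I11 - I01^2, 1e-12)
  se_b1 <- sqrt(I00 / det)
  list(b0 = b0, b1 = b1, se_b1 = se_b1, alpha = alpha)
}

#' Pseudobulk negative-binomial differential expression
#'
#' Fits, per gene, a negative-binomial GLM with log link on the genotype
#' indicator with a log-total-count offset, dispersion estimated by
#' Cox-Reid adjusted maximum likelihood (floored at 1e-8, no shrinkage),
#' and tests the genotype coefficient with a Wald statistic referenced to
#' a t distribution on (pseudobulks - 2) df. Requires at least two pseudobulks per
#' arm; otherwise the contrast is skipped with a warning.
#'
#' @param pseudobulks tibble from [make_pseudobulks()] (may span genotypes).
#' @param mutant,control genotype labels.
#' @return A tibble `gene`, `lfc` (log2), `p`, `p_adj`,
#'   `method = "pseudobulk_nb"`, or `NULL` if skipped.
#' @export
pseudobulk_de <- function(pseudobulks, mutant, control = "control") {
  pb <- pseudobulks[pseudobulks$genotype %in% c(mutant, control), , drop = FALSE]
  n_mut <- sum(pb$genotype == mutant)
  n_ctl <- sum(pb$genotype == control)
  if (n_mut < 2 || n_ctl < 2) {
    warning("fewer than 2 pseudobulks per arm; contrast skipped")
    return(NULL)
  }
  Y <- do.call(cbind, pb$counts)
  g <- as.numeric(pb$genotype == mutant)
  libsize <- colSums(Y)
  if (any(libsize == 0)) stop("pseudobulk with zero total counts", call. = FALSE)
  offset <- log(libsize)
  fit <- nbglm_fit(Y, g, offset)
  z <- fit$b1 / fit$se_b1
  nonzero <- rowSums(Y) > 0
  # Wald statistic referenced to t with S - 2 df: with a handful of
  # pseudobulks the normal reference is anticonservative
  p <- 2 * stats::pt(-abs(z), df = length(g) - 2)
  p[!nonzero] <- NA_real_
  lfc <- fit$b1 / log(2)
  lfc[!nonzero] <- 0
  tibble::tibble(gene = rownames(Y), lfc = unname(lfc), p = unname(p),
                 p_adj = unname(stats::p.adjust(p, method = "BH")),
                 method = "pseudobulk_nb")
}

#' Signed significance score
#'
#' `lfc * (-log10 p)`: significant upregulated genes score large positive,
#' significant downregulated genes large negative. p-values of exactly 0
#' are floored at 1e-300.
#'
#' @param table a DE tibble with `lfc` and `p`.
#' @return The table with a `signed_score` column appended.
#' @export
signed_significance <- function(table) {
  p_floored <- pmax(table$p, 1e-300)
  dplyr::mutate(table, signed_score = .data$lfc * (-log10(p_floored)))
}

#' Spearman concordance of two DE tables
#'
#' Spearman correlation (average-rank ties) of the signed significance
#' scores of two DE tables on their shared gene universe.
#'
#' @param table_a,table_b DE tibbles with `gene`, `lfc`, `p`.
#' @return Spearman rho (a single number).
#' @export
method_concordance <- function(table_a, table_b) {
  a <- signed_significance(table_a)
  b <- signed_significance(table_b)
  shared <- intersect(a$gene[!is.na(a$signed_score)], b$gene[!is.na(b$signed_score)])
  assert_that(length(shared) >= 3, "need at least 3 shared genes")
  sa <- a$signed_score[match(shared, a$gene)]
  sb <- b$signed_score[match(shared, b$gene)]
  stats::cor(sa, sb, method = "spearman")
}

#' Downsample a cluster to equal arm sizes
#'
#' Draws a uniform random subset of `n` cells per genotype arm within one
#' cluster (seeded), leaving all other cells untouched. Used to correct
#' DEG counts for cluster-size bias.
#'
#' @param x a [cohort()].
#' @param cluster cluster id.
#' @param n cells to keep per genotype within the cluster.
#' @param seed integer seed.
#' @return A [cohort()] with the cluster downsampled.
#' @export
downsample_cluster <- function(x, cluster, n, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  in_cl <- x$cells$cluster == cluster
  keep <- !in_cl
  with_seed(seed, {
    for (g in unique(x$cells$genotype[in_cl])) {
      idx <- which(in_cl & x$cells$genotype == g)
      if (length(idx) < n) {
        stop(sprintf("cluster %s genotype %s has %d < n = %d cells",
                     as.character(cluster), g, length(idx), n), call. = FALSE)
      }
      keep[sample(idx, n)] <- TRUE
    }
  })
  subset_cells(x, keep)
}

#' Run a DE route over every cluster x mutant contrast
#'
#' @param x a [cohort()].
#' @param route `"ranksum"` or `"pseudobulk_nb"`.
#' @param control control genotype label.
#' @param clusters cluster ids (default: all).
#' @param min_cells skip threshold passed to the route.
#' @return A tibble of per-gene DE rows with `genotype` and `cluster`
#'   columns prepended.
#' @export
de_all <- function(x, route = c("ranksum", "pseudobulk_nb"),
                   control = "control", clusters = NULL, min_cells = NULL) {
  route <- match.arg(route)
  stopifnot(inherits(x, "cohort"))
  assert_that(control %in% x$cells$genotype, "control genotype absent from cohort")
  clusters <- clusters %||% sort(unique(x$cells$cluster))
  mutants <- setdiff(unique(x$cells$genotype), control)
  out <- list()
  for (cl in clusters) {
    pb <- if (route == "pseudobulk_nb") make_pseudobulks(x, cl) else NULL
    for (g in mutants) {
      tab <- if (route == "ranksum") {
        ranksum_de(x, cl, g, control, min_cells = min_cells %||% 3)
      } else {
        pseudobulk_de(pb, g, control)
      }
      if (!is.null(tab)) {
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(genotype = g, cluster = cl)[rep(1, nrow(tab)), ], tab)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Count differential genes per cluster x genotype contrast
#'
#' @param de_tables output of [de_all()].
#' @param x the cohort the tables came from (for arm cell counts).
#' @param alpha adjusted-p significance cutoff for calling a DEG.
#' @param control control genotype label.
#' @return A tibble `genotype`, `cluster`, `y` (nDEG), `x1` (mutant cells),
#'   `x2` (control cells) -- the vulnerability model's inputs.
#' @export
cluster_stats <- function(de_tables, x, alpha = 0.05, control = "control") {
  stopifnot(inherits(x, "cohort"))
  ndeg <- de_tables |>
    dplyr::group_by(.data$genotype, .data$cluster) |>
    dplyr::summarise(y = sum(.data$p_adj < alpha, na.rm = TRUE), .groups = "drop")
  sizes <- x$cells |>
    dplyr::count(.data$genotype, .data$cluster, name = "n_cells")
  ctl <- sizes[sizes$genotype == control, c("cluster", "n_cells")]
  names(ctl)[2] <- "x2"
  ndeg |>
    dplyr::left_join(dplyr::rename(sizes, x1 = "n_cells"),
                     by = c("genotype", "cluster")) |>
    dplyr::left_join(ctl, by = "cluster")
}
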