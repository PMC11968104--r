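#' Configuration for a synthetic multi-genotype cohort
#'
#' Defaults describe the regime the pipeline is designed for: five mutant
#' genotypes against one wild-type control, tens of clusters whose sizes
#' follow a log-normal law, sparse brain-like expression (median baseline
#' 0.5 counts per cell per gene), overdispersed counts, and a handful of
#' "vulnerable" clusters that carry planted differentially expressed genes
#' partially shared across genotypes.
#'
#' @param n_genotypes number of mutant genotypes (the control is added on
#'   top and is always named `"control"`).
#' @param n_clusters number of cell clusters.
#' @param cluster_size_median,cluster_size_sdlog log-normal law for cells
#'   per cluster per genotype (median cells, log-scale SD).
#' @param n_genes number of genes.
#' @param mito_fraction fraction of genes flagged mitochondrial.
#' @param n_runs_per_genotype experimental runs per genotype; cells are
#'   assigned to runs round-robin so each run holds cells of every cluster.
#' @param vulnerable_clusters integer ids of clusters carrying planted
#'   effects in mutant genotypes.
#' @param n_deg_per_vulnerable planted differentially expressed genes per
#'   vulnerable cluster per genotype.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param shared_fraction fraction of each genotype's planted genes drawn
#'   from one common pool (same genes, same signs, in every genotype).
#' @param baseline_nb_dispersion negative-binomial dispersion alpha of the
#'   counts (variance mu + alpha mu^2); 0 gives Poisson counts.
#' @param gene_mean_median,gene_mean_sdlog log-normal law for baseline gene
#'   means (counts per cell).
#' @param cluster_profile_sdlog log-scale SD of the per-(gene, cluster)
#'   identity factor that makes cluster expression profiles distinct.
#' @param seed integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genotypes = 5,
                          n_clusters = 20,
                          cluster_size_median = 200,
                          cluster_size_sdlog = 0.3,
                          n_genes = 2000,
                          mito_fraction = 0.05,
                          n_runs_per_genotype = 4,
                          vulnerable_clusters = 1:3,
                          n_deg_per_vulnerable = 200,
                          lfc_magnitude = 1,
                          shared_fraction = 0.5,
                          baseline_nb_dispersion = 0.5,
                          gene_mean_median = 0.5,
                          gene_mean_sdlog = 1,
                          cluster_profile_sdlog = 0.5,
                          seed = 1L) {
  cfg <- list(n_genotypes = n_genotypes, n_clusters = n_clusters,
              cluster_size_median = cluster_size_median,
              cluster_size_sdlog = cluster_size_sdlog,
              n_genes = n_genes, mito_fraction = mito_fraction,
              n_runs_per_genotype = n_runs_per_genotype,
              vulnerable_clusters = as.integer(vulnerable_clusters),
              n_deg_per_vulnerable = n_deg_per_vulnerable,
              lfc_magnitude = lfc_magnitude,
              shared_fraction = shared_fraction,
              baseline_nb_dispersion = baseline_nb_dispersion,
              gene_mean_median = gene_mean_median,
              gene_mean_sdlog = gene_mean_sdlog,
              cluster_profile_sdlog = cluster_profile_sdlog,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_genotypes", "n_clusters", "n_genes", "n_runs_per_genotype")
  for (f in counts) assert_that(cfg[[f]] >= 1, paste0("`", f, "` must be a positive count"))
  props <- c("mito_fraction", "shared_fraction")
  for (f in props) {
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste0("`", f, "` must lie in [0, 1]"))
  }
  assert_that(cfg$baseline_nb_dispersion >= 0, "`baseline_nb_dispersion` must be >= 0")
  assert_that(cfg$n_deg_per_vulnerable >= 0, "`n_deg_per_vulnerable` must be >= 0")
  assert_that(all(cfg$vulnerable_clusters %in% seq_len(cfg$n_clusters)),
              "`vulnerable_clusters` must be a subset of 1..n_clusters")
  invisible(cfg)
}

rnb <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a gene x cell negative-binomial count matrix for `n_genotypes`
#' mutants plus a `"control"` genotype. Every cluster has its own expression
#' profile (baseline gene means times a per-cluster log-normal identity
#' factor); in mutant genotypes the vulnerable clusters additionally carry
#' planted differentially expressed genes whose means are multiplied by
#' `2^(+/- lfc_magnitude)`. A `shared_fraction` of each genotype's planted
#' genes comes from one common signed pool, so convergence across genotypes
#' is a recoverable ground truth.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `cohort` (a [cohort()]) and `truth`, a list
#'   holding `planted_deg` (tibble: genotype, cluster, gene, sign, lfc),
#'   `shared_up`, `shared_down`, and `vulnerable_clusters`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n_mito <- round(config$mito_fraction * config$n_genes)
    gene_names <- c(sprintf("mt:gene%04d", seq_len(n_mito)),
                    sprintf("gene%04d", seq_len(config$n_genes - n_mito)))
    genes <- tibble::tibble(gene = gene_names,
                            mito = seq_len(config$n_genes) <= n_mito)
    base_mean <- stats::rlnorm(config$n_genes,
                               meanlog = log(config$gene_mean_median),
                               sdlog = config$gene_mean_sdlog)
    # per-(gene, cluster) identity factor: clusters get distinct profiles
    clfac <- matrix(stats::rlnorm(config$n_genes * config$n_clusters,
                                  0, config$cluster_profile_sdlog),
                    nrow = config$n_genes)
    mu_gc <- base_mean * clfac

    genotypes <- c("control", sprintf("mut%d", seq_len(config$n_genotypes)))
    sizes <- matrix(pmax(0L, as.integer(round(stats::rlnorm(
      length(genotypes) * config$n_clusters,
      meanlog = log(config$cluster_size_median),
      sdlog = config$cluster_size_sdlog)))),
      nrow = length(genotypes),
      dimnames = list(genotypes, NULL))
    if (any(sizes < 1)) {
      stop("cluster size draw produced an empty cluster; increase cluster_size_median",
           call. = FALSE)
    }

    # planted truth: one shared signed pool + genotype-specific extras
    n_deg <- config$n_deg_per_vulnerable
    n_shared <- round(config$shared_fraction * n_deg)
    planted <- NULL
    shared_up <- character(0)
    shared_down <- character(0)
    if (n_deg > 0 && length(config$vulnerable_clusters) > 0 && config$n_genotypes > 0) {
      shared_idx <- sample.int(config$n_genes, n_shared)
      shared_sign <- rep_len(c(1, -1), n_shared)
      shared_up <- gene_names[shared_idx[shared_sign > 0]]
      shared_down <- gene_names[shared_idx[shared_sign < 0]]
      rest <- setdiff(seq_len(config$n_genes), shared_idx)
      rows <- list()
      for (g in setdiff(genotypes, "control")) {
        own_idx <- sample(rest, n_deg - n_shared)
        own_sign <- sample(c(1, -1), length(own_idx), replace = TRUE)
        for (cl in config$vulnerable_clusters) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            genotype = g, cluster = cl,
            gene = c(gene_names[shared_idx], gene_names[own_idx]),
            sign = c(shared_sign, own_sign),
            lfc = config$lfc_magnitude * c(shared_sign, own_sign))
        }
      }
      planted <- dplyr::bind_rows(rows)
    } else {
      planted <- tibble::tibble(genotype = character(0), cluster = integer(0),
                                gene = character(0), sign = numeric(0), lfc = numeric(0))
    }

    blocks <- list()
    cells <- list()
    for (g in genotypes) {
      g_cells <- 0L
      for (cl in seq_len(config$n_clusters)) {
        n_c <- sizes[g, cl]
        mu <- mu_gc[, cl]
        pl <- planted[planted$genotype == g & planted$cluster == cl, ]
        if (nrow(pl) > 0) {
          idx <- match(pl$gene, gene_names)
          mu[idx] <- mu[idx] * 2^pl$lfc
        }
        blocks[[length(blocks) + 1L]] <- matrix(
          rnb(config$n_genes * n_c, mu = rep(mu, n_c),
              alpha = config$baseline_nb_dispersion),
          nrow = config$n_genes)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          genotype = g, cluster = cl,
          run = sprintf("%s_run%d", g,
                        ((g_cells + seq_len(n_c) - 1L) %% config$n_runs_per_genotype) + 1L))
        g_cells <- g_cells + n_c
      }
    }
    counts <- do.call(cbind, blocks)
    cell_tbl <- dplyr::bind_rows(cells)
    cell_tbl$cell_id <- sprintf("cell%06d", seq_len(nrow(cell_tbl)))
    cell_tbl <- cell_tbl[, c("cell_id", "genotype", "run", "cluster")]

    list(cohort = cohort(counts, cell_tbl, genes),
         truth = list(planted_deg = planted,
                      shared_up = shared_up,
                      shared_down = shared_down,
                      vulnerable_clusters = config$vulnerable_clusters))
  })
}

#' Synthesize a bulk reference panel from a cohort
#'
#' One reference profile per cluster: the cluster's mean raw counts,
#' perturbed gene-wise by multiplicative log-normal noise of log-scale SD
#' `noise_sd`. Emulates bulk transcriptomes of sorted cell populations for
#' the lasso annotation module.
#'
#' @param x a [cohort()].
#' @param noise_sd log-scale SD of the multiplicative noise (0 = exact
#'   cluster means).
#' @param seed integer seed.
#' @return A tibble with a `gene` column and one numeric column per cluster
#'   profile (named `ref_<cluster>`).
#' @export
generate_bulk_references <- function(x, noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  clusters <- sort(unique(x$cells$cluster))
  with_seed(seed, {
    profs <- vapply(clusters, function(cl) {
      idx <- x$cells$cluster == cl
      if (!any(idx)) stop("cluster ", cl, " has no cells", call. = FALSE)
      m <- Matrix::rowMeans(x$counts[, idx, drop = FALSE])
      if (noise_sd > 0) m <- m * stats::rlnorm(length(m), 0, noise_sd)
      m
    }, numeric(nrow(x$counts)))
    colnames(profs) <- paste0("ref_", clusters)
    dplyr::bind_cols(tibble::tibble(gene = x$genes$gene),
                     tibble::as_tibble(profs))
  })
}

#' Synthesize a fly-to-human orthologue map with confidence scores
#'
#' Each fly gene is paired with 0 to `max_pairs` human genes, each pair
#' carrying an integer confidence score drawn uniformly from `score_range`
#' (the DIOPT-score analogue).
#'
#' @param fly_genes,human_genes character vectors of gene symbols.
#' @param score_range length-2 integer interval for scores.
#' @param max_pairs maximum human partners per fly gene.
#' @param p_unmapped probability a fly gene has no partner.
#' @param seed integer seed.
#' @return A tibble `fly_gene`, `human_gene`, `score` with unique pairs.
#' @export
generate_ortholog_map <- function(fly_genes, human_genes,
                                  score_range = c(1L, 15L),
                                  max_pairs = 2L, p_unmapped = 0.2,
                                  seed = 1L) {
  assert_that(length(fly_genes) > 0 && length(human_genes) > 0,
              "gene lists must be nonempty")
  assert_that(length(score_range) == 2 && score_range[2] >= score_range[1],
              "`score_range` must be a nondegenerate or singleton integer interval")
  with_seed(seed, {
    n_pairs <- ifelse(stats::runif(length(fly_genes)) < p_unmapped, 0L,
                      sample.int(max_pairs, length(fly_genes), replace = TRUE))
    fly <- rep(fly_genes, n_pairs)
    hum <- sample(human_genes, length(fly), replace = TRUE)
    score_vals <- seq.int(score_range[1], score_range[2])
    sc <- score_vals[sample.int(length(score_vals), length(fly), replace = TRUE)]
    dplyr::distinct(tibble::tibble(fly_gene = fly, human_gene = hum, score = as.integer(sc)),
                    .data$fly_gene, .data$human_gene, .keep_all = TRUE)
  })
}

#' Synthesize fluorescence traces with planted spikes
#'
#' Traces are `baseline + spike_amp * (frame in spike_times) + N(0, noise_sd)`
#' per frame, one column per ROI, the convention used throughout the
#' calcium-imaging scores.
#'
#' @param n_rois number of regions of interest (columns).
#' @param n_frames frames per trace (rows).
#' @param frame_rate acquisition rate in Hz (metadata; must be positive).
#' @param baseline basal fluorescence level (arbitrary units, > 0).
#' @param spike_times integer frame indices receiving a spike, applied to
#'   every ROI; or a list of length `n_rois` with per-ROI frames.
#' @param spike_amp additive spike amplitude (same units as `baseline`).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return A list of class `trace_set`: `F` (frames x ROI matrix),
#'   `frame_rate`, and `spike_times` (the planted truth, as a list).
#' @export
generate_traces <- function(n_rois, n_frames = 300, frame_rate = 5,
                            baseline = 10, spike_times = integer(0),
                            spike_amp = 5, noise_sd = 0.1, seed = 1L) {
  assert_that(n_rois > 0, "`n_rois` must be positive")
  assert_that(frame_rate > 0, "`frame_rate` must be positive")
  if (!is.list(spike_times)) spike_times <- rep(list(as.integer(spike_times)), n_rois)
  assert_that(length(spike_times) == n_rois, "one spike-time vector per ROI required")
  with_seed(seed, {
    F <- matrix(baseline, nrow = n_frames, ncol = n_rois)
    for (j in seq_len(n_rois)) F[spike_times[[j]], j] <- F[spike_times[[j]], j] + spike_amp
    if (noise_sd > 0) F <- F + matrix(stats::rnorm(n_frames * n_rois, 0, noise_sd), n_frames)
    structure(list(F = F, frame_rate = frame_rate, spike_times = spike_times),
              class = "trace_set")
  })
}
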