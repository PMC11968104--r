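# End-to-end orchestration: a single config (R list or YAML file) drives
# simulate -> qc -> de -> vuln -> converge -> xspecies -> annotate ->
# saturate -> pheno, with per-stage seeds derived from one global seed and
# a JSON manifest of outputs and their hashes.

pipeline_stage_order <- c("simulate", "qc", "de", "vuln", "converge",
                          "xspecies", "annotate", "saturate", "pheno")

default_run_config <- function() {
  list(
    seed = 1L,
    control = "control",
    out_dir = NULL,
    stages = pipeline_stage_order,
    cohort = list(),
    qc = list(preset = "fly"),
    de = list(routes = c("ranksum", "pseudobulk_nb"), alpha = 0.05),
    vuln = list(top_k = 3),
    converge = list(tail_fraction = 0.05),
    xspecies = list(min_score = 5),
    annotate = list(noise_sd = 0.1, threshold = 0.1),
    saturate = list(max_n = NULL, step = 100, reps = 10, threshold = 5),
    pheno = list()
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, checks stage names and order, and
#' requires the control genotype. Used by [run_pipeline()] and its dry-run
#' mode.
#'
#' @param config named list, or path to a YAML file.
#' @return The completed config list, invisibly on error-free validation.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  assert_that(all(cfg$stages %in% pipeline_stage_order),
              paste("unknown stages:",
                    paste(setdiff(cfg$stages, pipeline_stage_order), collapse = ", ")))
  ord <- match(cfg$stages, pipeline_stage_order)
  assert_that(!is.unsorted(ord), "stages must follow the pipeline order")
  assert_that(identical(cfg$control, "control"),
              "the cohort's reference genotype `control` is required")
  cfg$cohort$seed <- cfg$cohort$seed %||% derive_seed(cfg$seed, "simulate")
  invisible(cfg)
}

#' Run the pipeline end-to-end
#'
#' Executes the configured stages on a synthetic cohort, writing each
#' stage's tables under `out_dir` and returning a manifest (also written
#' as `manifest.json`) with the config, per-stage seeds, and an MD5 hash
#' of every output file. Deterministic stages reproduce identical hashes
#' under identical configs.
#'
#' @param config named list or YAML path; see [validate_run_config()].
#' @param dry_run validate the full config and return the planned stages
#'   without touching any output.
#' @return The manifest list, invisibly; the dry-run returns the validated
#'   config.
#' @export
run_pipeline <- function(config = list(), dry_run = FALSE) {
  cfg <- validate_run_config(config)
  if (dry_run) return(cfg)
  assert_that(!is.null(cfg$out_dir), "`out_dir` is required unless dry_run = TRUE")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_tsv(tbl, path)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- run_stage("simulate", {
    gen <- generate_cohort(do.call(cohort_config, cfg$cohort))
    if ("simulate" %in% cfg$stages) {
      write_cohort(gen$cohort, file.path(cfg$out_dir, "cohort"), truth = gen$truth)
      outputs <- c(outputs, file.path(cfg$out_dir, "cohort",
                                      c("matrix.mtx", "cells.tsv", "genes.tsv", "truth.json")))
    }
    gen
  })
  x <- sim$cohort

  if ("qc" %in% cfg$stages) {
    run_stage("qc", {
      f <- filter_cells(x, qc_preset(cfg$qc$preset))
      emit(f$report, "qc_report.tsv")
      x <- f$cohort
    })
  }

  de_tabs <- list()
  if ("de" %in% cfg$stages) {
    run_stage("de", {
      for (route in cfg$de$routes) {
        de_tabs[[route]] <- de_all(x, route = route, control = cfg$control)
        emit(de_tabs[[route]], paste0("de_", route, ".tsv"))
      }
    })
  }

  resid_tbl <- NULL
  if ("vuln" %in% cfg$stages) {
    run_stage("vuln", {
      stats_tbl <- cluster_stats(de_tabs[[1]], x, alpha = cfg$de$alpha,
                                 control = cfg$control)
      resids <- stats_tbl |>
        dplyr::group_by(.data$genotype) |>
        dplyr::group_map(~ dplyr::mutate(
          cluster_residuals(fit_ndeg_model(.x)), genotype = .y$genotype)) |>
        dplyr::bind_rows()
      resid_tbl <- resids
      emit(resids, "residuals.tsv")
      emit(rank_vulnerable(resids, top_k = cfg$vuln$top_k), "vulnerable_clusters.tsv")
    })
  }

  conv <- NULL
  if ("converge" %in% cfg$stages) {
    run_stage("converge", {
      vuln_cl <- sim$truth$vulnerable_clusters
      tabs <- de_tabs[[1]] |>
        dplyr::filter(.data$cluster %in% vuln_cl)
      conv <- aggregate_ranks(rank_genes_signed(tabs),
                               tail_fraction = cfg$converge$tail_fraction)
      emit(conv$summed, "summed_ranks.tsv")
      emit(tibble::tibble(gene = c(conv$common_up, conv$common_down),
                          tail = rep(c("up", "down"),
                                     c(length(conv$common_up), length(conv$common_down)))),
           "common_tails.tsv")
    })
  }

  if ("xspecies" %in% cfg$stages && !is.null(conv)) {
    run_stage("xspecies", {
      human_genes <- paste0("HS_", toupper(x$genes$gene))
      omap <- generate_ortholog_map(x$genes$gene, human_genes,
                                    seed = derive_seed(cfg$seed, "xspecies"))
      mapped <- map_orthologs(c(conv$common_up, conv$common_down), omap,
                              min_score = cfg$xspecies$min_score)
      universe <- map_orthologs(x$genes$gene, omap,
                                min_score = cfg$xspecies$min_score)$mapped
      human_deg <- map_orthologs(sim$truth$shared_up, omap,
                                 min_score = cfg$xspecies$min_score)$mapped
      ov <- overlap_stats(intersect(mapped$mapped, universe),
                          intersect(human_deg, universe), unique(universe))
      emit(ov, "xspecies_overlap.tsv")
    })
  }

  if ("annotate" %in% cfg$stages) {
    run_stage("annotate", {
      panel <- generate_bulk_references(x, noise_sd = cfg$annotate$noise_sd,
                                        seed = derive_seed(cfg$seed, "annotate"))
      emit(annotate_clusters(x, panel, threshold = cfg$annotate$threshold,
                             seed = derive_seed(cfg$seed, "annotate")),
           "cluster_labels.tsv")
    })
  }

  if ("saturate" %in% cfg$stages) {
    run_stage("saturate", {
      labels <- paste(x$cells$cluster)
      max_n <- cfg$saturate$max_n %||% length(labels)
      curve <- subsample_curve(labels, max_n = max_n, step = cfg$saturate$step,
                               reps = cfg$saturate$reps,
                               threshold = cfg$saturate$threshold,
                               seed = derive_seed(cfg$seed, "saturate"))
      emit(curve, "saturation_curve.tsv")
      fit <- fit_michaelis_menten(curve)
      emit(tidy(fit), "saturation_fit.tsv")
    })
  }

  if ("pheno" %in% cfg$stages) {
    run_stage("pheno", {
      tr <- generate_traces(n_rois = 8, n_frames = 200,
                            spike_times = c(60, 120, 180), spike_amp = 5,
                            noise_sd = 0.05,
                            seed = derive_seed(cfg$seed, "pheno"))
      dff <- dff_trace(tr, "min_mean5")
      emit(activity_metrics(dff), "trace_metrics.tsv")
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vulnscan")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg[setdiff(names(cfg), "out_dir")],
    files = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = basename(p), md5 = digest::digest(file = p, algo = "md5"))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
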