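# End-to-end orchestration: read -> CCF -> cluster -> copy-number events ->
# tree -> timing -> write.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' All thresholds are validated against their documented ranges.
#'
#' @param min_depth Minimum per-sample read depth for a variant (>= 0).
#' @param ccf_cap Raw CCF above which a variant is flagged (>= 1).
#' @param sweeps,burn_in Gibbs sweeps and burn-in for [dp_cluster()].
#' @param grid_step CCF grid resolution in (0, 0.5].
#' @param min_cluster_size Minimum cluster size (`NULL` = automatic).
#' @param presence_threshold CCF center above which a clone is present, in
#'   (0, 1).
#' @param mrca_threshold Minimum per-sample center for the MRCA, in (0, 1].
#' @param epsilon Sum-rule tolerance, in \[0, 1\].
#' @param amp_factor,focal_max_len Focal-amplification rule (multiple of
#'   ploidy; maximum span in bp).
#' @param arm_gain_margin,arm_frac Arm-level event rule.
#' @param seed Integer seed recorded in all outputs.
#' @return A named list of class `clone_config`.
#' @export
clone_config <- function(min_depth = 10, ccf_cap = 1.2, sweeps = 2000,
                         burn_in = 500, grid_step = 0.01,
                         min_cluster_size = NULL, presence_threshold = 0.1,
                         mrca_threshold = 0.9, epsilon = 0.15,
                         amp_factor = 2, focal_max_len = 10e6,
                         arm_gain_margin = 0.6, arm_frac = 0.9, seed = 1) {
  cfg <- list(min_depth = min_depth, ccf_cap = ccf_cap, sweeps = sweeps,
              burn_in = burn_in, grid_step = grid_step,
              min_cluster_size = min_cluster_size,
              presence_threshold = presence_threshold,
              mrca_threshold = mrca_threshold, epsilon = epsilon,
              amp_factor = amp_factor, focal_max_len = focal_max_len,
              arm_gain_margin = arm_gain_margin, arm_frac = arm_frac,
              seed = as.integer(seed))
  stopifnot(cfg$min_depth >= 0, cfg$ccf_cap >= 1,
            cfg$sweeps > cfg$burn_in, cfg$burn_in >= 0,
            cfg$grid_step > 0, cfg$grid_step <= 0.5,
            cfg$presence_threshold > 0, cfg$presence_threshold < 1,
            cfg$mrca_threshold > 0, cfg$mrca_threshold <= 1,
            cfg$epsilon >= 0, cfg$epsilon <= 1,
            cfg$amp_factor > 0, cfg$focal_max_len > 0,
            cfg$arm_gain_margin > 0, cfg$arm_frac > 0, cfg$arm_frac <= 1)
  structure(cfg, class = "clone_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file with [clone_config()] keys.
#' @return A `clone_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(clone_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(clone_config, vals)
}

#' Run the full clonal-evolution pipeline
#'
#' Reads the inputs (or accepts already-parsed tibbles), builds the CCF
#' matrix, clusters SNVs, calls per-sample ploidy/WGD and gene/arm
#' copy-number events, compares events across samples, reconstructs the
#' clone tree with CNA precedence, times events across dated samples, and
#' writes all result files to `out_dir`.
#'
#' @param vcf Path to the multi-sample VCF, or a variant tibble from
#'   [read_vcf()].
#' @param segments Path to the segment TSV, or a segment tibble.
#' @param panel Path to the panel TSV, or a panel tibble.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @param config A [clone_config()].
#' @param gene_table,arm_table Region tables (defaults shipped with the
#'   package).
#' @param normal_sample_id Name of the matched normal in the VCF.
#' @return An object of class `clone_run`: list with `ccf`, `fit`
#'   (`dp_cluster`), `clusters` (summary table), `ploidy`, `events`,
#'   `event_sharing`, `tree` (`clone_tree`), `timed`, `config`, `paths`.
#' @examples
#' sim <- simulate_case(sim_preset("null_single_clone"), out_dir = tempfile())
#' run <- run_all(sim$paths[["vcf"]], sim$paths[["segments"]],
#'                sim$paths[["panel"]],
#'                config = clone_config(sweeps = 200, burn_in = 50))
#' run$ploidy
#' @export
run_all <- function(vcf, segments, panel, out_dir = NULL,
                    config = clone_config(),
                    gene_table = default_gene_table(),
                    arm_table = default_arm_table(),
                    normal_sample_id = "NORMAL") {
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.character(segments)) segments <- read_segments(segments)
  if (is.character(vcf)) {
    vcf <- read_vcf(vcf, tumor_sample_ids = panel$sample_id,
                    normal_sample_id = normal_sample_id)
  }
  if (nrow(vcf) == 0) abort("no usable SNVs")
  seg_samples <- unique(segments$sample_id)
  if (!all(panel$sample_id %in% seg_samples)) {
    abort("panel samples missing from the segment table")
  }

  log_msg("stage ccf: %d variants, %d samples",
          dplyr::n_distinct(vcf$variant_id), nrow(panel))
  ccf <- build_ccf_matrix(vcf, segments, panel,
                          min_depth = config$min_depth,
                          ccf_cap = config$ccf_cap)

  log_msg("stage cluster: %d SNVs", dplyr::n_distinct(ccf$variant_id))
  fit <- dp_cluster(ccf, sweeps = config$sweeps, burn_in = config$burn_in,
                    grid_step = config$grid_step,
                    min_size = config$min_cluster_size, seed = config$seed)
  clusters <- summarize_clusters(fit, ccf,
                                 presence_threshold = config$presence_threshold)

  log_msg("stage cnv")
  ploidy <- ploidy_by_sample(segments)
  events <- call_events_by_sample(segments, gene_table, arm_table, panel,
                                  amp_factor = config$amp_factor,
                                  focal_max_len = config$focal_max_len,
                                  arm_gain_margin = config$arm_gain_margin,
                                  arm_frac = config$arm_frac)
  sharing <- if (nrow(panel) >= 2) {
    compare_events_across_samples(events, panel$sample_id)
  } else NULL

  log_msg("stage tree")
  tree <- build_tree(clusters, events = sharing, panel = panel,
                     epsilon = config$epsilon,
                     presence_threshold = config$presence_threshold,
                     mrca_threshold = config$mrca_threshold)

  log_msg("stage timing")
  timed <- NULL
  if (!is.null(sharing) && nrow(sharing) > 0) {
    timed <- time_events(
      dplyr::mutate(sharing,
                    target = paste(.data$target, .data$kind, sep = ":")),
      panel)
  }
  cl_timed <- time_events(
    dplyr::mutate(clusters, target = paste0("cluster_", .data$cluster)),
    panel)
  timed <- dplyr::bind_rows(timed, cl_timed)

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_results(ccf, fit, tree, events, out_dir, timed = timed)
    run_log <- file.path(out_dir, "run.log")
    writeLines(c(sprintf("seed: %d", config$seed),
                 paste0("config: ", jsonlite::toJSON(unclass(config),
                                                     auto_unbox = TRUE,
                                                     null = "null"))),
               run_log)
  }

  structure(list(ccf = ccf, fit = fit, clusters = clusters, ploidy = ploidy,
                 events = events, event_sharing = sharing, tree = tree,
                 timed = timed, panel = panel, config = config,
                 paths = paths),
            class = "clone_run")
}

#' @export
print.clone_run <- function(x, ...) {
  cat(sprintf("clonetrace run: %d SNVs in %d clusters across %d samples\n",
              dplyr::n_distinct(x$ccf$variant_id), nrow(x$fit$centers),
              nrow(x$panel)))
  cat("\nPloidy / WGD:\n")
  print(as.data.frame(x$ploidy), row.names = FALSE)
  cat(sprintf("\nMRCA: %s\n", x$tree$root))
  print(x$tree)
  if (!is.null(x$timed)) {
    timed <- x$timed[x$timed$status == "timed", ]
    if (nrow(timed) > 0) {
      cat("\nTimed events:\n")
      print(as.data.frame(timed), row.names = FALSE)
    }
  }
  invisible(x)
}
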