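#' Configuration for an end-to-end phenotyping run
#'
#' Defaults reproduce the reference analysis settings: 80% subsampling with
#' 1000 repetitions, k swept from 2 to 9, PAC interval (0.1, 0.9), outlier
#' rule mean - 2 SD. All parameters are echoed into the run manifest.
#'
#' @param table_path,schema_path,outcomes_path input files (see
#'   [read_feature_table()] / [read_outcomes()]); alternatively supply
#'   `sim_spec`.
#' @param sim_spec a [cohort_spec()] to simulate the cohort instead of
#'   reading files.
#' @param k_min,k_max cluster-count sweep range.
#' @param n_reps,subsample_fraction consensus settings.
#' @param pac_interval length-2 PAC interval.
#' @param outlier_sd outlier threshold in SDs below the cluster mean.
#' @param assoc_threshold,ari_threshold feature-reduction thresholds.
#' @param reduce run the feature-reduction stage (default TRUE).
#' @param final_method consensus final-assignment method.
#' @param seed master seed (mandatory).
#' @param out_dir run directory to create.
#' @return object of class `run_config`.
#' @export
run_config <- function(table_path = NULL, schema_path = NULL,
                       outcomes_path = NULL, sim_spec = NULL,
                       k_min = 2L, k_max = 9L, n_reps = 1000L,
                       subsample_fraction = 0.8,
                       pac_interval = c(0.1, 0.9), outlier_sd = 2,
                       assoc_threshold = 0.1, ari_threshold = 0.9,
                       reduce = TRUE, final_method = "pam",
                       seed, out_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(out_dir)) stop("out_dir is mandatory")
  if (is.null(sim_spec) && (is.null(table_path) || is.null(schema_path)))
    stop("supply either input paths or a simulation spec")
  structure(list(table_path = table_path, schema_path = schema_path,
                 outcomes_path = outcomes_path, sim_spec = sim_spec,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_reps = as.integer(n_reps),
                 subsample_fraction = subsample_fraction,
                 pac_interval = pac_interval, outlier_sd = outlier_sd,
                 assoc_threshold = assoc_threshold,
                 ari_threshold = ari_threshold,
                 reduce = isTRUE(reduce), final_method = final_method,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_manifest <- function(config) {
  m <- unclass(config)
  m$sim_spec <- if (is.null(config$sim_spec)) NULL else {
    s <- unclass(config$sim_spec)
    s$binary_prevalence <- as.data.frame(s$binary_prevalence)
    s$continuous_means <- as.data.frame(s$continuous_means)
    s$continuous_sds <- as.data.frame(s$continuous_sds)
    s$categorical_probs <- lapply(s$categorical_probs, as.data.frame)
    s$disposition_probs <- as.data.frame(s$disposition_probs)
    s
  }
  m$package_version <- as.character(utils::packageVersion("phenoclust"))
  m
}

#' Run the full phenotyping pipeline into a run directory
#'
#' Orchestrates simulate/load, transform, Gower, consensus sweep, PAC-based
#' selection of k, validity reporting, optional feature reduction, and all
#' plots. Every number in the human-readable outputs is traceable to a
#' machine-readable artifact in the directory; the manifest plus the seed
#' reproduce the run byte-for-byte (matrices, labels, reports). On failure
#' a `FAILED` marker names the stage; warnings (no structure, boundary
#' minimum, sparse contingency cells) are first-class entries in
#' `warnings.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory results (`sweep`,
#'   `profile`, `run`, `validity`, `reduction`, `cohort`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- list()
  note <- function(stage, msg)
    warnings_log[[length(warnings_log) + 1L]] <<-
      list(stage = stage, message = msg)
  stage <- "setup"
  on.exit({
    if (!is.null(stage))
      writeLines(paste("failed at stage:", stage),
                 file.path(config$out_dir, "FAILED"))
  })

  jsonlite::write_json(config_manifest(config),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  stage <- "input"
  true_labels <- NULL
  if (!is.null(config$sim_spec)) {
    cohort <- generate_cohort(config$sim_spec)
    tab <- cohort$table
    outcomes <- cohort$outcomes
    true_labels <- cohort$true_labels
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  } else {
    cohort <- NULL
    tab <- read_feature_table(config$table_path, config$schema_path)
    outcomes <- if (!is.null(config$outcomes_path))
      read_outcomes(config$outcomes_path) else NULL
    if (!is.null(outcomes)) check_alignment(tab, outcomes)
  }

  stage <- "transform"
  tab_t <- apply_transforms(tab, strict = FALSE)

  stage <- "gower"
  D <- gower_matrix(tab_t)

  stage <- "consensus_sweep"
  sweep <- consensus_sweep(D, k_min = config$k_min, k_max = config$k_max,
                           n_reps = config$n_reps,
                           fraction = config$subsample_fraction,
                           seed = config$seed,
                           final_method = config$final_method)

  stage <- "model_selection"
  profile <- withCallingHandlers(
    select_k(sweep, lower = config$pac_interval[1L],
             upper = config$pac_interval[2L]),
    warning = function(w) {
      note("model_selection", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (profile$boundary)
    note("model_selection",
         paste0("PAC minimum sits at the boundary of the k range (k = ",
                profile$selected_k, ")"))
  da <- delta_area(sweep)
  jsonlite::write_json(list(profile = profile$profile,
                            selected_k = profile$selected_k,
                            interval = as.list(profile$interval),
                            no_structure = profile$no_structure,
                            boundary = profile$boundary,
                            delta_area = da),
                       file.path(config$out_dir, "pac_profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stage <- "final_labels"
  run <- sweep$runs[[paste0("k", profile$selected_k)]]
  write_dissimilarity(run$consensus,
                      file.path(config$out_dir, "consensus_selected_k.tsv"))
  utils::write.csv(data.frame(id = tab$patient_ids,
                              cluster = run$final_labels),
                   file.path(config$out_dir, "final_labels.csv"),
                   row.names = FALSE)

  stage <- "validity"
  validity <- NULL
  if (!is.null(outcomes)) {
    validity <- validity_report(run, tab, outcomes, n_sd = config$outlier_sd)
    for (lv in names(validity$outcomes))
      for (oc in c("mortality", "disposition"))
        if (validity$outcomes[[lv]][[oc]]$sparse)
          note("validity", paste("sparse contingency cells in", lv, oc,
                                 "table (expected < 1)"))
    write_validity_report(validity,
                          file.path(config$out_dir, "validity_report.json"))
    utils::write.csv(data.frame(id = tab$patient_ids,
                                cluster = validity$purified_labels),
                     file.path(config$out_dir, "purified_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(validity$phenotype_summary,
                     file.path(config$out_dir, "phenotype_summary.csv"),
                     row.names = FALSE)
  }

  stage <- "reduction"
  reduction <- NULL
  if (config$reduce) {
    reduction <- reduce_features(tab_t, k = profile$selected_k,
                                 assoc_threshold = config$assoc_threshold,
                                 ari_threshold = config$ari_threshold,
                                 n_reps = config$n_reps,
                                 fraction = config$subsample_fraction,
                                 seed = config$seed,
                                 final_method = config$final_method)
    write_reduction_trace(reduction,
                          file.path(config$out_dir, "reduction_trace.json"))
  }

  stage <- "plots"
  plot_png <- function(name, expr) {
    grDevices::png(file.path(config$out_dir, name), width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
  }
  plot_png("consensus_heatmap.png", plot_consensus_heatmap(run))
  plot_png("consensus_cdf.png", plot_consensus_cdf(sweep))
  plot_png("pac_curve.png", plot_pac(profile))
  plot_png("delta_area.png", plot_delta_area(da))
  if (!is.null(validity))
    plot_png("item_consensus.png", plot_item_consensus(validity$item_consensus))

  stage <- "finalize"
  jsonlite::write_json(warnings_log, file.path(config$out_dir, "warnings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines("ok", file.path(config$out_dir, "DONE"))
  stage <- NULL

  invisible(list(sweep = sweep, profile = profile, run = run,
                 validity = validity, reduction = reduction,
                 cohort = cohort, dissimilarity = D,
                 warnings = warnings_log))
}
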