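#' End-to-end orchestration
#'
#' `run_discovery()` executes the discovery phase (pathology screen ->
#' seeded network -> soft power -> topological overlap -> module detection
#' -> seed filtering -> prioritisation against the three assessment sets);
#' `run_biomarker()` executes the biomarker phase (module expansion ->
#' blood evaluation -> CSF evaluation). Both return their stage artifacts
#' together with a manifest (parameter snapshot, per-artifact content
#' hashes, versions, timestamp) so identical inputs reproduce identical
#' checksums.
#'
#' @name pipeline
NULL

#' Default discovery/biomarker parameters
#'
#' All thresholds surfaced with the workflow's published defaults: 0.01
#' pathology screen, 0.05 assessment screens and enrichment, 5e-8 GWAS,
#' top 1 percent seeding, 2y/4y progression bounds, 0.25 staging centile,
#' 15 principal components.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    screen_alpha = 0.01, set_alpha = 0.05, gwas_threshold = 5e-8,
    seed_fraction = 0.01, powers = 1:20, r2_target = 0.8,
    min_module_size = 30, cut_height_quantile = 0.9,
    enrich_alpha = 0.05, n_pcs = 15, centile = 0.25,
    min_edges = 2, max_added = 12, panel_size = 3
  )
  modifyList(defaults, list(...))
}

manifest_entry <- function(stage, object) {
  tibble(stage = stage, checksum = rlang::hash(object))
}

build_manifest <- function(entries, params) {
  list(created = format(Sys.time(), tz = "UTC"),
       r_version = as.character(getRversion()),
       pathmod_version = as.character(utils::packageVersion("pathmod")),
       params = params,
       artifacts = entries)
}

#' Run the discovery phase
#'
#' @param study A `pm_synthetic_study`, or a CNS [expression_study()] (in
#'   which case `blood_study` and `gwas_table` must be supplied).
#' @param params See [pipeline_params()].
#' @param blood_study,gwas_table Inputs for the lymphoblastoid and genetic
#'   assessment sets when `study` is a plain expression study.
#' @param out_dir Optional directory for stage artifacts (TSV/JSON/GMT).
#' @return A `pm_discovery` list: `screen`, `network`, `power_scan`,
#'   `partition`, `module_sets`, `assessment_sets`, `priority`, `manifest`.
#' @export
run_discovery <- function(study, params = pipeline_params(),
                          blood_study = NULL, gwas_table = NULL,
                          out_dir = NULL) {
  if (inherits(study, "pm_synthetic_study")) {
    cns <- study$cns
    blood_study <- blood_study %||% study$blood
    gwas_table <- gwas_table %||% study$truth$gwas_table
  } else {
    cns <- study
    if (is.null(blood_study) || is.null(gwas_table)) {
      abort("configuration error: blood_study and gwas_table are required",
            class = "pathmod_config_error")
    }
  }
  screen <- screen_pathology_correlates(cns, alpha = params$screen_alpha)
  seeds <- screen$transcript_id[screen$selected]
  if (length(seeds) == 0) {
    abort("stage 'screen' failed: no pathology-correlated transcripts at alpha",
          class = "pathmod_stage_error")
  }
  network <- seed_neighborhoods(cns, seeds, fraction = params$seed_fraction)
  power_scan <- suppressWarnings(
    select_soft_power(network, powers = params$powers,
                      r2_target = params$r2_target))
  tom <- topological_overlap(network, attr(power_scan, "chosen_power"))
  partition <- detect_modules(tom, min_module_size = params$min_module_size,
                              cut_height_quantile = params$cut_height_quantile)
  partition <- filter_seeded_modules(partition, seeds)
  msets <- module_gene_sets(partition, cns)
  universe <- study_universe(cns)
  assessment <- list(
    motor_neuron = derive_duration_set(cns, alpha = params$set_alpha),
    lymphoblastoid = derive_progression_set(blood_study,
                                            alpha = params$set_alpha),
    genetic = load_gwas_set(gwas_table, threshold = params$gwas_threshold)
  )
  priority <- if (length(msets)) {
    prioritize_modules(msets, assessment, universe,
                       alpha = params$enrich_alpha)
  } else {
    warn("no seeded modules survive; empty priority report")
    NULL
  }
  entries <- bind_rows(
    manifest_entry("screen", screen),
    manifest_entry("network", network$node_ids),
    manifest_entry("power_scan", as.data.frame(power_scan)),
    manifest_entry("partition", as.data.frame(partition)),
    manifest_entry("priority", priority$records)
  )
  res <- structure(
    list(screen = screen, network = network, power_scan = power_scan,
         partition = partition, module_sets = msets,
         assessment_sets = assessment, priority = priority,
         universe = universe,
         manifest = build_manifest(entries, params)),
    class = "pm_discovery")
  if (!is.null(out_dir)) write_discovery(res, out_dir)
  res
}

write_discovery <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$screen, file.path(out_dir, "screen.tsv"))
  readr::write_tsv(as_tibble(res$power_scan),
                   file.path(out_dir, "power_scan.tsv"))
  readr::write_tsv(as_tibble(res$partition),
                   file.path(out_dir, "partition.tsv"))
  write_gmt(c(lapply(res$assessment_sets, as.character),
              lapply(res$module_sets, as.character)),
            file.path(out_dir, "gene_sets.gmt"))
  if (!is.null(res$priority)) {
    write_priority_report(res$priority, file.path(out_dir, "priority.json"))
    readr::write_tsv(res$priority$records,
                     file.path(out_dir, "priority_records.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the biomarker phase
#'
#' Expands the candidate module with interaction partners (when an edge
#' table is given), evaluates the expanded module in blood (survival model
#' on module principal components; per-gene logistic screen; leave-one-out
#' cross-validated panel) and in CSF (group comparison, staging, stage
#' summaries and stage-stratified duration association).
#'
#' @param blood_study An [expression_study()] with progression labels and
#'   durations.
#' @param module Candidate module gene set (e.g. the top triple-enriched
#'   module's genes); must be non-empty.
#' @param edges Optional interaction edge table.
#' @param csf_table CSF table (defaults to the packaged one).
#' @param params See [pipeline_params()].
#' @param assessment_sets Optional named list of assessment sets for the
#'   expansion before/after comparison.
#' @param universe Gene universe for that comparison.
#' @return A `pm_biomarker` list with `expansion`, `improvement`,
#'   `ph_fit`, `gene_screen`, `panel_fit`, `csf` and `manifest`.
#' @export
run_biomarker <- function(blood_study, module, edges = NULL,
                          csf_table = load_csf_table(),
                          params = pipeline_params(),
                          assessment_sets = NULL, universe = NULL) {
  if (length(module) == 0) {
    abort("stage 'expansion' failed: empty module",
          class = "pathmod_stage_error")
  }
  expansion <- NULL
  improvement <- NULL
  working <- gene_set(module, set_name(module, "module"))
  if (!is.null(edges)) {
    expansion <- expand_module(working, edges, min_edges = params$min_edges,
                               max_added = params$max_added)
    working <- expansion$members
    if (!is.null(assessment_sets) && !is.null(universe)) {
      improvement <- enrichment_improvement(expansion$original, expansion,
                                            assessment_sets, universe)
    }
  }
  measured <- intersect(as.character(working),
                        unique(blood_study$gene_map$gene))
  features <- suppressWarnings(
    module_pc_features(blood_study, measured, k = params$n_pcs))
  ph_fit <- fit_ph_model(blood_study$samples[
    match(rownames(features), blood_study$samples$sample_id), ], features)
  gene_screen <- per_gene_logistic_screen(blood_study, measured,
                                          alpha = params$set_alpha)
  panel <- gene_screen |>
    filter(.data$selected) |>
    arrange(.data$p_value) |>
    head(params$panel_size) |>
    pull("gene")
  panel_fit <- if (length(panel) >= 1) loocv_panel_accuracy(blood_study, panel)
  stages <- assign_stage(csf_table, centile = params$centile)
  csf <- list(
    comparison = compare_strem2_groups(csf_table),
    stages = stages,
    stage_summary = stage_summary(csf_table, stages),
    stage_association = stage_stratified_association(csf_table, stages)
  )
  entries <- bind_rows(
    manifest_entry("expansion", expansion$support),
    manifest_entry("ph_fit", ph_fit$lrt),
    manifest_entry("gene_screen", gene_screen),
    manifest_entry("panel", panel),
    manifest_entry("csf_comparison", csf$comparison),
    manifest_entry("csf_stage_summary", as.data.frame(csf$stage_summary))
  )
  structure(list(module = working, expansion = expansion,
                 improvement = improvement, ph_fit = ph_fit,
                 gene_screen = gene_screen, panel = panel,
                 panel_fit = panel_fit, csf = csf,
                 manifest = build_manifest(entries, params)),
            class = "pm_biomarker")
}
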