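#' Module prioritisation by assessment-set enrichment
#'
#' Every seeded module is scored against three independently curated
#' assessment gene sets (duration-correlated motor-neuron genes,
#' rapid-vs-slow lymphoblastoid genes, GWAS susceptibility genes) with a
#' one-sided Fisher test on the measured-gene universe. Modules enriched
#' with all three sets at unadjusted p < alpha are "triple enriched";
#' Benjamini-Hochberg adjusted values are reported alongside but selection
#' follows the raw threshold.
#'
#' @name module-prioritization
NULL

#' Enrichment of one module against one gene set
#'
#' Module and assessment set are intersected with the universe before
#' counting; the p-value is the one-sided hypergeometric tail
#' `P(X >= overlap)`.
#'
#' @param module_genes,assessment Character vectors (or [gene_set()]s) of
#'   gene identifiers.
#' @param universe Background gene universe (typically
#'   [study_universe()]).
#' @param module_label,set_label Labels for the output record; default to
#'   the sets' `name` attributes.
#' @return One-row tibble: `module`, `set_name`, `overlap`,
#'   `module_in_universe`, `set_in_universe`, `universe_size`, `p_value`,
#'   `adjusted_p` (NA until adjusted across a batch).
#' @export
enrich_module <- function(module_genes, assessment, universe,
                          module_label = set_name(module_genes, "module"),
                          set_label = set_name(assessment, "set")) {
  universe <- unique(as.character(universe))
  m <- intersect(unique(as.character(module_genes)), universe)
  s <- intersect(unique(as.character(assessment)), universe)
  if (length(m) == 0 || length(s) == 0) {
    warn(sprintf("empty intersection with universe for %s vs %s",
                 module_label, set_label))
    return(tibble(module = module_label, set_name = set_label,
                  overlap = 0L, module_in_universe = length(m),
                  set_in_universe = length(s),
                  universe_size = length(universe),
                  p_value = 1, adjusted_p = NA_real_))
  }
  ov <- length(intersect(m, s))
  ft <- fisher_enrichment(
    overlap = ov,
    set_only = length(s) - ov,
    module_only = length(m) - ov,
    neither = length(universe) - length(s) - length(m) + ov
  )
  tibble(module = module_label, set_name = set_label, overlap = ov,
         module_in_universe = length(m), set_in_universe = length(s),
         universe_size = length(universe), p_value = ft$p_value,
         adjusted_p = NA_real_)
}

#' Score seeded modules against the three assessment sets
#'
#' @param module_sets Named list of module gene sets (see
#'   [module_gene_sets()]).
#' @param assessment_sets Named list of exactly three assessment gene sets.
#' @param universe Background gene universe.
#' @param alpha Unadjusted selection threshold (default 0.05).
#' @return A `pm_priority` report: `records` (one row per module x set,
#'   with BH adjustment within each set across modules),
#'   `triple_enriched` (module labels with all three raw p < alpha, ranked
#'   by their best per-set p), `alpha`, and an empty `control` slot filled
#'   by [negative_control_compare()].
#' @export
prioritize_modules <- function(module_sets, assessment_sets, universe,
                               alpha = 0.05) {
  stopifnot(length(assessment_sets) == 3, !is.null(names(module_sets)))
  records <- map_df(names(module_sets), function(m) {
    map_df(seq_along(assessment_sets), function(i) {
      enrich_module(module_sets[[m]], assessment_sets[[i]], universe,
                    module_label = m,
                    set_label = set_name(assessment_sets[[i]],
                                         names(assessment_sets)[i]))
    })
  })
  records <- records |>
    group_by(.data$set_name) |>
    mutate(adjusted_p = bh_adjust(.data$p_value)) |>
    ungroup()
  hits <- records |>
    group_by(.data$module) |>
    # alpha = 1 means "no filtering": include the p = 1 boundary
    summarise(all_three = all(.data$p_value < alpha | alpha >= 1),
              best_p = min(.data$p_value), .groups = "drop") |>
    filter(.data$all_three) |>
    arrange(.data$best_p)
  structure(list(records = records, triple_enriched = hits$module,
                 alpha = alpha, control = NULL),
            class = "pm_priority")
}

#' @export
print.pm_priority <- function(x, ...) {
  cat(sprintf("<pm_priority> %d modules x %d sets; %d triple-enriched at raw p < %g\n",
              length(unique(x$records$module)),
              length(unique(x$records$set_name)),
              length(x$triple_enriched), x$alpha))
  if (length(x$triple_enriched))
    cat("  triple-enriched:", paste(x$triple_enriched, collapse = ", "), "\n")
  invisible(x)
}

#' Score a negative-control module against the assessment sets
#'
#' An artificial module of cell-identity genes (expressed specifically in
#' non-diseased motor neurons) should show no disease-progression
#' enrichment; its records are flagged for side-by-side reporting.
#'
#' @param control_set Control module gene set (non-empty).
#' @inheritParams prioritize_modules
#' @return Tibble of three enrichment records with a `control` column.
#' @export
negative_control_compare <- function(control_set, assessment_sets, universe) {
  stopifnot(length(control_set) > 0, length(assessment_sets) == 3)
  map_df(seq_along(assessment_sets), function(i) {
    enrich_module(control_set, assessment_sets[[i]], universe,
                  module_label = set_name(control_set, "control"),
                  set_label = set_name(assessment_sets[[i]],
                                       names(assessment_sets)[i]))
  }) |>
    mutate(control = TRUE)
}

#' Attach a control comparison to a priority report
#'
#' @param report A `pm_priority`.
#' @param control Output of [negative_control_compare()].
#' @return The report with its `control` slot filled.
#' @export
with_control <- function(report, control) {
  stopifnot(inherits(report, "pm_priority"))
  report$control <- control
  report
}

#' Functional enrichment of a module over a gene-set collection
#'
#' Local stand-in for web-service over-representation analysis: a one-sided
#' Fisher test per collection member with BH adjustment across the
#' collection, sorted by adjusted then raw p. Used both for functional
#' (e.g. GO-style) collections and for cell-type expression collections.
#'
#' @param module_genes Module gene set.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene universe.
#' @return Tibble of enrichment records sorted by evidence.
#' @export
functional_enrichment <- function(module_genes, collections, universe) {
  stopifnot(length(collections) > 0, !is.null(names(collections)))
  map_df(names(collections), function(nm) {
    enrich_module(module_genes, collections[[nm]], universe,
                  set_label = nm)
  }) |>
    mutate(adjusted_p = bh_adjust(.data$p_value)) |>
    arrange(.data$adjusted_p, .data$p_value)
}

#' Serialise / restore a priority report
#'
#' JSON round-trip is lossless for the records, the triple-enriched list,
#' alpha and the control comparison.
#'
#' @param report A `pm_priority`.
#' @param path JSON file path.
#' @export
write_priority_report <- function(report, path) {
  stopifnot(inherits(report, "pm_priority"))
  jsonlite::write_json(
    list(records = report$records, triple_enriched = report$triple_enriched,
         alpha = report$alpha, control = report$control),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_priority_report
#' @export
read_priority_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # an all-NA column (e.g. adjusted_p on a control comparison) serialises to
  # nulls and vanishes on reading; restore it
  restore <- function(df) {
    if (is.null(df)) return(NULL)
    df <- as_tibble(df)
    if (nrow(df) && !"adjusted_p" %in% names(df)) df$adjusted_p <- NA_real_
    df
  }
  structure(list(records = restore(x$records),
                 triple_enriched = as.character(x$triple_enriched %||% character()),
                 alpha = x$alpha,
                 control = restore(x$control)),
            class = "pm_priority")
}
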