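#' Module expansion with interaction partners
#'
#' To make a CNS-derived module measurable in peripheral tissue, globally
#' co-expressed genes and protein-protein interaction partners are appended
#' from a weighted edge table (the offline stand-in for an interaction
#' prediction server). Candidates need support from at least `min_edges`
#' edges into the module and are ranked by summed edge weight.
#'
#' @name module-expansion
NULL

#' Read and validate an interaction edge table
#'
#' Expects a 4-column TSV: `gene_a`, `gene_b`, `edge_type`
#' (`coexpression` or `ppi`), `weight` in (0, 1]. Self edges are dropped,
#' the undirected canonical ordering `gene_a < gene_b` is enforced and
#' duplicate rows removed.
#'
#' @param path TSV file path.
#' @return A validated edge tibble.
#' @export
read_edge_table <- function(path) {
  validate_edge_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @param edges Data frame with the four edge columns.
#' @rdname read_edge_table
#' @export
validate_edge_table <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "edge_type", "weight") %in% names(edges)))
  if (!all(edges$edge_type %in% c("coexpression", "ppi"))) {
    abort("edge_type must be 'coexpression' or 'ppi'",
          class = "pathmod_bad_edges")
  }
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    abort("edge weights must lie in (0, 1]", class = "pathmod_bad_edges")
  }
  edges <- filter(edges, .data$gene_a != .data$gene_b)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  dplyr::distinct(arrange(edges, .data$gene_a, .data$gene_b))
}

#' Expand a module with supported interaction partners
#'
#' Non-member genes with at least `min_edges` edges into the module are
#' ranked by summed edge weight (ties broken by edge count, then by gene
#' identifier) and the top `max_added` are appended. The defaults mirror an
#' expansion on the order of a dozen genes while requiring more than
#' single-edge support.
#'
#' @param module Module gene set.
#' @param edges Edge tibble (see [read_edge_table()]).
#' @param min_edges Minimum edges into the module per candidate (default 2).
#' @param max_added Maximum genes appended (default 12).
#' @return A `pm_expanded_module`: `original`, `added`, `members`
#'   (union), and `support` (per added gene: edge count, summed weight).
#' @export
expand_module <- function(module, edges, min_edges = 2, max_added = 12) {
  module_members <- unique(as.character(module))
  edges <- validate_edge_table(edges)
  if (nrow(edges) == 0) {
    warn("empty edge table; no genes added")
    support <- tibble(gene = character(), n_edges = integer(),
                      total_weight = numeric())
  } else {
    touching <- bind_rows(
      edges |> filter(.data$gene_b %in% module_members) |>
        select(gene = "gene_a", "weight"),
      edges |> filter(.data$gene_a %in% module_members) |>
        select(gene = "gene_b", "weight")
    ) |>
      filter(!(.data$gene %in% module_members))
    support <- touching |>
      group_by(.data$gene) |>
      summarise(n_edges = n(), total_weight = sum(.data$weight),
                .groups = "drop") |>
      filter(.data$n_edges >= min_edges) |>
      arrange(desc(.data$total_weight), desc(.data$n_edges), .data$gene) |>
      head(max_added)
  }
  structure(list(original = gene_set(module_members,
                                     set_name(module, "module")),
                 added = support$gene,
                 members = gene_set(c(module_members, support$gene),
                                    paste0(set_name(module, "module"),
                                           "_expanded")),
                 support = support),
            class = "pm_expanded_module")
}

#' @export
print.pm_expanded_module <- function(x, ...) {
  cat(sprintf("<pm_expanded_module> %d -> %d genes (%d added)\n",
              length(x$original), length(x$members), length(x$added)))
  invisible(x)
}

#' Does expansion improve assessment-set enrichment?
#'
#' Computes the one-sided Fisher enrichment of the original and the
#' expanded module against each assessment set and flags per set whether
#' the expanded p-value is smaller.
#'
#' @param original,expanded Gene sets with `expanded` a superset of
#'   `original` (an `pm_expanded_module` is accepted for `expanded`).
#' @param assessment_sets Named list of assessment gene sets.
#' @param universe Background gene universe.
#' @return Tibble with one row per set: `set_name`, `p_before`, `p_after`,
#'   `overlap_before`, `overlap_after`, `improved`.
#' @export
enrichment_improvement <- function(original, expanded, assessment_sets,
                                   universe) {
  if (inherits(expanded, "pm_expanded_module")) expanded <- expanded$members
  if (!all(as.character(original) %in% as.character(expanded))) {
    abort("expanded module must contain the original module",
          class = "pathmod_bad_expansion")
  }
  map_df(seq_along(assessment_sets), function(i) {
    nm <- names(assessment_sets)[i] %||%
      set_name(assessment_sets[[i]], paste0("set", i))
    before <- enrich_module(original, assessment_sets[[i]], universe,
                            set_label = nm)
    after <- enrich_module(expanded, assessment_sets[[i]], universe,
                           set_label = nm)
    tibble(set_name = nm,
           p_before = before$p_value, p_after = after$p_value,
           overlap_before = before$overlap, overlap_after = after$overlap,
           improved = after$p_value < before$p_value)
  })
}
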