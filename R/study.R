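#' Expression study container
#'
#' Bundles a transcripts-by-samples expression matrix (normalised
#' intensities) with a transcript-to-gene map and per-sample clinical
#' annotations. The clinical table may carry any of: `pathology_count`
#' (p62-positive inclusions per unit area), `duration_years` (symptom onset
#' to death), `onset_age`, `sex`, `genotype` and `progression`
#' (rapid/intermediate/slow).
#'
#' @param expr Numeric matrix, transcripts in rows (rownames are transcript
#'   identifiers), samples in columns (colnames are sample identifiers).
#' @param gene_map Data frame with columns `transcript_id` and `gene`,
#'   covering every row of `expr`. Several transcripts may map to one gene.
#' @param samples Data frame of clinical annotations with a `sample_id`
#'   column matching the columns of `expr`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(expr, gene_map, samples) {
  expr <- as.matrix(expr)
  gene_map <- as_tibble(gene_map)
  samples <- as_tibble(samples)
  stopifnot(
    !is.null(rownames(expr)), !is.null(colnames(expr)),
    all(c("transcript_id", "gene") %in% names(gene_map)),
    "sample_id" %in% names(samples)
  )
  if (!setequal(gene_map$transcript_id, rownames(expr))) {
    abort("gene_map must cover exactly the transcripts in the matrix")
  }
  if (!all(samples$sample_id %in% colnames(expr))) {
    abort("every annotated sample needs a matrix column")
  }
  gene_map <- gene_map[match(rownames(expr), gene_map$transcript_id), ]
  structure(list(expr = expr, gene_map = gene_map, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d transcripts (%d genes) x %d samples\n",
              nrow(x$expr), length(unique(x$gene_map$gene)), ncol(x$expr)))
  cat("clinical fields:", paste(setdiff(names(x$samples), "sample_id"),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Measured-gene universe of a study
#'
#' All distinct genes on the platform after transcript-to-gene collapse;
#' the default enrichment background.
#'
#' @param study An [expression_study()].
#' @return Character vector of gene identifiers.
#' @export
study_universe <- function(study) {
  sort(unique(study$gene_map$gene))
}

#' Collapse transcript expression to gene level
#'
#' Averages the rows of all transcripts mapped to each gene, the convention
#' used when module membership is defined on genes but measurement is
#' per-transcript.
#'
#' @param study An [expression_study()].
#' @param genes Optional character vector restricting the output.
#' @return Genes-by-samples matrix.
#' @export
collapse_to_genes <- function(study, genes = NULL) {
  map <- study$gene_map
  if (!is.null(genes)) {
    map <- filter(map, .data$gene %in% genes)
    if (nrow(map) == 0) {
      abort("no requested genes are measured in the study",
            class = "pathmod_missing_genes")
    }
  }
  sub <- study$expr[map$transcript_id, , drop = FALSE]
  rowsum(sub, group = map$gene) / as.vector(table(map$gene)[sort(unique(map$gene))])
}

#' Write / read a study as plain-text artifacts
#'
#' The on-disk layout is `expression.tsv.gz` (transcripts as rows, header of
#' sample identifiers), `gene_map.csv` and `clinical.csv`.
#'
#' @param study An [expression_study()].
#' @param dir Directory to create/read.
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns an
#'   [expression_study()].
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_tbl <- bind_cols(tibble(transcript_id = rownames(study$expr)),
                        as_tibble(study$expr))
  readr::write_tsv(expr_tbl, file.path(dir, "expression.tsv.gz"))
  readr::write_csv(study$gene_map, file.path(dir, "gene_map.csv"))
  readr::write_csv(study$samples, file.path(dir, "clinical.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  expr_tbl <- readr::read_tsv(file.path(dir, "expression.tsv.gz"),
                              show_col_types = FALSE)
  expr <- as.matrix(expr_tbl[, -1])
  rownames(expr) <- expr_tbl$transcript_id
  expression_study(
    expr,
    readr::read_csv(file.path(dir, "gene_map.csv"), show_col_types = FALSE),
    readr::read_csv(file.path(dir, "clinical.csv"), show_col_types = FALSE)
  )
}
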