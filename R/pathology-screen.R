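#' Transcriptome screens against clinical covariates
#'
#' The discovery phase rests on three unadjusted screens: transcripts whose
#' expression tracks the motor-neuron pathology burden (the network seeds),
#' transcripts tracking disease duration (the motor-neuron assessment set)
#' and transcripts separating rapid from slow progressors in blood (the
#' lymphoblastoid assessment set). No multiplicity correction is applied in
#' any screen; selection is at the stated unadjusted threshold, which
#' reports therefore state prominently.
#'
#' @name pathology-screen
NULL

# Vectorised per-transcript Spearman against one covariate. For cohorts of
# at least 10 samples the t-approximation is applied row-wise in one matrix
# operation; smaller cohorts fall back to the exact kernel per transcript.
spearman_screen <- function(expr, covariate, alpha) {
  keep <- !is.na(covariate)
  expr <- expr[, keep, drop = FALSE]
  covariate <- covariate[keep]
  n <- length(covariate)
  if (n < 3) {
    abort("insufficient data: need at least 3 annotated samples",
          class = "pathmod_insufficient_data")
  }
  if (var(covariate) == 0) {
    abort("degenerate covariate: no variation across samples",
          class = "pathmod_degenerate_input")
  }
  row_var <- apply(expr, 1, var)
  degenerate <- row_var == 0
  ranks <- t(apply(expr, 1, rank))
  rho <- suppressWarnings(as.vector(cor(t(ranks), rank(covariate))))
  rho[degenerate] <- NA_real_
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t_approx"
  } else {
    p <- vapply(seq_len(nrow(expr)), function(i) {
      if (degenerate[i]) return(NA_real_)
      spearman_test(expr[i, ], covariate)$p_value
    }, numeric(1))
    method <- "small_n"
  }
  out <- tibble(
    transcript_id = rownames(expr),
    rho = rho,
    p_value = p,
    n_eff = n,
    degenerate = degenerate,
    # alpha = 1 means "no filtering": include the p = 1 boundary
    selected = !degenerate & !is.na(p) & (p < alpha | alpha >= 1)
  )
  structure(out, class = c("pm_screen", class(out)),
            alpha = alpha, method = method)
}

#' Screen transcripts for correlation with pathology burden
#'
#' Spearman rank correlation between each transcript's expression and the
#' per-sample count of inclusion-bearing motor neurons per unit area.
#' Transcripts with unadjusted p below `alpha` become the seeds of the
#' co-expression network. Constant transcript rows are reported unselected
#' with a `degenerate` flag.
#'
#' @param study An [expression_study()] whose samples carry
#'   `pathology_count`.
#' @param alpha Unadjusted selection threshold (default 0.01).
#' @return A `pm_screen` tibble: `transcript_id`, `rho`, `p_value`, `n_eff`,
#'   `degenerate`, `selected`.
#' @export
screen_pathology_correlates <- function(study, alpha = 0.01) {
  stopifnot(inherits(study, "expression_study"))
  if (!"pathology_count" %in% names(study$samples)) {
    abort("study has no pathology_count annotation",
          class = "pathmod_missing_field")
  }
  counts <- study$samples$pathology_count[
    match(colnames(study$expr), study$samples$sample_id)]
  spearman_screen(study$expr, counts, alpha)
}

screen_to_genes <- function(screen, study, name) {
  sel <- screen$transcript_id[screen$selected]
  genes <- study$gene_map$gene[study$gene_map$transcript_id %in% sel]
  gene_set(genes, name)
}

#' Duration-correlated assessment set
#'
#' Transcripts whose expression Spearman-correlates with disease duration
#' (unadjusted p < `alpha`, two-sided, direction unrestricted), collapsed to
#' genes: the "motor neuron assessment set".
#'
#' @inheritParams screen_pathology_correlates
#' @param alpha Unadjusted threshold (default 0.05).
#' @return A [gene_set()].
#' @export
derive_duration_set <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  durations <- study$samples$duration_years[
    match(colnames(study$expr), study$samples$sample_id)]
  screen <- spearman_screen(study$expr, durations, alpha)
  screen_to_genes(screen, study, "motor_neuron_assessment")
}

# exact-when-possible Mann-Whitney p per transcript row
row_mw_p <- function(expr, idx_a, idx_b) {
  n <- length(idx_a) + length(idx_b)
  vapply(seq_len(nrow(expr)), function(i) {
    a <- expr[i, idx_a]; b <- expr[i, idx_b]
    if (var(c(a, b)) == 0) return(NA_real_)
    exact <- n <= 20 && anyDuplicated(c(a, b)) == 0
    suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
    )
  }, numeric(1))
}

#' Progression-contrast assessment set
#'
#' Transcripts differentially expressed between rapidly (< 2 years) and
#' slowly (> 4 years) progressive patients by Mann-Whitney U-test
#' (unadjusted p < `alpha`), collapsed to genes: the "lymphoblastoid
#' assessment set". Intermediate-duration samples are excluded from the
#' contrast.
#'
#' @inheritParams derive_duration_set
#' @return A [gene_set()].
#' @export
derive_progression_set <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  samp <- study$samples
  labels <- if ("progression" %in% names(samp)) samp$progression
            else classify_progression(samp$duration_years)
  labels <- labels[match(colnames(study$expr), samp$sample_id)]
  idx_a <- which(labels == "rapid")
  idx_b <- which(labels == "slow")
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    abort("group definition error: need >= 2 rapid and >= 2 slow samples",
          class = "pathmod_group_error")
  }
  p <- row_mw_p(study$expr, idx_a, idx_b)
  sel <- tibble(transcript_id = rownames(study$expr), p_value = p,
                selected = !is.na(p) & p < alpha)
  screen_to_genes(sel, study, "lymphoblastoid_assessment")
}

#' Genetic assessment set from a GWAS gene table
#'
#' Keeps genes whose association p-value falls below the genome-wide
#' threshold (default 5e-8, unadjusted), deduplicated. Malformed rows
#' (missing gene, p outside \[0, 1\]) are skipped with a message.
#'
#' @param table Data frame with columns `gene` and `p`.
#' @param threshold Significance threshold (default 5e-8).
#' @return A [gene_set()] labelled `genetic_assessment`.
#' @export
load_gwas_set <- function(table, threshold = 5e-8) {
  table <- as_tibble(table)
  stopifnot(all(c("gene", "p") %in% names(table)))
  bad <- is.na(table$gene) | table$gene == "" | is.na(table$p) |
    table$p < 0 | table$p > 1
  if (any(bad)) {
    inform(sprintf("load_gwas_set: skipped %d malformed rows", sum(bad)))
  }
  ok <- table[!bad, ]
  gene_set(ok$gene[ok$p < threshold], "genetic_assessment")
}

#' Classify progression rate from disease duration
#'
#' Rapid if duration is under 2 years, slow if over 4 years, otherwise
#' intermediate. Boundary durations of exactly 2 or 4 years are
#' intermediate (strict inequalities).
#'
#' @param duration_years Positive durations (vectorised).
#' @return Character vector of `"rapid"`, `"intermediate"`, `"slow"`.
#' @examples
#' classify_progression(c(1.17, 3, 5.25))
#' @export
classify_progression <- function(duration_years) {
  if (any(is.na(duration_years)) || any(duration_years <= 0)) {
    abort("durations must be positive", class = "pathmod_bad_duration")
  }
  ifelse(duration_years < 2, "rapid",
         ifelse(duration_years > 4, "slow", "intermediate"))
}
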