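#' Configuration for synthetic study generation
#'
#' The generator emulates the two study designs the pipeline consumes: a
#' microarray over laser-captured motor neurons from a small post-mortem
#' cohort carrying a pathology-count covariate, and lymphoblastoid
#' expression from a blood-derived cohort labelled by progression rate.
#' Planted modules follow a single-latent-factor model: each module member
#' is `sqrt(w) * factor + sqrt(1 - w) * noise` so the expected within-module
#' pairwise correlation equals `within_module_correlation`.
#'
#' The pathology-linked and progression-linked module may be (and by default
#' are) the same module, mirroring a disease module that is both correlated
#' with neuropathology in the CNS and discriminates rapid from slow
#' progressors in blood. The cell-identity control module is co-expressed
#' but carries no disease signal.
#'
#' @param n_transcripts Number of transcripts (default 2000; the
#'   full-platform scale of 54675 is configurable).
#' @param n_samples_cns,n_samples_blood Cohort sizes.
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector of planted module sizes.
#' @param pathology_linked_module,progression_linked_module,control_identity_module
#'   Indices of the planted modules carrying each role; the control index
#'   must differ from the other two.
#' @param within_module_correlation Expected pairwise correlation of module
#'   members, in (0, 1).
#' @param pathology_effect Slope of the pathology-linked latent factor on
#'   log pathology rate (counts are Poisson with a log link).
#' @param group_effect Mean shift (in units of the per-transcript SD)
#'   between rapid and slow progressors for progression-module members in
#'   blood.
#' @param noise_sd Per-transcript residual standard deviation.
#' @param duration_range_years Range the blood-cohort disease durations are
#'   drawn from; both rapid (< 2 y) and slow (> 4 y) groups are populated.
#' @param seed Integer seed; identical configs yield bit-identical studies.
#' @param pathology_baseline Expected inclusion count per unit area at a
#'   neutral latent factor.
#' @param n_gwas_background Non-module genes planted in the GWAS-like
#'   significant set.
#' @return A `pm_sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2000,
                       n_samples_cns = 12,
                       n_samples_blood = 26,
                       n_modules = 3,
                       module_sizes = c(60, 50, 40),
                       pathology_linked_module = 1,
                       progression_linked_module = 1,
                       control_identity_module = 3,
                       within_module_correlation = 0.7,
                       pathology_effect = 1.0,
                       group_effect = 1.5,
                       noise_sd = 1,
                       duration_range_years = c(0.5, 8),
                       seed = 1,
                       pathology_baseline = 20,
                       n_gwas_background = 40) {
  cfg <- as.list(environment())
  if (length(cfg$module_sizes) != n_modules ||
      sum(cfg$module_sizes) > n_transcripts) {
    abort("configuration error: module sizes incompatible with transcript count",
          class = "pathmod_config_error")
  }
  idx <- c(pathology_linked_module, progression_linked_module,
           control_identity_module)
  if (any(idx < 1) || any(idx > n_modules) ||
      control_identity_module %in% idx[1:2]) {
    abort("configuration error: bad module role indices",
          class = "pathmod_config_error")
  }
  if (within_module_correlation <= 0 || within_module_correlation >= 1 ||
      noise_sd <= 0) {
    abort("configuration error: correlation must be in (0,1), noise_sd > 0",
          class = "pathmod_config_error")
  }
  structure(cfg, class = "pm_sim_config")
}

# transcript/gene id scaffolding; roughly every 10th background transcript
# shares its gene with the previous one so the transcript->gene collapse is
# genuinely many-to-one
sim_gene_map <- function(n_transcripts, planted_idx) {
  transcript_id <- sprintf("T%05d_at", seq_len(n_transcripts))
  gene_idx <- seq_len(n_transcripts)
  background <- setdiff(seq_len(n_transcripts), planted_idx)
  dup <- background[seq_along(background) %% 10 == 0]
  dup <- dup[dup > 1 & !((dup - 1) %in% planted_idx)]
  gene_idx[dup] <- gene_idx[dup - 1]
  tibble(transcript_id = transcript_id,
         gene = sprintf("G%05d", gene_idx))
}

sim_expression <- function(cfg, n_samples, module_rows, factors,
                           shift = NULL) {
  w <- cfg$within_module_correlation
  expr <- matrix(rnorm(cfg$n_transcripts * n_samples),
                 cfg$n_transcripts, n_samples)
  for (m in seq_len(cfg$n_modules)) {
    rows <- module_rows[[m]]
    signal <- matrix(factors[m, ], length(rows), n_samples, byrow = TRUE)
    expr[rows, ] <- sqrt(w) * signal + sqrt(1 - w) * expr[rows, ]
    if (!is.null(shift) && m == cfg$progression_linked_module) {
      expr[rows, ] <- expr[rows, ] +
        matrix(cfg$group_effect * shift, length(rows), n_samples, byrow = TRUE)
    }
  }
  cfg$noise_sd * expr + rnorm(cfg$n_transcripts, mean = 8, sd = 2)
}

#' Generate a synthetic two-cohort study with planted structure
#'
#' Produces a CNS (motor-neuron) study whose pathology-linked module factor
#' drives Poisson pathology counts and (inversely) disease duration, and a
#' blood study whose progression-linked module members are shifted between
#' rapid and slow progressors. Ground truth (module membership, seed
#' transcripts, GWAS-like gene table) travels with the result so recovery is
#' checkable at every stage.
#'
#' @param config A [sim_config()].
#' @return A `pm_synthetic_study` list with elements `cns` and `blood`
#'   (both [expression_study()] objects sharing one gene map), `truth` and
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "pm_sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  starts <- cumsum(c(1, head(cfg$module_sizes, -1)))
  module_rows <- map2(starts, cfg$module_sizes, ~ seq(.x, .x + .y - 1))
  planted_idx <- unlist(module_rows)
  gene_map <- sim_gene_map(cfg$n_transcripts, planted_idx)

  ## ---- CNS cohort -------------------------------------------------------
  n_cns <- cfg$n_samples_cns
  f_cns <- matrix(rnorm(cfg$n_modules * n_cns), cfg$n_modules, n_cns)
  f_path <- f_cns[cfg$pathology_linked_module, ]
  pathology <- rpois(n_cns, lambda = cfg$pathology_baseline *
                       exp(cfg$pathology_effect * f_path))
  # duration declines with the pathology factor, mapped into a plausible
  # onset-to-death range so the duration screen has a planted signal
  dur_latent <- -0.8 * f_path + 0.6 * rnorm(n_cns)
  rng <- cfg$duration_range_years
  duration_cns <- rng[1] + (rng[2] - rng[1]) * pnorm(dur_latent)
  expr_cns <- sim_expression(cfg, n_cns, module_rows, f_cns)
  cns_ids <- sprintf("CNS%02d", seq_len(n_cns))
  colnames(expr_cns) <- cns_ids
  rownames(expr_cns) <- gene_map$transcript_id
  cns <- expression_study(
    expr_cns, gene_map,
    tibble(sample_id = cns_ids,
           pathology_count = pathology,
           duration_years = duration_cns,
           onset_age = runif(n_cns, 45, 75),
           sex = sample(c("M", "F"), n_cns, replace = TRUE),
           genotype = rep_len(c("C9ORF72", "sporadic"), n_cns))
  )

  ## ---- blood cohort -----------------------------------------------------
  n_bl <- cfg$n_samples_blood
  n_rapid <- max(2, round(0.38 * n_bl))
  n_slow <- max(2, round(0.38 * n_bl))
  labels <- sample(rep(c("rapid", "slow", "intermediate"),
                       c(n_rapid, n_slow, n_bl - n_rapid - n_slow)))
  duration_bl <- numeric(n_bl)
  duration_bl[labels == "rapid"] <- runif(n_rapid, max(rng[1], 0.3), 1.95)
  duration_bl[labels == "slow"] <- runif(n_slow, 4.05, max(rng[2], 4.5))
  duration_bl[labels == "intermediate"] <-
    runif(sum(labels == "intermediate"), 2.05, 3.95)
  shift <- c(rapid = 0.5, intermediate = 0, slow = -0.5)[labels]
  f_bl <- matrix(rnorm(cfg$n_modules * n_bl), cfg$n_modules, n_bl)
  expr_bl <- sim_expression(cfg, n_bl, module_rows, f_bl, shift = shift)
  bl_ids <- sprintf("LB%02d", seq_len(n_bl))
  colnames(expr_bl) <- bl_ids
  rownames(expr_bl) <- gene_map$transcript_id
  blood <- expression_study(
    expr_bl, gene_map,
    tibble(sample_id = bl_ids,
           duration_years = duration_bl,
           onset_age = runif(n_bl, 30, 80),
           sex = sample(c("M", "F"), n_bl, replace = TRUE),
           progression = labels)
  )

  ## ---- ground truth -----------------------------------------------------
  truth_modules <- tibble(
    transcript_id = gene_map$transcript_id[planted_idx],
    gene = gene_map$gene[planted_idx],
    module = rep(seq_len(cfg$n_modules), cfg$module_sizes)
  )
  prog_genes <- gene_map$gene[module_rows[[cfg$progression_linked_module]]]
  background_genes <- setdiff(unique(gene_map$gene), gene_map$gene[planted_idx])
  gwas_planted <- sort(sample(prog_genes, ceiling(0.3 * length(prog_genes))))
  gwas_bg <- sort(sample(background_genes,
                         min(cfg$n_gwas_background,
                             floor(length(background_genes) / 2))))
  filler_pool <- setdiff(background_genes, gwas_bg)
  n_filler <- min(200, length(filler_pool))
  gwas_table <- bind_rows(
    tibble(gene = c(gwas_planted, gwas_bg),
           p = 10^runif(length(gwas_planted) + length(gwas_bg), -14, -7.35)),
    tibble(gene = sort(sample(filler_pool, n_filler)),
           p = runif(n_filler, 1e-6, 1))
  )

  structure(
    list(
      cns = cns, blood = blood,
      truth = list(
        modules = truth_modules,
        seed_transcripts = truth_modules$transcript_id[
          truth_modules$module == cfg$pathology_linked_module],
        progression_genes = prog_genes,
        control_genes = gene_map$gene[module_rows[[cfg$control_identity_module]]],
        gwas_like = c(gwas_planted, gwas_bg),
        gwas_table = gwas_table,
        latent_factors = list(cns = f_cns, blood = f_bl)
      ),
      config = cfg
    ),
    class = "pm_synthetic_study"
  )
}

#' @export
print.pm_synthetic_study <- function(x, ...) {
  cat(sprintf("<pm_synthetic_study> %d transcripts; CNS n=%d, blood n=%d; %d planted modules\n",
              x$config$n_transcripts, x$config$n_samples_cns,
              x$config$n_samples_blood, x$config$n_modules))
  invisible(x)
}

#' Generate an interaction edge table with planted module partners
#'
#' Emulates a global co-expression / protein-interaction resource: each of
#' `n_partners` out-of-module genes is connected to at least two members of
#' the progression-linked planted module (edges labelled `coexpression` or
#' `ppi` with weights in (0, 1]), plus random noise edges among non-module
#' genes. Planted partners are recorded in the `partners` attribute.
#'
#' @param study A `pm_synthetic_study`.
#' @param n_partners Number of planted partner genes (the default mirrors a
#'   65-to-77-gene expansion).
#' @param noise_edges Number of random edges among non-module genes.
#' @param seed Optional seed for reproducible tables.
#' @return A tibble with columns `gene_a`, `gene_b`, `edge_type`, `weight`
#'   (canonically ordered, no self edges) and attribute `partners`.
#' @export
simulate_edge_table <- function(study, n_partners = 12, noise_edges = 30,
                                seed = NULL) {
  stopifnot(inherits(study, "pm_synthetic_study"), n_partners >= 0)
  if (!is.null(seed)) set.seed(seed)
  module <- study$truth$progression_genes
  pool <- setdiff(unique(study$cns$gene_map$gene),
                  c(module, study$truth$gwas_like))
  partners <- sort(sample(pool, n_partners))
  edges <- map_df(partners, function(g) {
    members <- sample(module, sample(2:4, 1))
    tibble(gene_a = g, gene_b = members,
           edge_type = sample(c("coexpression", "ppi"), length(members),
                              replace = TRUE),
           weight = runif(length(members), 0.3, 1))
  })
  if (noise_edges > 0) {
    noise_pool <- setdiff(pool, partners)
    a <- sample(noise_pool, noise_edges, replace = TRUE)
    b <- sample(noise_pool, noise_edges, replace = TRUE)
    keep <- a != b
    edges <- bind_rows(edges, tibble(
      gene_a = a[keep], gene_b = b[keep],
      edge_type = sample(c("coexpression", "ppi"), sum(keep), replace = TRUE),
      weight = runif(sum(keep), 0.05, 0.3)
    ))
  }
  if (nrow(edges) > 0) {
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- arrange(edges, .data$gene_a, .data$gene_b)
  }
  attr(edges, "partners") <- partners
  edges
}

#' Generate a synthetic CSF soluble TREM2 table
#'
#' `paper_like` draws case concentrations from a right-skewed distribution
#' with an early-stage elevation (concentration decreasing over the first
#' quartile of the disease course) and a positive association with duration
#' in the last quartile; `null` draws both groups from the control
#' distribution.
#'
#' @param n_cases,n_controls Group sizes (each at least 2).
#' @param effect_profile `"paper_like"` or `"null"`.
#' @param seed Integer seed.
#' @return A tibble shaped like [load_csf_table()] output.
#' @export
simulate_csf_table <- function(n_cases = 46, n_controls = 20,
                               effect_profile = c("paper_like", "null"),
                               seed = 1) {
  effect_profile <- match.arg(effect_profile)
  stopifnot(n_cases >= 2, n_controls >= 2)
  set.seed(seed)
  ctl <- stats::rlnorm(n_controls, meanlog = log(6), sdlog = 0.55)
  percent <- runif(n_cases, 0, 100)
  duration <- pmin(pmax(stats::rlnorm(n_cases, log(3), 0.7), 0.4), 17)
  onset <- runif(n_cases, 30, 80)
  if (effect_profile == "null") {
    strem2 <- stats::rlnorm(n_cases, log(6), 0.55)
  } else {
    base <- stats::rlnorm(n_cases, log(6), 0.55)
    early_boost <- 1 + 6 * exp(-percent / 15)
    late_coupling <- ifelse(percent > 75, 1 + 0.15 * duration, 1)
    strem2 <- base * early_boost * late_coupling
  }
  bind_rows(
    tibble(group = "ALS",
           sex = sample(c("M", "F"), n_cases, replace = TRUE),
           onset_age_years = onset,
           duration_years = duration,
           age_at_sample = as.character(round(onset + duration * percent / 100, 1)),
           percent_course = percent,
           strem2_ng_ml = strem2),
    tibble(group = "Control",
           sex = sample(c("M", "F"), n_controls, replace = TRUE),
           onset_age_years = NA_real_,
           duration_years = NA_real_,
           age_at_sample = NA_character_,
           percent_course = NA_real_,
           strem2_ng_ml = ctl)
  ) |>
    mutate(subject = sprintf("SIM%02d", row_number()), .before = 1)
}
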