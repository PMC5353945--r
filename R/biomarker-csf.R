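#' CSF soluble TREM2 biomarker analysis
#'
#' Soluble TREM2 (sTREM2), the cleaved ectodomain of a microglial receptor,
#' is measurable in CSF and is a candidate prognostic biomarker. This
#' module compares sTREM2 between ALS patients and controls, stages each
#' patient by where in their disease course the CSF was sampled (percent of
#' the onset-to-death interval), and tests the stage-stratified association
#' between sTREM2 and disease duration. All tests are rank-based so the
#' pronounced concentration outliers are handled without exclusion.
#'
#' The biomarker hypotheses are directional - sTREM2 elevated in ALS, and
#' positively associated with duration (higher sustained microglial
#' activation in slower disease) - so the default tests are one-sided; the
#' two-sided p-value is always reported alongside.
#'
#' @name biomarker-csf
NULL

csf_fixture_md5 <- "c3b7863678e476dfad3c479ba24bbe07"

#' Load the CSF sTREM2 clinical table
#'
#' With no arguments, loads the packaged table of 46 sporadic ALS patients
#' and 20 controls (group, sex, onset age, disease duration, age at
#' sampling, percent of disease course at sampling, sTREM2 in ng/ml). The
#' packaged file is checksum-verified; exactly one ALS row has unavailable
#' duration and staging, and control onset/duration/staging are not
#' applicable. Control ages at sampling are stored verbatim as transcribed
#' but are ambiguous and excluded from all computation.
#'
#' @param path Optional path to a CSV with the same columns.
#' @return A `pm_csf_table` tibble with a `subject` identifier column.
#' @export
load_csf_table <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "csf_strem2_table.csv",
                        package = "pathmod", mustWork = TRUE)
    if (unname(tools::md5sum(path)) != csf_fixture_md5) {
      abort("packaged CSF table is corrupted (checksum mismatch)",
            class = "pathmod_fixture_corrupt")
    }
  }
  tab <- readr::read_csv(
    path, na = c("NA", "Unavailable"),
    col_types = readr::cols(
      group = readr::col_character(),
      sex = readr::col_character(),
      onset_age_years = readr::col_double(),
      duration_years = readr::col_double(),
      age_at_sample = readr::col_character(),
      percent_course = readr::col_double(),
      strem2_ng_ml = readr::col_double()
    ))
  tab <- mutate(tab, subject = sprintf("CSF%02d", row_number()), .before = 1)
  if (packaged) {
    stopifnot(sum(tab$group == "ALS") == 46,
              sum(tab$group == "Control") == 20,
              all(tab$strem2_ng_ml > 0),
              sum(tab$group == "ALS" & is.na(tab$duration_years)) == 1)
  }
  structure(tab, class = c("pm_csf_table", class(tab)))
}

#' Compare sTREM2 between ALS patients and controls
#'
#' Arithmetic group means plus a Mann-Whitney U test on ranks. The default
#' alternative tests for elevation in ALS (one-sided); the two-sided value
#' is reported in `p_two_sided`.
#'
#' @param table A CSF table (see [load_csf_table()]).
#' @param alternative Alternative hypothesis for the rank test (default
#'   `"greater"`: ALS exceeds control).
#' @return One-row tibble: group means, U statistic, `p_value`,
#'   `p_two_sided`, test method and group sizes.
#' @export
compare_strem2_groups <- function(table,
                                  alternative = c("greater", "two.sided",
                                                  "less")) {
  alternative <- match.arg(alternative)
  a <- table$strem2_ng_ml[table$group == "ALS"]
  b <- table$strem2_ng_ml[table$group == "Control"]
  mw <- mann_whitney_test(a, b, alternative = alternative)
  mw2 <- mann_whitney_test(a, b, alternative = "two.sided")
  tibble(mean_als = mean(a), mean_control = mean(b),
         u_statistic = mw$statistic, p_value = mw$p_value,
         p_two_sided = mw2$p_value, method = mw$method,
         alternative = alternative,
         n_als = length(a), n_control = length(b))
}

#' Stage patients by position in the disease course at sampling
#'
#' ALS subjects with a known percent-of-course are ranked by it; the lowest
#' `floor(centile * n)` form the early-disease stage and the highest the
#' late-disease stage, the remainder middle. Subjects without staging
#' information are `unstaged`. Ties are broken by subject identifier. The
#' floor convention over the staged subjects is the one that reproduces
#' the published per-stage concentration summaries.
#'
#' @param table A CSF table.
#' @param centile Stage width as a fraction of staged subjects (default
#'   0.25, i.e. quartiles), in (0, 0.5).
#' @return A `pm_stage_assignment` tibble: `subject`, `percent_course`,
#'   `stage` in early/middle/late/unstaged.
#' @export
assign_stage <- function(table, centile = 0.25) {
  stopifnot(centile > 0, centile < 0.5)
  als <- filter(table, .data$group == "ALS")
  staged <- filter(als, !is.na(.data$percent_course)) |>
    arrange(.data$percent_course, .data$subject)
  n <- nrow(staged)
  k <- floor(centile * n)
  stage <- rep("middle", n)
  if (k > 0) {
    stage[seq_len(k)] <- "early"
    stage[seq(n - k + 1, n)] <- "late"
  }
  out <- bind_rows(
    tibble(subject = staged$subject, percent_course = staged$percent_course,
           stage = stage),
    tibble(subject = als$subject[is.na(als$percent_course)],
           percent_course = NA_real_, stage = "unstaged")
  )
  structure(out, class = c("pm_stage_assignment", class(out)),
            centile = centile, n_staged = n, n_per_stage = k)
}

#' Per-stage sTREM2 summary
#'
#' Arithmetic mean, standard error and size of each disease stage; empty
#' stages are omitted with a message.
#'
#' @param table A CSF table.
#' @param stages A [assign_stage()] result (defaults to quartile staging of
#'   `table`).
#' @return A `pm_stage_summary` tibble: `stage`, `n`, `mean_strem2`,
#'   `se_strem2`.
#' @export
stage_summary <- function(table, stages = assign_stage(table)) {
  joined <- left_join(stages, select(table, "subject", "strem2_ng_ml"),
                      by = "subject")
  out <- joined |>
    filter(.data$stage != "unstaged") |>
    group_by(.data$stage) |>
    summarise(n = n(), mean_strem2 = mean(.data$strem2_ng_ml),
              se_strem2 = sd(.data$strem2_ng_ml) / sqrt(n()),
              .groups = "drop") |>
    mutate(stage = factor(.data$stage, c("early", "middle", "late"))) |>
    arrange(.data$stage)
  missing <- setdiff(c("early", "middle", "late"), as.character(out$stage))
  if (length(missing)) {
    inform(paste("empty stages omitted:", paste(missing, collapse = ", ")))
  }
  structure(out, class = c("pm_stage_summary", class(out)))
}

#' Stage-stratified association of sTREM2 with disease duration
#'
#' Spearman rank correlation between sTREM2 concentration and disease
#' duration (onset to death) within each stage. The default alternative is
#' a positive association (the directional biomarker hypothesis); the
#' two-sided p is reported alongside. Stages with fewer than `min_n`
#' subjects of known duration yield an `insufficient data` record.
#'
#' @param table A CSF table.
#' @param stages A [assign_stage()] result.
#' @param alternative Alternative for the correlation test.
#' @param min_n Minimum stage size (default 4).
#' @return Tibble: `stage`, `n`, `rho`, `p_value`, `p_two_sided`, `method`,
#'   `note`.
#' @export
stage_stratified_association <- function(table, stages = assign_stage(table),
                                         alternative = c("greater",
                                                         "two.sided", "less"),
                                         min_n = 4) {
  alternative <- match.arg(alternative)
  joined <- left_join(stages,
                      select(table, "subject", "strem2_ng_ml",
                             "duration_years"),
                      by = "subject") |>
    filter(.data$stage %in% c("early", "middle", "late"),
           !is.na(.data$duration_years))
  map_df(c("early", "middle", "late"), function(s) {
    d <- filter(joined, .data$stage == s)
    if (nrow(d) < min_n) {
      return(tibble(stage = s, n = nrow(d), rho = NA_real_,
                    p_value = NA_real_, p_two_sided = NA_real_,
                    method = NA_character_, note = "insufficient data"))
    }
    ht <- tryCatch(
      spearman_test(d$strem2_ng_ml, d$duration_years,
                    alternative = alternative),
      pathmod_degenerate_input = function(e) NULL,
      pathmod_insufficient_data = function(e) NULL)
    if (is.null(ht)) {
      return(tibble(stage = s, n = nrow(d), rho = NA_real_,
                    p_value = NA_real_, p_two_sided = NA_real_,
                    method = NA_character_, note = "degenerate input"))
    }
    ht2 <- spearman_test(d$strem2_ng_ml, d$duration_years)
    tibble(stage = s, n = nrow(d), rho = ht$statistic,
           p_value = ht$p_value, p_two_sided = ht2$p_value,
           method = ht$method, note = NA_character_)
  })
}
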