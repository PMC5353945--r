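#' Plots for screen, prioritisation and CSF results
#'
#' `autoplot()` methods give the standard visual for each result type:
#' screens as rho versus evidence, priority reports as per-set enrichment
#' bars, stage summaries as mean +/- standard error profiles.
#'
#' @param object A pathmod result object.
#' @param ... Unused.
#' @name pathmod-plots
NULL

#' @rdname pathmod-plots
#' @export
autoplot.pm_screen <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rho, y = -log10(.data$p_value),
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho vs covariate",
                  y = expression(-log[10](p)),
                  colour = sprintf("p < %g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' @rdname pathmod-plots
#' @export
autoplot.pm_priority <- function(object, ...) {
  rec <- object$records |>
    mutate(neglog = -log10(.data$p_value),
           triple = .data$module %in% object$triple_enriched)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$module, y = .data$neglog,
                                    fill = .data$triple)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~set_name, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "module", y = expression(-log[10](p)),
                  fill = "triple enriched") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname pathmod-plots
#' @export
autoplot.pm_stage_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stage, y = .data$mean_strem2)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_strem2 - .data$se_strem2,
                   ymax = .data$mean_strem2 + .data$se_strem2),
      width = 0.15) +
    ggplot2::labs(x = "disease stage at CSF sampling",
                  y = "soluble TREM2 (ng/ml)") +
    ggplot2::theme_minimal()
}

#' CSF concentrations by group
#'
#' Jittered per-subject sTREM2 concentrations for ALS and control groups on
#' a log scale (the distribution is right-skewed with a pronounced
#' outlier).
#'
#' @param table A CSF table.
#' @return A ggplot.
#' @export
plot_csf_groups <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group,
                                      y = .data$strem2_ng_ml)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, colour = "steelblue") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "soluble TREM2 (ng/ml, log scale)") +
    ggplot2::theme_minimal()
}
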