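#' Tidiers for pathmod fit objects
#'
#' `tidy()` returns per-term (or per-fold) detail; `glance()` returns the
#' one-row model summary, following the broom convention.
#'
#' @param x A `pm_ph_fit` or `pm_panel_fit`.
#' @param ... Unused.
#' @name pathmod-tidiers
NULL

#' @rdname pathmod-tidiers
#' @export
tidy.pm_ph_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s),
         estimate = s[, "coef"],
         std_error = s[, grep("^se", colnames(s))[1]],
         statistic = s[, "z"],
         p_value = s[, ncol(s)])
}

#' @rdname pathmod-tidiers
#' @export
glance.pm_ph_fit <- function(x, ...) {
  tibble(n = x$n, n_features = x$n_features,
         lrt_chisq = x$lrt$chisq, lrt_df = x$lrt$df,
         lrt_p_value = x$lrt$p_value, ridge_stabilised = x$flagged)
}

#' @rdname pathmod-tidiers
#' @export
tidy.pm_panel_fit <- function(x, ...) {
  x$predictions
}

#' @rdname pathmod-tidiers
#' @export
glance.pm_panel_fit <- function(x, ...) {
  tibble(n = x$n, n_genes = length(x$panel), accuracy = x$accuracy,
         majority_accuracy = x$majority_accuracy, chance_p = x$chance_p)
}
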