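#' Blood biomarker assessment of a module
#'
#' Two complementary evaluations of module expression in blood-derived
#' samples: a Cox proportional-hazards model testing whether the top
#' principal components of module expression predict survival (onset to
#' death) beyond onset age and sex, and per-gene logistic screens plus a
#' leave-one-out cross-validated gene panel classifying rapid versus slow
#' progressors.
#'
#' @name biomarker-blood
NULL

#' Principal-component features of module expression
#'
#' Restricts the study to the module's measured genes, collapses transcripts
#' to genes, standardises each gene across samples and returns the sample
#' scores on the top `k` components (fewer, with a warning, when `k`
#' exceeds the available rank).
#'
#' @param study An [expression_study()].
#' @param module Module gene set.
#' @param k Number of components (default 15).
#' @return Samples-by-k score matrix with sample identifiers as rownames.
#' @export
module_pc_features <- function(study, module, k = 15) {
  expr <- collapse_to_genes(study, as.character(module))
  keep <- apply(expr, 1, sd) > 0
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0) {
    abort("no non-constant module genes measured",
          class = "pathmod_missing_genes")
  }
  z <- t(scale(t(expr)))
  m <- t(z)
  k_max <- min(nrow(m) - 1, ncol(m))
  if (k > k_max) {
    warn(sprintf("k = %d exceeds available components; using %d", k, k_max))
    k <- k_max
  }
  pc <- principal_components(m, k)
  scores <- pc$scores
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Proportional-hazards assessment of module features
#'
#' Fits a Cox model of survival time (disease duration rounded to the
#' nearest half-year, all events observed unless `event` is supplied) on
#' clinical covariates plus the module feature block, with Efron handling
#' of the tied times the rounding guarantees. Global significance is the
#' likelihood-ratio chi-squared of the feature block against the
#' covariates-only null, with degrees of freedom equal to the number of
#' features. On non-convergence or collinearity the feature block is
#' ridge-stabilised and the fit flagged.
#'
#' @param samples Data frame with `duration_years` and the covariate
#'   columns.
#' @param features Numeric matrix of per-sample features (rows align with
#'   `samples`; 0 columns allowed). Typically [module_pc_features()].
#' @param covariates Covariate column names (default onset age and sex).
#' @param event Optional 0/1 vector of observed-event flags (default all 1,
#'   i.e. all patients deceased).
#' @param round_half_year Round event times to the nearest half-year
#'   (default TRUE).
#' @param ridge Ridge penalty used only for the stabilised fallback fit.
#' @return A `pm_ph_fit` with [tidy()] and [glance()] methods.
#' @export
fit_ph_model <- function(samples, features,
                         covariates = intersect(c("onset_age", "sex"),
                                                names(samples)),
                         event = NULL, round_half_year = TRUE,
                         ridge = 0.5) {
  samples <- as_tibble(samples)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(samples) || ncol(features) == 0)
  time <- samples$duration_years
  if (round_half_year) time <- round(time * 2) / 2
  event <- event %||% rep(1, nrow(samples))
  if (length(unique(time[event == 1])) < 2) {
    abort("need at least 2 distinct event times",
          class = "pathmod_insufficient_data")
  }
  dat <- bind_cols(tibble(.time = time, .event = event),
                   samples[, covariates, drop = FALSE])
  null_rhs <- if (length(covariates)) paste(covariates, collapse = " + ")
              else "1"
  null_fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", null_rhs)),
    data = dat, ties = "efron")
  if (ncol(features) == 0) {
    lrt <- tibble(chisq = 0, df = 0L, p_value = 1)
    return(structure(list(fit = null_fit, null_fit = null_fit, lrt = lrt,
                          n = nrow(dat), flagged = FALSE,
                          n_features = 0L), class = "pm_ph_fit"))
  }
  colnames(features) <- colnames(features) %||%
    paste0("f", seq_len(ncol(features)))
  dat_full <- bind_cols(dat, as_tibble(features))
  rhs <- paste(c(if (length(covariates)) covariates, colnames(features)),
               collapse = " + ")
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  rank_ok <- qr(cbind(1, features))$rank == ncol(features) + 1
  flagged <- FALSE
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(form, data = dat_full, ties = "efron"),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        flagged <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || flagged || !rank_ok ||
      any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15)) {
    flagged <- TRUE
    pen <- paste(c(if (length(covariates)) covariates,
                   sprintf("survival::ridge(%s, theta = %g)",
                           paste(colnames(features), collapse = ", "),
                           ridge)),
                 collapse = " + ")
    fit <- suppressWarnings(survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~", pen)),
      data = dat_full, ties = "efron"))
  }
  chisq <- max(0, 2 * (fit$loglik[2] - null_fit$loglik[2]))
  df <- ncol(features)
  lrt <- tibble(chisq = chisq, df = as.integer(df),
                p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
  structure(list(fit = fit, null_fit = null_fit, lrt = lrt, n = nrow(dat),
                 flagged = flagged, n_features = ncol(features)),
            class = "pm_ph_fit")
}

#' @export
print.pm_ph_fit <- function(x, ...) {
  cat(sprintf(
    "<pm_ph_fit> n=%d, %d features; LRT chisq=%.2f (df=%d), p=%.3g%s\n",
    x$n, x$n_features, x$lrt$chisq, x$lrt$df, x$lrt$p_value,
    if (x$flagged) " [ridge-stabilised]" else ""))
  invisible(x)
}

# ridge-penalised logistic fit for separated data: maximises
# loglik - lambda/2 * slope^2 over (intercept, slope)
ridge_logistic <- function(x, y, lambda = 0.1) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda / 2 * b[2]^2
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS")
  null_opt <- stats::optimize(function(b0) sum(log1p(exp(-(2 * y - 1) * b0))),
                              c(-20, 20))
  list(coef = opt$par, deviance_drop = 2 * (null_opt$objective -
                                              (opt$value - lambda / 2 * opt$par[2]^2)))
}

#' Per-gene logistic screen for progression classification
#'
#' For each module gene, fits a binomial logistic regression of the
#' rapid/slow label on (standardised) gene expression and tests it against
#' the intercept-only null by likelihood ratio. Perfect-separation cases
#' are flagged and assigned the test from a small-ridge penalised fit so
#' the screen never aborts on small cohorts. Constant genes are skipped.
#'
#' @param study An [expression_study()] whose samples carry `progression`
#'   (or `duration_years`, from which labels are derived).
#' @param module Module gene set.
#' @param alpha Selection threshold on the unadjusted LRT p (default 0.05).
#' @return Tibble: `gene`, `estimate` (log-odds slope), `p_value`,
#'   `separation`, `selected`.
#' @export
per_gene_logistic_screen <- function(study, module, alpha = 0.05) {
  lab <- blood_labels(study)
  expr <- collapse_to_genes(study, as.character(module))[, lab$sample_id,
                                                         drop = FALSE]
  y <- as.integer(lab$progression == "rapid")
  out <- map_df(rownames(expr), function(g) {
    x <- as.numeric(expr[g, ])
    if (sd(x) == 0) return(NULL)
    x <- as.numeric(scale(x))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || abs(coef(fit)[2]) > 15) {
      sep <- TRUE
      rf <- ridge_logistic(x, y)
      est <- rf$coef[2]
      p <- stats::pchisq(max(0, rf$deviance_drop), 1, lower.tail = FALSE)
    } else {
      est <- unname(coef(fit)[2])
      p <- stats::pchisq(fit$null.deviance - fit$deviance, 1,
                         lower.tail = FALSE)
    }
    tibble(gene = g, estimate = est, p_value = p, separation = sep)
  })
  if (nrow(out) < length(unique(as.character(module)))) {
    inform(sprintf("per_gene_logistic_screen: skipped constant/unmeasured genes"))
  }
  mutate(out, selected = .data$p_value < alpha)
}

blood_labels <- function(study) {
  samp <- study$samples
  labels <- if ("progression" %in% names(samp)) samp$progression
            else classify_progression(samp$duration_years)
  lab <- tibble(sample_id = samp$sample_id, progression = labels) |>
    filter(.data$progression %in% c("rapid", "slow"))
  if (sum(lab$progression == "rapid") < 2 || sum(lab$progression == "slow") < 2) {
    abort("group definition error: need >= 2 rapid and >= 2 slow samples",
          class = "pathmod_group_error")
  }
  lab
}

#' Leave-one-out cross-validated panel accuracy
#'
#' Fits a binomial logistic regression of the rapid/slow label on the panel
#' genes' expression with each sample held out in turn, predicting the
#' held-out label at probability threshold 0.5. `chance_p` is the exact
#' binomial tail probability of at least as many correct calls under a fair
#' coin; the majority-class baseline accuracy is reported alongside. Folds
#' whose training data lose a class fall back to a majority-class
#' prediction and are flagged.
#'
#' @param study An [expression_study()] with progression labels.
#' @param panel Character vector of panel gene identifiers.
#' @return A `pm_panel_fit` with [tidy()] and [glance()] methods.
#' @export
loocv_panel_accuracy <- function(study, panel) {
  lab <- blood_labels(study)
  expr <- collapse_to_genes(study, as.character(panel))[, lab$sample_id,
                                                        drop = FALSE]
  x <- t(scale(t(expr)))
  dat <- as_tibble(t(x), .name_repair = ~ paste0("g", seq_along(.x)))
  y <- as.integer(lab$progression == "rapid")
  n <- nrow(dat)
  preds <- map_df(seq_len(n), function(i) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      maj <- as.integer(mean(ytr) >= 0.5)
      return(tibble(sample_id = lab$sample_id[i], truth = y[i],
                    prob = NA_real_, predicted = maj, degenerate_fold = TRUE))
    }
    fit <- suppressWarnings(glm(ytr ~ ., data = dat[-i, ], family = binomial()))
    p <- suppressWarnings(
      predict(fit, newdata = dat[i, , drop = FALSE], type = "response"))
    tibble(sample_id = lab$sample_id[i], truth = y[i], prob = unname(p),
           predicted = as.integer(p > 0.5), degenerate_fold = FALSE)
  })
  correct <- sum(preds$predicted == preds$truth)
  structure(list(
    panel = as.character(panel),
    predictions = preds,
    accuracy = correct / n,
    chance_p = pbinom(correct - 1, n, 0.5, lower.tail = FALSE),
    majority_accuracy = max(mean(y), 1 - mean(y)),
    n = n
  ), class = "pm_panel_fit")
}

#' @export
print.pm_panel_fit <- function(x, ...) {
  cat(sprintf(
    "<pm_panel_fit> %d-gene panel, n=%d: accuracy %.0f%% (majority %.0f%%), chance p=%.3g\n",
    length(x$panel), x$n, 100 * x$accuracy, 100 * x$majority_accuracy,
    x$chance_p))
  invisible(x)
}
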