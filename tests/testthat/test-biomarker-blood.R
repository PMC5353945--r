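test_that("module PC features reduce to standardised expression for one gene", {
  st <- simulate_study(sim_config(n_transcripts = 400,
                                  module_sizes = c(40, 30, 30), seed = 51))
  g <- st$truth$progression_genes[1]
  f <- module_pc_features(st$blood, g, k = 1)
  z <- as.numeric(scale(collapse_to_genes(st$blood, g)[1, ]))
  expect_gt(abs(cor(f[, 1], z)), 1 - 1e-10)
  expect_warning(module_pc_features(st$blood, g, k = 3), "exceeds")
})

test_that("PC1 of a planted one-factor module tracks the latent factor", {
  st <- simulate_study(sim_config(seed = 52))
  # module 2 carries no group shift, so its only structure is the factor
  m2 <- st$truth$modules$gene[st$truth$modules$module == 2]
  f <- module_pc_features(st$blood, m2, k = 3)
  expect_gte(abs(cor(f[, 1], st$truth$latent_factors$blood[2, ])), 0.9)
})

test_that("proportional hazards fit recovers a known log hazard ratio", {
  set.seed(61)
  n <- 200
  ests <- replicate(10, {
    x <- rbinom(n, 1, 0.5)
    samples <- tibble::tibble(duration_years = rexp(n, 0.2 * exp(log(3) * x)),
                              onset_age = runif(n, 40, 70),
                              sex = sample(c("M", "F"), n, TRUE))
    fit <- fit_ph_model(samples, matrix(x, ncol = 1,
                                        dimnames = list(NULL, "grp")),
                        round_half_year = FALSE)
    expect_false(fit$flagged)
    expect_lt(glance(fit)$lrt_p_value, 1e-4)
    td <- tidy(fit)
    td$estimate[td$term == "grp"]
  })
  expect_lt(abs(mean(ests) - log(3)), 0.15)
})

test_that("proportional hazards LRT is null-calibrated and hits edge cases", {
  set.seed(62)
  ps <- replicate(500, {
    n <- 40
    samples <- tibble::tibble(duration_years = rexp(n, 0.3) + 0.1,
                              onset_age = runif(n, 40, 70),
                              sex = sample(c("M", "F"), n, TRUE))
    fit_ph_model(samples, matrix(rnorm(n), ncol = 1))$lrt$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  samples <- tibble::tibble(duration_years = c(1, 2, 3, 4, 2, 5),
                            onset_age = 50 + 1:6,
                            sex = rep(c("M", "F"), 3))
  f0 <- fit_ph_model(samples, matrix(nrow = 6, ncol = 0))
  expect_equal(f0$lrt$chisq, 0)
  expect_equal(f0$lrt$p_value, 1)

  fid <- suppressWarnings(
    fit_ph_model(samples, matrix(1, nrow = 6, ncol = 1)))
  expect_equal(fid$lrt$chisq, 0)
})

test_that("event times are rounded to half-years with Efron tie handling", {
  samples <- tibble::tibble(duration_years = c(1.1, 1.2, 2.6, 2.7, 3.9, 4.1),
                            onset_age = 50 + 1:6,
                            sex = rep(c("M", "F"), 3))
  set.seed(1)
  # 6 samples with 3 covariates: the toy null fit may grumble about
  # convergence, which is irrelevant to the rounding contract under test
  fit <- suppressWarnings(fit_ph_model(samples, matrix(rnorm(6), ncol = 1)))
  expect_setequal(unique(fit$fit$y[, "time"]), c(1, 2.5, 4))
})

test_that("logistic likelihood-ratio statistic matches a direct optimiser", {
  set.seed(63)
  checked <- 0
  while (checked < 5) {
    n <- sample(8:12, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(0.5 * x))
    if (length(unique(y)) < 2) next
    # quasi-separated draws have no finite optimum to compare against
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    if (any(abs(fit$fitted.values - 0.5) > 0.49)) next
    expect_lt(abs((fit$null.deviance - fit$deviance) -
                    oracle_logistic_lrt(x, y)), 1e-6)
    checked <- checked + 1
  }
})

test_that("per-gene screen flags perfect separators yet reports them significant", {
  st <- simulate_study(sim_config(n_transcripts = 400,
                                  module_sizes = c(40, 30, 30), seed = 53))
  lab <- st$blood$samples$progression
  expr <- st$blood$expr
  sep_tx <- rownames(expr)[200]
  expr[sep_tx, ] <- ifelse(lab == "rapid", 5, 0) + seq_along(lab) * 1e-3
  st_mod <- expression_study(expr, st$blood$gene_map, st$blood$samples)
  sep_gene <- st$blood$gene_map$gene[st$blood$gene_map$transcript_id == sep_tx]
  res <- per_gene_logistic_screen(st_mod, sep_gene)
  expect_true(res$separation[1])
  expect_true(res$selected[1])
})

test_that("per-gene screen is null-calibrated", {
  set.seed(64)
  n <- 40
  y <- rep(0:1, each = n / 2)
  ps <- replicate(2000, {
    x <- rnorm(n)
    fitp <- suppressWarnings(glm(y ~ x, family = binomial()))
    stats::pchisq(fitp$null.deviance - fitp$deviance, 1, lower.tail = FALSE)
  })
  expect_gte(mean(ps < 0.05), 0.035)
  expect_lte(mean(ps < 0.05), 0.065)
})

test_that("per-gene screen recovers most of a planted discriminative module", {
  st <- simulate_study(sim_config(seed = 54, group_effect = 2))
  res <- per_gene_logistic_screen(st$blood, st$truth$progression_genes)
  expect_gte(mean(res$selected), 0.8)
})

test_that("LOOCV panel accuracy is exact on separable data and order-invariant", {
  st <- simulate_study(sim_config(n_transcripts = 400,
                                  module_sizes = c(40, 30, 30), seed = 55))
  lab <- st$blood$samples$progression
  expr <- st$blood$expr
  expr["T00200_at", ] <- ifelse(lab == "rapid", 3, -3) + rnorm(26, sd = 0.1)
  st_mod <- expression_study(expr, st$blood$gene_map, st$blood$samples)
  panel_gene <- st$blood$gene_map$gene[
    st$blood$gene_map$transcript_id == "T00200_at"]
  fit <- loocv_panel_accuracy(st_mod, panel_gene)
  expect_equal(fit$accuracy, 1)
  expect_lt(fit$chance_p, 0.001)

  perm <- sample(ncol(expr))
  st_perm <- expression_study(expr[, perm], st$blood$gene_map,
                              st$blood$samples)
  expect_equal(loocv_panel_accuracy(st_perm, panel_gene)$accuracy,
               fit$accuracy)
})

test_that("LOOCV accuracy of a label-independent panel is centred on chance", {
  set.seed(65)
  accs <- replicate(200, {
    n <- 20
    expr <- matrix(rnorm(3 * n), 3, n,
                   dimnames = list(paste0("T", 1:3), paste0("S", 1:n)))
    st <- expression_study(
      expr,
      tibble::tibble(transcript_id = rownames(expr),
                     gene = paste0("G", 1:3)),
      tibble::tibble(sample_id = colnames(expr),
                     progression = rep(c("rapid", "slow"), each = n / 2)))
    loocv_panel_accuracy(st, paste0("G", 1:3))$accuracy
  })
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("glance and tidy expose the panel fit summary", {
  st <- simulate_study(sim_config(seed = 56, group_effect = 1.5))
  res <- per_gene_logistic_screen(st$blood, st$truth$progression_genes)
  panel <- head(dplyr::arrange(res, p_value)$gene, 3)
  fit <- loocv_panel_accuracy(st$blood, panel)
  g <- glance(fit)
  expect_named(g, c("n", "n_genes", "accuracy", "majority_accuracy",
                    "chance_p"))
  expect_equal(nrow(tidy(fit)), fit$n)
  expect_true(all(tidy(fit)$predicted %in% 0:1))
})
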