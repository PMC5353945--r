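test_that("spearman_test recovers perfect monotone and antitone association", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$statistic, 1)
  expect_equal(spearman_test(1:3, 3:1)$statistic, -1)
})

test_that("spearman_test matches midrank-Pearson and permutation oracles under ties", {
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  res <- spearman_test(x, y)
  expect_equal(res$statistic, cor(rank(x), rank(y)))
  expect_equal(res$p_value, oracle_spearman_p(x, y))
  expect_identical(res$method, "exact")

  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- rnorm(n)
    if (var(rank(x)) == 0) next
    expect_equal(spearman_test(x, y)$p_value, oracle_spearman_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_test uses the t-approximation from 10 pairs and drops NA pairs", {
  set.seed(3)
  x <- rnorm(12)
  y <- rnorm(12)
  res <- spearman_test(x, y)
  expect_identical(res$method, "t_approx")
  rho <- cor(rank(x), rank(y))
  tt <- rho * sqrt(10 / (1 - rho^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 10))

  x[3] <- NA
  expect_equal(spearman_test(x, y)$n_eff, 11L)
})

test_that("spearman_test rejects undersized and degenerate input", {
  expect_error(spearman_test(1:2, 2:1), class = "pathmod_insufficient_data")
  expect_error(spearman_test(c(1, 1, 1), 1:3),
               class = "pathmod_degenerate_input")
})

test_that("mann_whitney_test matches exact enumeration on small samples", {
  res <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$method, "exact")

  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    res <- mann_whitney_test(a, b)
    expect_equal(res$statistic, oracle_u(a, b))
    expect_equal(res$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("mann_whitney_test on identical samples is far from rejection", {
  a <- rep(c(1, 2, 5, 9, 3), 3)
  res <- mann_whitney_test(a, a)
  expect_identical(res$method, "normal_approx")
  expect_gte(res$p_value, 0.99)
})

test_that("mann_whitney_test requires two observations per group", {
  expect_error(mann_whitney_test(1, c(2, 3)),
               class = "pathmod_insufficient_data")
  expect_error(mann_whitney_test(numeric(0), c(2, 3)),
               class = "pathmod_insufficient_data")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  a <- rnorm(15); b <- rnorm(14) + 0.5
  f <- function(v) exp(3 * v) + 1
  expect_equal(spearman_test(x, y)$p_value,
               spearman_test(f(x), f(y))$p_value)
  expect_equal(mann_whitney_test(a, b)$p_value,
               mann_whitney_test(f(a), f(b))$p_value)
})

test_that("fisher_enrichment reproduces closed forms and the tail-sum oracle", {
  # minimum attainable overlap of zero
  expect_equal(fisher_enrichment(0, 10, 5, 85)$p_value, 1)
  # complete overlap point mass: both sets of 10 drawn identical in 100
  expect_equal(fisher_enrichment(10, 0, 0, 90)$p_value, 1 / choose(100, 10))

  set.seed(31)
  for (i in 1:20) {
    uni <- sample(20:200, 1)
    s <- sample(1:(uni - 1), 1)
    m <- sample(1:(uni - 1), 1)
    ov <- sample(max(0, s + m - uni):min(s, m), 1)
    res <- fisher_enrichment(ov, s - ov, m - ov, uni - s - m + ov)
    expect_equal(res$p_value, oracle_hyper_tail(ov, s, m, uni),
                 tolerance = 1e-12)
    expect_equal(res$p_value,
                 fisher.test(matrix(c(ov, s - ov, m - ov, uni - s - m + ov),
                                    2), alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_enrichment equals exhaustive enumeration on all small tables", {
  for (uni in c(12, 25)) {
    for (s in 1:(uni - 1)) for (m in 1:(uni - 1)) {
      if (s + m > uni + 6) next
      for (ov in max(0, s + m - uni):min(s, m)) {
        expect_equal(
          fisher_enrichment(ov, s - ov, m - ov, uni - s - m + ov)$p_value,
          oracle_hyper_tail(ov, s, m, uni), tolerance = 1e-12)
      }
    }
  }
})

test_that("fisher_enrichment validates its contingency counts", {
  expect_error(fisher_enrichment(-1, 2, 3, 4),
               class = "pathmod_inconsistent_universe")
  expect_error(fisher_enrichment(1.5, 2, 3, 4),
               class = "pathmod_inconsistent_universe")
})

test_that("bh_adjust performs the step-up adjustment", {
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.01), 0.01)
  # hand-computed step-up: p_(i) * n / i then cumulative minimum from the top
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.04))
  p2 <- c(0.005, 0.04, 0.03, 0.9)
  expect_equal(bh_adjust(p2), c(0.02, 0.0533333333333333, 0.0533333333333333, 0.9))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), class = "pathmod_bad_pvalues")
})

test_that("principal_components handles rank-1, orthogonal blocks and k = 0", {
  u <- c(1, 2, 3, -1, 0.5, 2)
  v <- c(2, -1, 0.5, 1)
  m <- outer(u, v)
  pc <- principal_components(m, 1)
  expect_equal(pc$variance_fractions[1], 1)

  # two orthogonal blocks of features; compare against an eigen oracle
  block <- cbind(c(1, 1, -1, -1, 1, -1) * 2, c(1, -1, 1, -1, -1, 1) * 1.5)
  m2 <- cbind(block[, 1], block[, 1], block[, 2], block[, 2]) +
    matrix(rnorm(24, sd = 0.01), 6)
  pc2 <- principal_components(m2, 2)
  ev <- eigen(cov(m2))
  for (j in 1:2) {
    expect_gt(abs(cor(pc2$scores[, j],
                      scale(m2, scale = FALSE) %*% ev$vectors[, j])), 0.999)
  }
  expect_equal(pc2$variance_fractions[1:2],
               (ev$values / sum(ev$values))[1:2])

  pc0 <- principal_components(m2, 0)
  expect_identical(ncol(pc0$scores), 0L)
  expect_identical(pc0$variance_fractions, numeric(0))
})

test_that("principal_components truncates beyond the rank with a warning and reconstructs", {
  set.seed(8)
  m <- matrix(rnorm(5 * 9), 5, 9) # rank 5 at most (4 after centring)
  expect_warning(pc <- principal_components(m, 9), "rank deficient")
  expect_lte(ncol(pc$scores), 4)
  recon <- pc$scores %*% t(pc$rotation)
  centred <- scale(m, scale = FALSE)
  expect_lt(norm(recon - centred, "F") / norm(centred, "F"), 1e-8)
  expect_true(all(diff(pc$variance_fractions) <= 1e-12))
})

test_that("rejection rates under the null are calibrated at alpha = 0.05", {
  set.seed(71)
  n_rep <- 2000
  sp <- replicate(n_rep, spearman_test(rnorm(12), rnorm(12))$p_value < 0.05)
  expect_gte(mean(sp), 0.035); expect_lte(mean(sp), 0.065)
  mw <- replicate(n_rep,
                  mann_whitney_test(rnorm(15), rnorm(15))$p_value < 0.05)
  expect_gte(mean(mw), 0.035); expect_lte(mean(mw), 0.065)
  # hypergeometric null: overlap drawn from the null distribution itself
  fi <- replicate(n_rep, {
    ov <- stats::rhyper(1, 200, 1800, 100)
    fisher_enrichment(ov, 200 - ov, 100 - ov, 1700 + ov)$p_value < 0.05
  })
  expect_gte(mean(fi), 0.035); expect_lte(mean(fi), 0.065)
})
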