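#' Rank-based and exact statistical kernels
#'
#' These kernels back every downstream stage of the workflow: the
#' pathology/duration screens (Spearman), the rapid-vs-slow contrasts
#' (Mann-Whitney), module-vs-gene-set enrichment (one-sided hypergeometric),
#' multiple-testing adjustment (Benjamini-Hochberg) and module summarisation
#' (principal components). Each returns a one-row tibble carrying method
#' metadata so reports can state exactly how a p-value was obtained.
#'
#' @name core-stats
NULL

pm_test_result <- function(statistic, p_value, method, n_eff, alternative) {
  tibble(
    statistic = statistic,
    p_value = min(max(p_value, .Machine$double.xmin), 1),
    method = method,
    n_eff = as.integer(n_eff),
    alternative = alternative
  )
}

## all permutations of 1..n as an (n!)-by-n matrix; only ever used for n < 10
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exact permutation p for the midrank correlation: distribution of rho over
# all orderings of y against fixed x (valid with or without ties)
spearman_perm_p <- function(rx, ry, rho, alternative) {
  n <- length(rx)
  perms <- perm_matrix(n)
  ry_perm <- matrix(ry[perms], nrow(perms), n)
  rx_c <- rx - mean(rx)
  denom <- sqrt(sum(rx_c^2)) *
    sqrt(sum((ry - mean(ry))^2))
  rho_perm <- as.vector(ry_perm %*% rx_c) / denom
  eps <- 1e-12
  switch(alternative,
    two.sided = mean(abs(rho_perm) >= abs(rho) - eps),
    greater = mean(rho_perm >= rho - eps),
    less = mean(rho_perm <= rho + eps)
  )
}

#' Spearman rank correlation test
#'
#' Computes the tie-corrected Spearman correlation (Pearson correlation of
#' midranks). Pairs with a missing entry in either vector are dropped before
#' ranking and `n_eff` reports the number of usable pairs. For fewer than 10
#' usable pairs the p-value is exact (full enumeration of the permutation
#' distribution of the midrank correlation, valid under ties); otherwise a
#' t-distribution approximation on the tie-corrected correlation is used,
#' as is standard for small clinical cohorts of 11-14 samples.
#'
#' @param x,y Numeric vectors of equal length (at least 3 usable pairs).
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @return A one-row tibble with columns `statistic` (the correlation),
#'   `p_value`, `method` (`"exact"` or `"t_approx"`), `n_eff`, `alternative`.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))
#' @export
spearman_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("insufficient data: fewer than 3 usable pairs",
          class = "pathmod_insufficient_data")
  }
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    abort("degenerate input: zero variance in a ranked vector",
          class = "pathmod_degenerate_input")
  }
  rho <- cor(rx, ry)
  if (n < 10) {
    p <- spearman_perm_p(rx, ry, rho, alternative)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
      two.sided = 2 * pt(-abs(tt), df = n - 2),
      greater = pt(tt, df = n - 2, lower.tail = FALSE),
      less = pt(tt, df = n - 2)
    )
    method <- "t_approx"
  }
  pm_test_result(rho, p, method, n, alternative)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test for a location difference between groups. The U
#' statistic counts, over all cross-group pairs, how often an observation in
#' `a` exceeds one in `b` (ties count one half). The p-value is exact
#' (distribution over all group labelings) when the combined sample size is
#' at most 20 and there are no ties, otherwise a normal approximation with
#' tie and continuity correction is used.
#'
#' @param a,b Numeric vectors, each with at least 2 non-missing observations.
#' @inheritParams spearman_test
#' @return A one-row tibble; `statistic` is U for the first sample.
#' @examples
#' mann_whitney_test(c(1, 2), c(3, 4))
#' @export
mann_whitney_test <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("insufficient data: each group needs at least 2 observations",
          class = "pathmod_insufficient_data")
  }
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && n <= 20
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  pm_test_result(unname(ht$statistic), ht$p.value,
                 if (exact) "exact" else "normal_approx", n, alternative)
}

#' One-sided hypergeometric enrichment test
#'
#' Probability that an overlap at least as large as the one observed between
#' a module and a gene set occurs by chance when drawing the module from the
#' universe (Fisher's exact test, over-enrichment tail):
#' `P(X >= overlap)` for `X` hypergeometric.
#'
#' @param overlap Genes in both the module and the set.
#' @param set_only Genes in the set but not the module.
#' @param module_only Genes in the module but not the set.
#' @param neither Universe genes in neither.
#' @return A one-row tibble; `statistic` is the observed overlap.
#' @examples
#' fisher_enrichment(overlap = 10, set_only = 0, module_only = 0, neither = 90)
#' @export
fisher_enrichment <- function(overlap, set_only, module_only, neither) {
  counts <- c(overlap, set_only, module_only, neither)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("inconsistent universe: contingency counts must be non-negative integers",
          class = "pathmod_inconsistent_universe")
  }
  universe <- sum(counts)
  set_size <- overlap + set_only
  module_size <- overlap + module_only
  if (universe < set_size || universe < module_size) {
    abort("inconsistent universe", class = "pathmod_inconsistent_universe")
  }
  p <- phyper(overlap - 1, m = set_size, n = universe - set_size,
              k = module_size, lower.tail = FALSE)
  pm_test_result(overlap, p, "exact", universe, "greater")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, capped at 1. Returned values are
#' monotone non-decreasing when sorted by raw p.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "pathmod_bad_pvalues")
  }
  p.adjust(p, method = "BH")
}

#' Principal components of a samples-by-features matrix
#'
#' Column-centres the matrix and projects samples onto the `k` leading
#' eigenvectors of the feature covariance. The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making scores
#' reproducible across platforms. If `k` exceeds the matrix rank the
#' available components are returned with a warning.
#'
#' @param m Numeric matrix, samples in rows.
#' @param k Number of components requested (0 allowed).
#' @return List with `scores` (samples x k'), `variance_fractions`
#'   (non-increasing, length k') and `rotation` (features x k').
#' @export
principal_components <- function(m, k) {
  m <- as.matrix(m)
  stopifnot(k >= 0)
  if (k == 0) {
    return(list(scores = matrix(0, nrow(m), 0),
                variance_fractions = numeric(0),
                rotation = matrix(0, ncol(m), 0)))
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  tol <- pc$sdev[1] * 1e-8
  rank <- sum(pc$sdev > tol)
  avail <- min(k, rank, ncol(pc$x))
  if (avail < k) {
    warn(sprintf("rank deficient: %d components requested, %d available",
                 k, avail))
  }
  idx <- seq_len(avail)
  scores <- pc$x[, idx, drop = FALSE]
  rotation <- pc$rotation[, idx, drop = FALSE]
  for (j in idx) {
    top <- which.max(abs(rotation[, j]))
    if (rotation[top, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       variance_fractions = (pc$sdev^2 / sum(pc$sdev^2))[idx],
       rotation = rotation)
}
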