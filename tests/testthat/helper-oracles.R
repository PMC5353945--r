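# Brute-force oracles, independent of the implementation paths they check.

# all permutations of 1..n (n small)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# two-sided permutation p for the midrank correlation
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- oracle_perms(length(y))
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# U statistic of sample a
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# exact two-sided Mann-Whitney p by enumeration of all labelings
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  labelings <- utils::combn(n, length(a))
  us <- apply(labelings, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  obs <- oracle_u(a, b)
  lo <- mean(us <= obs + 1e-12)
  hi <- mean(us >= obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# hypergeometric upper tail by explicit point-mass summation
oracle_hyper_tail <- function(overlap, set_size, module_size, universe) {
  ks <- overlap:min(set_size, module_size)
  sum(stats::dhyper(ks, set_size, universe - set_size, module_size))
}

# triple-loop topological overlap from a correlation matrix
oracle_tom <- function(cc, beta) {
  a <- abs(cc)^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(cc)
  tom
}

# maximised binomial log-likelihood for label ~ x by direct optimisation
oracle_logistic_lrt <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  full <- stats::optim(c(0, 0), nll, method = "BFGS")$value
  null <- stats::optimize(function(b0) nll(c(b0, 0)), c(-20, 20))$objective
  2 * (null - full)
}
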