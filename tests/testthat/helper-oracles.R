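# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Hardy-Weinberg exact test by direct enumeration of the conditional
# heterozygote distribution (log-gamma arithmetic, no recurrence).
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- vapply(hets, function(h) {
    ra <- (na - h) / 2
    rb <- n - h - ra
    lgamma(n + 1) - lgamma(ra + 1) - lgamma(h + 1) - lgamma(rb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Brute-force OLS by explicit normal equations.
normal_equations_oracle <- function(y, X) {
  X <- as.matrix(X)
  XtX <- t(X) %*% X
  beta <- solve(XtX) %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tt <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# Draw n observations from a 3-variable standard MVN with the given
# correlation matrix (Cholesky; base R only).
rmvn3 <- function(n, R) {
  L <- chol(R)
  matrix(rnorm(n * 3), n, 3) %*% L
}

# A small complete default cohort for quick end-to-end checks.
quick_cohort <- function(seed = 1, n = 379, m_null = 20, ...) {
  simulate_cohort(sim_config(n_samples = n, n_null_variants = m_null,
                             missing_rate = 0, seed = seed, ...))
}

with_seed_runif <- function(seed, n, lo, hi) {
  set.seed(seed)
  runif(n, lo, hi)
}

covariates_of <- function(pheno) {
  build_covariate_matrix(pheno, c("age", "gender", "batch"))
}
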