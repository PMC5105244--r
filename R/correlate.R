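#' Pearson correlation on complete pairs
#'
#' @param x,y Numeric vectors of equal length; pairs with any missing value
#'   are dropped.
#' @return List with `r`, `p` (two-sided, from t = r sqrt(n-2)/sqrt(1-r²)),
#'   and `n` (complete pairs).
#' @export
pearson_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector on complete pairs", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Fisher z-transform of a correlation
#'
#' @param r Correlation(s) with |r| < 1.
#' @return `0.5 * log((1 + r) / (1 - r))`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1", call. = FALSE)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Meng Z-test for two dependent overlapping correlations
#'
#' Compares `r_jk` (target vs. variable k) with `r_jh` (target vs. variable
#' h) when k and h are themselves correlated (`r_kh`) and all three are
#' measured on the same `n` subjects. Following Meng, Rosenthal & Rubin:
#' \deqn{\bar r^2 = (r_{jk}^2 + r_{jh}^2)/2, \quad
#'       f = \min\left(1, \frac{1 - r_{kh}}{2(1 - \bar r^2)}\right), \quad
#'       h = \frac{1 - f \bar r^2}{1 - \bar r^2},}
#' \deqn{Z = (z_{jk} - z_{jh})\sqrt{\frac{n - 3}{2(1 - r_{kh})h}},}
#' with z the Fisher transforms, a standard-normal two-sided p, and the 95%
#' confidence interval reported on the Fisher-z difference scale. The null
#' (equal correlations) is retained iff the interval contains 0.
#'
#' @param r_jk,r_jh,r_kh The three correlations (|r| < 1, jointly forming a
#'   positive semidefinite correlation matrix).
#' @param n Common number of complete cases (>= 4).
#' @param conf_level Confidence level for the interval.
#' @return A list of class `correlation_comparison`: the three correlations,
#'   `n`, `z_jk`, `z_jh`, `Z`, `p`, `ci_low`, `ci_high`, `decision`
#'   (`"retain"`/`"reject"`).
#' @export
meng_test <- function(r_jk, r_jh, r_kh, n, conf_level = 0.95) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || abs(r_jk) >= 1 || abs(r_jh) >= 1 || abs(r_kh) > 1) {
    stop("correlations must be finite with |r_jk|, |r_jh| < 1 and |r_kh| <= 1",
         call. = FALSE)
  }
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("impossible correlation structure: triple is not positive semidefinite",
         call. = FALSE)
  }
  z_jk <- fisher_z(r_jk)
  z_jh <- fisher_z(r_jh)
  rbar2 <- (r_jk^2 + r_jh^2) / 2
  f <- min(1, (1 - r_kh) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  sd_diff <- sqrt(2 * (1 - r_kh) * h / (n - 3))
  diff <- z_jk - z_jh
  # r_kh = 1 collapses the null variance; only a zero difference is coherent
  # there (a nonzero one would have failed the PSD check above)
  Z <- if (sd_diff == 0) 0 else diff / sd_diff
  p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- diff + c(-1, 1) * q * sd_diff
  structure(
    list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n,
         z_jk = z_jk, z_jh = z_jh, Z = Z, p = p,
         ci_low = ci[1], ci_high = ci[2],
         decision = if (ci[1] <= 0 && ci[2] >= 0) "retain" else "reject"),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "<correlation_comparison> n = %d\n  r(target, unadjusted) = %.3f\n  r(target, adjusted)   = %.3f\n  r(unadj, adj)         = %.3f\n  Meng Z = %.3f, p = %.3g, 95%% CI [%.3f, %.3f] -> %s\n",
    x$n, x$r_jk, x$r_jh, x$r_kh, x$Z, x$p, x$ci_low, x$ci_high, x$decision))
  invisible(x)
}

#' Compare a target analyte's correlation with a biomarker before vs after
#' genetic adjustment
#'
#' Computes the three Pearson correlations (target vs unadjusted, target vs
#' adjusted, unadjusted vs adjusted) on the common complete-case set — one
#' `n` for the whole triple, as the Meng formula assumes — then runs
#' [meng_test()].
#'
#' @param pheno_table Data frame holding all three columns.
#' @param biomarker_col Unadjusted biomarker column (log-standardized
#'   internally if `log_transform = TRUE`).
#' @param adjusted_col Genetically adjusted biomarker column.
#' @param target_col Target analyte column (log-standardized internally if
#'   `log_transform = TRUE`).
#' @param log_transform Log-standardize the raw biomarker and target before
#'   correlating (the adjusted column is already on the residual scale)?
#' @return A `correlation_comparison` (see [meng_test()]) with the pairwise
#'   correlations additionally carrying their own two-sided p-values in
#'   `p_jk`, `p_jh`.
#' @export
compare_adjusted <- function(pheno_table, biomarker_col, adjusted_col,
                             target_col, log_transform = TRUE) {
  cols <- c(biomarker_col, adjusted_col, target_col)
  miss <- setdiff(cols, names(pheno_table))
  if (length(miss)) {
    stop("columns not found: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bio <- pheno_table[[biomarker_col]]
  adj <- pheno_table[[adjusted_col]]
  tgt <- pheno_table[[target_col]]
  if (log_transform) {
    bio <- log_standardize(bio)
    tgt <- log_standardize(tgt)
  }
  keep <- !is.na(bio) & !is.na(adj) & !is.na(tgt)
  n <- sum(keep)
  if (n < 4) stop("need >= 4 common complete cases", call. = FALSE)
  bio <- bio[keep]; adj <- adj[keep]; tgt <- tgt[keep]
  c_jk <- pearson_cor(tgt, bio)
  c_jh <- pearson_cor(tgt, adj)
  c_kh <- pearson_cor(bio, adj)
  out <- meng_test(c_jk$r, c_jh$r, c_kh$r, n)
  out$p_jk <- c_jk$p
  out$p_jh <- c_jh$p
  out
}
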