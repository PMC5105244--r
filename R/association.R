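#' Ordinary least squares with inference
#'
#' QR-based least squares with coefficient standard errors, t statistics,
#' two-sided p-values from the t distribution, residuals, leverages and R².
#' Serves every regression in the pipeline (covariate screens, per-variant
#' association, variance decomposition, genetic adjustment).
#'
#' @param y Numeric response vector (no missing values).
#' @param X Design matrix including the intercept column.
#' @return A list of class `ols_fit` with `coefficients`, `se`, `t`, `p`,
#'   `residuals`, `fitted`, `leverage`, `sigma2`, `r_squared`, `n`, `df`.
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (anyNA(y) || anyNA(X)) stop("fit_ols requires complete cases", call. = FALSE)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (n <= p) stop("need more observations than predictors", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  Q <- qr.Q(qx)
  lev <- rowSums(Q^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(
    list(coefficients = beta, se = se, t = tval, p = pval,
         residuals = res, fitted = fitted, leverage = lev,
         sigma2 = sigma2, r_squared = r2, n = n, df = df),
    class = "ols_fit"
  )
}

#' Per-variant additive-model GWAS
#'
#' Regresses a (log-standardized) phenotype on each variant's allele count
#' plus covariates, one ordinary-least-squares fit per variant on that
#' variant's complete cases. Variants with no missing calls are fit through
#' an exact residualization shortcut (projecting phenotype and genotypes off
#' the covariates once), algebraically identical to the full per-variant
#' regression; variants with missing calls are fit individually.
#'
#' @param G A [genotype_matrix()] (QC-passed).
#' @param pheno Numeric phenotype vector aligned with `G`'s samples, already
#'   log-transformed and standardized.
#' @param covariates Numeric matrix of covariate columns (no intercept;
#'   one is added internally), or `NULL` for none.
#' @param sort_by_p Return rows sorted by ascending p (ties broken by
#'   chromosome then position)? Default keeps input order.
#' @return An `association_table` data frame with columns CHR, POS, ID, A1
#'   (counted allele), A1_FREQ, N, BETA, SE, T, P, CLASS, REASON. Variants
#'   monomorphic within their complete cases get NA statistics and a reason
#'   code instead of being dropped.
#' @export
run_gwas <- function(G, pheno, covariates = NULL, sort_by_p = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$counts)
  pheno <- as.numeric(pheno)
  if (length(pheno) != n) stop("phenotype length must match sample count", call. = FALSE)
  if (anyNA(pheno)) stop("phenotype must be complete; subset samples first", call. = FALSE)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates)) stop("covariates must be complete", call. = FALSE)
    X0 <- cbind(X0, covariates)
  }
  p0 <- ncol(X0)
  m <- ncol(G$counts)
  beta <- se <- tval <- pval <- freq <- rep(NA_real_, m)
  nn <- integer(m)
  reason <- rep("", m)

  cnt <- G$counts * 1.0
  has_na <- colSums(is.na(cnt)) > 0L
  mono <- function(g) length(unique(g)) < 2L

  # fast exact path: complete variants, shared covariate projection
  idx_fast <- which(!has_na)
  if (length(idx_fast)) {
    qx <- qr(X0)
    if (qx$rank < p0) stop("singular covariate design", call. = FALSE)
    Q <- qr.Q(qx)
    yres <- pheno - Q %*% crossprod(Q, pheno)
    Gf <- cnt[, idx_fast, drop = FALSE]
    Gres <- Gf - Q %*% crossprod(Q, Gf)
    gg <- colSums(Gres^2)
    gy <- drop(crossprod(Gres, yres))
    yy <- sum(yres^2)
    ok <- gg > 1e-10
    df <- n - p0 - 1L
    b <- ifelse(ok, gy / gg, NA_real_)
    rss <- yy - b^2 * gg
    s2 <- rss / df
    sef <- sqrt(s2 / gg)
    tf <- b / sef
    pf <- 2 * stats::pt(abs(tf), df, lower.tail = FALSE)
    beta[idx_fast] <- ifelse(ok, b, NA_real_)
    se[idx_fast] <- ifelse(ok, sef, NA_real_)
    tval[idx_fast] <- ifelse(ok, tf, NA_real_)
    pval[idx_fast] <- ifelse(ok, pf, NA_real_)
    freq[idx_fast] <- colMeans(Gf) / 2
    nn[idx_fast] <- n
    reason[idx_fast[!ok]] <- "monomorphic"
  }

  # per-variant complete-case path for variants with missing calls
  for (j in which(has_na)) {
    g <- cnt[, j]
    keep <- !is.na(g)
    nj <- sum(keep)
    nn[j] <- nj
    if (nj < p0 + 2L) { reason[j] <- "insufficient_n"; next }
    gk <- g[keep]
    freq[j] <- mean(gk) / 2
    if (mono(gk)) { reason[j] <- "monomorphic"; next }
    fit <- fit_ols(pheno[keep], cbind(X0[keep, , drop = FALSE], G = gk))
    k <- length(fit$coefficients)
    beta[j] <- fit$coefficients[k]
    se[j] <- fit$se[k]
    tval[j] <- fit$t[k]
    pval[j] <- fit$p[k]
  }

  cls <- rep(NA_character_, m)
  okp <- !is.na(pval)
  cls[okp] <- classify_significance(pmax(pval[okp], 1e-320))
  out <- data.frame(
    CHR = G$variants$chrom, POS = G$variants$pos, ID = G$variants$id,
    A1 = G$variants$counted, A1_FREQ = freq, N = nn,
    BETA = beta, SE = se, T = tval, P = pval,
    CLASS = cls, REASON = reason,
    stringsAsFactors = FALSE
  )
  if (sort_by_p) {
    out <- out[order(out$P, out$CHR, out$POS, na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("association_table", "data.frame")
  out
}

#' Conditional association analysis
#'
#' Re-runs the per-variant GWAS with the allele counts of an index variant
#' appended to the covariates; the index variant itself is reported with NA
#' statistics and reason `"conditioned_on"`. Samples missing the index
#' genotype are dropped from the conditional analysis.
#'
#' @inheritParams run_gwas
#' @param index_variant_id Id of the variant to condition on.
#' @return An `association_table` (see [run_gwas()]).
#' @export
conditional_analysis <- function(G, pheno, covariates = NULL, index_variant_id,
                                 sort_by_p = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  j <- match(index_variant_id, G$variants$id)
  if (is.na(j)) {
    stop("unknown index variant '", index_variant_id, "'; available: ",
         paste(utils::head(G$variants$id, 20), collapse = ", "),
         if (ncol(G$counts) > 20) ", ..." else "", call. = FALSE)
  }
  g_idx <- G$counts[, j]
  keep <- !is.na(g_idx)
  covariates <- if (is.null(covariates)) {
    matrix(g_idx[keep], ncol = 1, dimnames = list(NULL, "index_variant"))
  } else {
    cbind(as.matrix(covariates)[keep, , drop = FALSE],
          index_variant = g_idx[keep])
  }
  Gk <- subset_genotypes(G, samples = which(keep))
  out <- run_gwas(Gk, pheno[keep], covariates, sort_by_p = FALSE)
  at <- match(index_variant_id, out$ID)
  out[at, c("BETA", "SE", "T", "P")] <- NA_real_
  out$CLASS[at] <- NA_character_
  out$REASON[at] <- "conditioned_on"
  if (sort_by_p) {
    out <- out[order(out$P, out$CHR, out$POS, na.last = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square quantiles of the p-values divided
#' by 0.4549364 (the median of a central chi-square with 1 df). Values near 1
#' indicate calibrated association tests with no residual stratification.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied", call. = FALSE)
  stopifnot_prob(p_values, "p_values")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Classify association p-values
#'
#' `"genome-wide"` for p < 5e-8, `"suggestive"` for 5e-8 <= p < 1e-5,
#' `"ns"` otherwise — the conventional single-variant thresholds.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Character vector of classes.
#' @export
classify_significance <- function(p) {
  stopifnot_prob(p, "p")
  ifelse(p < 5e-8, "genome-wide", ifelse(p < 1e-5, "suggestive", "ns"))
}
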