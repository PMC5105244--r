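#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression fit by iteratively reweighted
#' least squares (via `stats::glm.fit`), with Wald z statistics and
#' two-sided normal p-values. Complete or quasi-complete separation is
#' surfaced as an explicit error rather than silently returned divergent
#' coefficients.
#'
#' @param y Binary 0/1 response; both classes must be present.
#' @param X Design matrix including the intercept column.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `logistic_fit`: `coefficients` (log-odds scale),
#'   `se`, `z`, `p`, `n`, `deviance`, `converged`, `iterations`,
#'   `max_score` (largest absolute score-equation residual).
#' @export
fit_logistic <- function(y, X, max_iter = 50L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  n <- length(y)
  if (n <= ncol(X)) stop("need more observations than predictors", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("fit_logistic requires complete cases", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = max_iter))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # separation: fitted probabilities pinned to 0/1 with diverging coefficients
  eps <- 1e-8
  pinned <- (mu < eps & y == 0) | (mu > 1 - eps & y == 1)
  if ((any(mu < eps | mu > 1 - eps) && max(abs(beta)) > 12) ||
      (!fit$converged && max(abs(beta)) > 12)) {
    stop("complete or quasi-complete separation detected; ",
         "coefficient estimates diverge", call. = FALSE)
  }
  if (!fit$converged) {
    stop("IRLS failed to converge in ", max_iter, " iterations", call. = FALSE)
  }
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  cov_beta <- chol2inv(chol(XtWX))
  se <- sqrt(diag(cov_beta))
  names(se) <- colnames(X)
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  score <- drop(crossprod(X, y - mu))
  structure(
    list(coefficients = beta, se = se, z = z, p = p, n = n,
         deviance = fit$deviance, converged = fit$converged,
         iterations = fit$iter, max_score = max(abs(score)),
         pinned = sum(pinned)),
    class = "logistic_fit"
  )
}

#' Case/control association of a biomarker
#'
#' Logistic regression of case/control status on the (log-standardized by
#' default) analyte plus covariates — the test of whether cases have
#' elevated biomarker levels after accounting for age, gender and batch.
#'
#' @param pheno_table Phenotype data frame with a 0/1 `status` column.
#' @param analyte_col Analyte column to test (raw positive levels, or an
#'   already-adjusted column with `log_transform = FALSE`).
#' @param covariate_cols Character vector of covariate column names
#'   (categorical columns such as `batch` are expanded to indicators).
#' @param log_transform Log-standardize the analyte first? Default `TRUE`.
#' @param status_col Name of the status column.
#' @return A `logistic_fit` (see [fit_logistic()]) with an extra element
#'   `analyte` naming the tested column; the analyte's coefficient is named
#'   `"analyte"` in the coefficient vector.
#' @export
test_status_association <- function(pheno_table, analyte_col,
                                    covariate_cols = c("age", "gender", "batch"),
                                    log_transform = TRUE,
                                    status_col = "status") {
  if (!status_col %in% names(pheno_table)) {
    stop("status column '", status_col, "' not found", call. = FALSE)
  }
  x <- pheno_table[[analyte_col]]
  if (log_transform) x <- log_standardize(x)
  covs <- build_covariate_matrix(pheno_table, covariate_cols)
  y <- pheno_table[[status_col]]
  keep <- !is.na(x) & !is.na(y) & stats::complete.cases(covs)
  X <- cbind(`(Intercept)` = 1, analyte = x[keep], covs[keep, , drop = FALSE])
  out <- fit_logistic(y[keep], X)
  out$analyte <- analyte_col
  out
}

#' Expand phenotype-table covariates to a numeric design
#'
#' `batch` (or any non-numeric/categorical column with few levels) becomes
#' 0/1 indicator columns with the first level as reference; numeric columns
#' pass through.
#'
#' @param pheno_table Phenotype data frame.
#' @param covariate_cols Character vector of column names.
#' @param extra Optional extra numeric matrix (e.g. principal-component
#'   scores) bound onto the result.
#' @return Numeric matrix with one row per sample.
#' @export
build_covariate_matrix <- function(pheno_table, covariate_cols, extra = NULL) {
  cols <- lapply(covariate_cols, function(cc) {
    if (!cc %in% names(pheno_table)) {
      stop("covariate column '", cc, "' not found", call. = FALSE)
    }
    v <- pheno_table[[cc]]
    if (cc == "batch" || is.factor(v) || is.character(v)) {
      f <- factor(v)
      if (nlevels(f) < 2L) return(NULL)     # single batch: nothing to encode
      m <- vapply(levels(f)[-1], function(l) as.numeric(f == l),
                  numeric(length(f)))       # NA propagates, rows stay aligned
      colnames(m) <- paste0(cc, levels(f)[-1])
      m
    } else {
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cc))
    }
  })
  cols <- Filter(Negate(is.null), cols)
  if (!length(cols) && is.null(extra)) {
    return(matrix(numeric(0), nrow = nrow(pheno_table), ncol = 0))
  }
  out <- do.call(cbind, cols)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}
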