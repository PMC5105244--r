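#' Log-transform and standardize an analyte
#'
#' Natural log, then centered and scaled to unit sample standard deviation
#' (n - 1 denominator) over the non-missing values. Missing values propagate.
#'
#' @param values Positive numeric vector (NA allowed).
#' @return Numeric vector with mean 0 and SD 1 over non-missing entries.
#' @export
log_standardize <- function(values) {
  ok <- !is.na(values)
  if (any(values[ok] <= 0)) {
    bad <- which(!is.na(values) & values <= 0)
    stop("non-positive analyte values at positions: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  lv <- log(values)
  s <- stats::sd(lv[ok])
  if (!is.finite(s) || s == 0) {
    stop("analyte is constant on the log scale; cannot standardize", call. = FALSE)
  }
  (lv - mean(lv[ok])) / s
}

#' Shapiro-Wilk normality check
#'
#' Advisory normality diagnostic for the transformed analyte; never gates
#' the pipeline.
#'
#' @param values Numeric vector, 3 <= n <= 5000 non-missing values.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk supports 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Variance explained by covariates and by a variant
#'
#' Nested-model R² decomposition: the covariate-only R², and the increment
#' (delta R²) from adding the variant's allele counts — the fraction of
#' phenotype variance the locus explains over and above the covariates.
#'
#' @param pheno Log-standardized phenotype vector.
#' @param variant_counts Allele counts aligned with `pheno`.
#' @param covariates Covariate matrix (no intercept), or `NULL`.
#' @return List with `r2_covariates`, `r2_variant` (both >= 0), and `n`
#'   (complete cases used).
#' @export
variance_explained <- function(pheno, variant_counts, covariates = NULL) {
  n0 <- length(pheno)
  keep <- !is.na(pheno) & !is.na(variant_counts)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  y <- pheno[keep]
  g <- variant_counts[keep]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  fit0 <- fit_ols(y, X0)
  r2_cov <- fit0$r_squared
  if (length(unique(g)) < 2L) {
    r2_var <- 0
  } else {
    fit1 <- fit_ols(y, cbind(X0, G = g))
    r2_var <- max(0, fit1$r_squared - r2_cov)
  }
  list(r2_covariates = r2_cov, r2_variant = r2_var, n = n)
}

#' Genetically residualize a phenotype via studentized residuals
#'
#' Regresses the log-standardized phenotype on an intercept and the allele
#' counts of a single variant and returns studentized residuals — the
#' genetically adjusted phenotype. Externally studentized residuals
#' (leave-one-out variance, `e_i / (s_(i) sqrt(1 - h_ii))`) are the default;
#' internal studentization is available via `method`.
#'
#' @param pheno Log-standardized phenotype vector (NA allowed).
#' @param variant_counts Allele counts aligned with `pheno` (NA allowed).
#' @param method `"external"` (default) or `"internal"` studentization.
#' @return Numeric vector of adjusted values; NA where phenotype or genotype
#'   is missing.
#' @export
genetic_adjust <- function(pheno, variant_counts,
                           method = c("external", "internal")) {
  method <- match.arg(method)
  keep <- !is.na(pheno) & !is.na(variant_counts)
  n <- sum(keep)
  if (n < 10) stop("need >= 10 complete cases to adjust", call. = FALSE)
  g <- variant_counts[keep]
  if (length(unique(g)) < 2L) {
    stop("variant is monomorphic among complete cases; nothing to adjust",
         call. = FALSE)
  }
  fit <- fit_ols(pheno[keep], cbind(`(Intercept)` = rep(1, n), G = g))
  e <- fit$residuals
  h <- fit$leverage
  p <- 2L
  if (method == "external") {
    # leave-one-out variance: s_(i)^2 = (RSS - e_i^2/(1-h_i)) / (n - p - 1)
    s2i <- (fit$sigma2 * fit$df - e^2 / (1 - h)) / (fit$df - 1)
    stud <- e / sqrt(s2i * (1 - h))
  } else {
    stud <- e / sqrt(fit$sigma2 * (1 - h))
  }
  out <- rep(NA_real_, length(pheno))
  out[keep] <- stud
  out
}

#' Build the adjusted-phenotype record for a biomarker and top variant
#'
#' Convenience wrapper combining [log_standardize()], [variance_explained()]
#' and [genetic_adjust()] into the full adjusted-phenotype bundle, and
#' appending the adjusted column to the phenotype table as
#' `<analyte>_adj_<variant id>`.
#'
#' @param pheno_table Phenotype data frame with a `sample_id` column.
#' @param G A [genotype_matrix()] covering the same samples.
#' @param analyte Name of the analyte column to adjust.
#' @param variant_id Id of the adjusting variant (the GWAS top hit).
#' @param covariates Optional covariate matrix for the variance
#'   decomposition (the adjustment regression itself uses only intercept +
#'   allele counts).
#' @param method Studentization method, see [genetic_adjust()].
#' @return A list of class `adjusted_phenotype`: `sample_ids`, `raw`,
#'   `log_standardized`, `adjusted`, `top_variant_id`, `r2_covariates`,
#'   `r2_variant`, `column_name`, and `pheno_table` (input table plus the
#'   new adjusted column).
#' @export
adjust_biomarker <- function(pheno_table, G, analyte, variant_id,
                             covariates = NULL,
                             method = c("external", "internal")) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!analyte %in% names(pheno_table)) {
    stop("analyte column '", analyte, "' not found", call. = FALSE)
  }
  j <- match(variant_id, G$variants$id)
  if (is.na(j)) stop("variant '", variant_id, "' not in genotype matrix", call. = FALSE)
  idx <- match(pheno_table$sample_id, G$sample_ids)
  if (anyNA(idx)) stop("phenotype samples missing from genotype matrix", call. = FALSE)
  g <- G$counts[idx, j]
  raw <- pheno_table[[analyte]]
  ls <- log_standardize(raw)
  adj <- genetic_adjust(ls, g, method = method)
  ve <- variance_explained(ls, g, covariates)
  col <- paste0(analyte, "_adj_", variant_id)
  pheno_table[[col]] <- adj
  structure(
    list(sample_ids = pheno_table$sample_id, raw = raw,
         log_standardized = ls, adjusted = adj,
         top_variant_id = variant_id,
         r2_covariates = ve$r2_covariates, r2_variant = ve$r2_variant,
         column_name = col, pheno_table = pheno_table),
    class = "adjusted_phenotype"
  )
}
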