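#' Simulation configuration for synthetic biomarker-GWAS cohorts
#'
#' Bundles and validates the generative parameters for [simulate_cohort()].
#' The defaults emulate a CSF biomarker cohort of 379 individuals in which a
#' single causal variant (MAF 0.244) explains 12.74% of the variance of the
#' log biomarker, age/gender/batch jointly explain 14.89%, a shared latent
#' factor induces a biomarker-ptau181 correlation of 0.52 (with the genetic
#' component independent of ptau), and 21.11% of participants are cases whose
#' log biomarker is shifted upward by 0.7 standard deviations.
#'
#' @param n_samples Number of individuals.
#' @param n_null_variants Number of non-causal variants drawn under
#'   Hardy-Weinberg proportions.
#' @param causal_maf Minor (= counted alt) allele frequency of the causal
#'   variant, in (0, 0.5].
#' @param null_maf_range Length-2 vector, lower/upper bound of the uniform
#'   MAF distribution for null variants; lower bound must be >= 0.02 so a
#'   null cohort clears the standard MAF filter.
#' @param target_snp_r2 Fraction of log-biomarker variance explained by the
#'   causal variant, in \[0, 1).
#' @param covariate_r2 Fraction explained jointly by age, gender and batch.
#' @param latent_corr Target correlation between log biomarker and log
#'   ptau181 induced by the shared latent factor, in (-1, 1).
#' @param case_fraction Fraction of cases, in \[0, 1).
#' @param case_shift Standardized mean shift of the log biomarker in cases.
#' @param n_batches Number of assay/genotyping batches.
#' @param missing_rate Per-genotype missing-call rate, in \[0, 1).
#' @param seed Mandatory integer seed; identical config + seed gives
#'   byte-identical cohorts.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 379L,
                       n_null_variants = 1000L,
                       causal_maf = 0.244,
                       null_maf_range = c(0.05, 0.5),
                       target_snp_r2 = 0.1274,
                       covariate_r2 = 0.1489,
                       latent_corr = 0.52,
                       case_fraction = 0.2111,
                       case_shift = 0.7,
                       n_batches = 2L,
                       missing_rate = 0.002,
                       seed = NULL) {
  if (is.null(seed)) stop("`seed` is mandatory in the simulation config", call. = FALSE)
  cfg <- list(n_samples = as.integer(n_samples),
              n_null_variants = as.integer(n_null_variants),
              causal_maf = causal_maf,
              null_maf_range = as.numeric(null_maf_range),
              target_snp_r2 = target_snp_r2,
              covariate_r2 = covariate_r2,
              latent_corr = latent_corr,
              case_fraction = case_fraction,
              case_shift = case_shift,
              n_batches = as.integer(n_batches),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$n_samples >= 2, "n_samples must be >= 2")
  chk(cfg$n_null_variants >= 0, "n_null_variants must be >= 0")
  chk(is.finite(cfg$causal_maf) && cfg$causal_maf > 0 && cfg$causal_maf <= 0.5,
      "causal_maf must lie in (0, 0.5]")
  chk(length(cfg$null_maf_range) == 2 &&
        all(is.finite(cfg$null_maf_range)) &&
        cfg$null_maf_range[1] > 0 && cfg$null_maf_range[2] <= 0.5 &&
        cfg$null_maf_range[1] <= cfg$null_maf_range[2],
      "null_maf_range must be increasing within (0, 0.5]")
  chk(cfg$target_snp_r2 >= 0 && cfg$target_snp_r2 < 1,
      "target_snp_r2 must lie in [0, 1)")
  chk(cfg$covariate_r2 >= 0 && cfg$covariate_r2 < 1,
      "covariate_r2 must lie in [0, 1)")
  chk(cfg$target_snp_r2 + cfg$covariate_r2 < 1,
      "target_snp_r2 + covariate_r2 must be < 1")
  chk(abs(cfg$latent_corr) < 1, "latent_corr must lie in (-1, 1)")
  chk(cfg$case_fraction >= 0 && cfg$case_fraction < 1,
      "case_fraction must lie in [0, 1)")
  chk(cfg$n_batches >= 1, "n_batches must be >= 1")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate must lie in [0, 1)")
  # full variance budget: covariates + SNP + latent + case shift must leave
  # strictly positive residual noise on the unit-variance log scale
  if (noise_variance(cfg) <= 0) {
    stop("inconsistent variance budget: configured fractions sum to >= 1",
         call. = FALSE)
  }
  invisible(cfg)
}

noise_variance <- function(cfg) {
  1 - cfg$target_snp_r2 - cfg$covariate_r2 - abs(cfg$latent_corr) -
    cfg$case_shift^2 * cfg$case_fraction * (1 - cfg$case_fraction)
}

#' Read a simulation config from a YAML key-value file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()]. `seed` must be present.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Simulate unlinked genotypes under Hardy-Weinberg proportions
#'
#' Each variant's genotype is the sum of two independent allele draws at its
#' alt-allele frequency, so genotype classes follow p^2 / 2pq / q^2 exactly in
#' expectation. The counted allele is the alt allele.
#'
#' @param n_samples Number of individuals.
#' @param mafs Vector of alt-allele frequencies, each in (0, 0.5].
#' @param missing_rate Fraction of calls masked to missing, in \[0, 1).
#' @param seed Integer seed.
#' @param variant_meta Optional metadata data frame (as in
#'   [genotype_matrix()]); autogenerated when `NULL`.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, mafs, missing_rate = 0, seed,
                               variant_meta = NULL) {
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5)) {
    stop("all MAFs must be finite and in (0, 0.5]", call. = FALSE)
  }
  if (!is.finite(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  m <- length(mafs)
  with_seed(seed, {
    cnt <- matrix(
      stats::rbinom(n_samples * m, size = 2L,
                    prob = rep(mafs, each = n_samples)),
      nrow = n_samples, ncol = m
    )
    if (missing_rate > 0) {
      cnt[stats::runif(n_samples * m) < missing_rate] <- NA_integer_
    }
    if (is.null(variant_meta)) {
      variant_meta <- data.frame(
        chrom = as.character(1L + (seq_len(m) - 1L) %% 22L),
        pos = 10000L + 137L * seq_len(m),
        id = sprintf("snp%05d", seq_len(m)),
        ref = "A", alt = "G", counted = "G",
        stringsAsFactors = FALSE
      )
    }
    genotype_matrix(cnt, variant_meta,
                    sample_ids = sprintf("S%04d", seq_len(n_samples)))
  })
}

#' Allele-count effect size for a target variance fraction
#'
#' Returns the per-allele effect beta such that a Hardy-Weinberg variant with
#' the given MAF explains `target_r2` of total phenotype variance when the
#' remaining (non-genetic) variance is `residual_sd^2`:
#' beta^2 2p(1-p) / (beta^2 2p(1-p) + residual_sd^2) = target_r2.
#'
#' @param target_r2 Variance fraction in \[0, 1).
#' @param maf Allele frequency in (0, 0.5].
#' @param residual_sd Standard deviation of the non-genetic remainder.
#' @return The (nonnegative) effect size per counted-allele copy.
#' @export
solve_effect_size <- function(target_r2, maf, residual_sd = 1) {
  if (!is.finite(target_r2) || target_r2 < 0 || target_r2 >= 1) {
    stop("target_r2 must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(maf) || maf <= 0 || maf > 0.5) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  if (!is.finite(residual_sd) || residual_sd < 0) {
    stop("residual_sd must be nonnegative", call. = FALSE)
  }
  var_g <- 2 * maf * (1 - maf)
  residual_sd * sqrt(target_r2 / (1 - target_r2) / var_g)
}

#' Simulate a genotype + phenotype cohort
#'
#' Generates a cohort under the structural model
#' \deqn{Z = \text{covariates} + \beta_g (G - 2p) + \gamma L +
#'       s\,(\text{status} - q) + \epsilon,}
#' where `Z` is the standardized log biomarker, `G` the causal allele count,
#' `L` a standard-normal latent factor shared with ptau181 and tau (but not
#' with the genotype or with abeta42), and `status` a Bernoulli case
#' indicator. Analytes are generated on the log scale and exponentiated, so
#' log-transformation downstream exactly linearizes them. The ratio column
#' `tau_abeta_ratio` is tau/abeta42.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]; causal
#'   variant first, id `"snp_causal"`), `phenotypes` (a data frame with
#'   columns sample_id, ykl40, ptau181, tau, abeta42, tau_abeta_ratio, age,
#'   gender, batch, status), and `truth` (the generative parameters actually
#'   used: causal id, beta, noise variance).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_samples
  sig2_eps <- noise_variance(config)

  with_seed(config$seed, {
    # --- genotypes: causal variant first, then HWE null variants ---
    mafs <- c(config$causal_maf,
              if (config$n_null_variants > 0)
                stats::runif(config$n_null_variants,
                             config$null_maf_range[1], config$null_maf_range[2]))
    m <- length(mafs)
    meta <- data.frame(
      chrom = c("1", as.character(1L + (seq_len(m - 1L)) %% 22L)[seq_len(m - 1L)]),
      pos = c(2003156L, 10000L + 137L * seq_len(m - 1L)),
      id = c("snp_causal", sprintf("snp%05d", seq_len(m - 1L))),
      ref = "A", alt = "G", counted = "G",
      stringsAsFactors = FALSE
    )[seq_len(m), , drop = FALSE]
    cnt <- matrix(
      stats::rbinom(n * m, 2L, rep(mafs, each = n)),
      nrow = n, ncol = m
    )
    g_causal <- cnt[, 1L]
    if (config$missing_rate > 0) {
      cnt[stats::runif(n * m) < config$missing_rate] <- NA_integer_
    }
    G <- genotype_matrix(cnt, meta, sample_ids = sprintf("S%04d", seq_len(n)))

    # --- covariates (age, gender, batch), standardized contributions ---
    age <- stats::rnorm(n, mean = 70.86, sd = 8.80)
    p_male <- 148 / 379
    gender <- stats::rbinom(n, 1L, p_male)
    batch <- sample.int(config$n_batches, n, replace = TRUE)
    u_age <- (age - 70.86) / 8.80
    u_gender <- (gender - p_male) / sqrt(p_male * (1 - p_male))
    if (config$n_batches > 1L) {
      lev <- seq(0, 1, length.out = config$n_batches)
      u_batch <- (lev[batch] - mean(lev)) / stats::sd(lev) /
        sqrt((config$n_batches - 1) / config$n_batches)
      ncov <- 3
    } else {
      u_batch <- 0
      ncov <- 2
    }
    cov_part <- sqrt(config$covariate_r2 / ncov) * (u_age + u_gender + u_batch)

    # --- genetic, latent, case-status components ---
    beta_g <- solve_effect_size(config$target_snp_r2, config$causal_maf,
                                sqrt(1 - config$target_snp_r2))
    lat_load <- sqrt(abs(config$latent_corr))
    L <- stats::rnorm(n)
    status <- stats::rbinom(n, 1L, config$case_fraction)

    z <- cov_part +
      beta_g * (g_causal - 2 * config$causal_maf) +
      lat_load * L +
      config$case_shift * (status - config$case_fraction) +
      sqrt(sig2_eps) * stats::rnorm(n)

    # second/third analytes share the latent factor only (no genetic term)
    tgt_load <- sign(config$latent_corr) * lat_load
    z_ptau <- tgt_load * L + sqrt(1 - abs(config$latent_corr)) * stats::rnorm(n)
    z_tau  <- tgt_load * L + sqrt(1 - abs(config$latent_corr)) * stats::rnorm(n)
    z_abeta <- stats::rnorm(n)

    # exponentiate to realistic positive analyte scales (ng/mL, pg/mL)
    ykl40 <- exp(log(307.25) + 0.341 * z)
    ptau181 <- exp(log(60) + 0.40 * z_ptau)
    tau <- exp(log(350) + 0.50 * z_tau)
    abeta42 <- exp(log(500) + 0.35 * z_abeta)

    pheno <- data.frame(
      sample_id = G$sample_ids,
      ykl40 = ykl40, ptau181 = ptau181, tau = tau, abeta42 = abeta42,
      tau_abeta_ratio = tau / abeta42,
      age = age, gender = gender, batch = batch, status = status,
      stringsAsFactors = FALSE
    )
    list(genotypes = G, phenotypes = pheno,
         truth = list(causal_id = "snp_causal", beta = beta_g,
                      noise_variance = sig2_eps,
                      latent_loading = lat_load))
  })
}
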