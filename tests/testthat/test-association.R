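test_that("fit_ols reproduces closed forms and the normal-equations oracle", {
  x <- 1:10
  fit <- fit_ols(2 * x, cbind(1, x))
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  set.seed(30)
  y <- rnorm(10, 3)
  fit0 <- fit_ols(y, matrix(1, 10, 1))
  expect_equal(unname(fit0$coefficients), mean(y))
  expect_equal(fit0$r_squared, 0)

  # random 50 x 4 design vs explicit (X'X)^-1 X'y
  X <- cbind(1, matrix(rnorm(150), 50, 3))
  y <- rnorm(50)
  fit <- fit_ols(y, X)
  orc <- normal_equations_oracle(y, X)
  expect_equal(unname(fit$coefficients), orc$beta, tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(orc$p), tolerance = 1e-10)
})

test_that("fit_ols honors its structural invariants", {
  set.seed(31)
  X <- cbind(1, matrix(rnorm(200), 50, 4))
  y <- rnorm(50)
  fit <- fit_ols(y, X)
  # residuals orthogonal to every predictor
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8 * sqrt(sum(y^2)))
  # leverages in [0,1] summing to the number of predictors
  expect_true(all(fit$leverage >= 0 & fit$leverage <= 1))
  expect_equal(sum(fit$leverage), ncol(X), tolerance = 1e-10)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  # rank deficiency is named
  expect_error(fit_ols(y, cbind(X, dup = X[, 2])), "singular.*dup")
})

test_that("run_gwas equals a direct OLS on the assembled design", {
  sim <- quick_cohort(seed = 32, n = 120, m_null = 30)
  y <- log_standardize(sim$phenotypes$ykl40)
  covs <- covariates_of(sim$phenotypes)
  tab <- run_gwas(sim$genotypes, y, covs)
  for (j in c(1, 5, 17)) {
    g <- sim$genotypes$counts[, j]
    orc <- fit_ols(y, cbind(1, covs, G = g))
    k <- length(orc$coefficients)
    expect_equal(tab$BETA[j], unname(orc$coefficients[k]), tolerance = 1e-10)
    expect_equal(tab$SE[j], unname(orc$se[k]), tolerance = 1e-10)
    expect_equal(tab$P[j], unname(orc$p[k]), tolerance = 1e-10)
  }
})

test_that("missing genotypes use per-variant complete cases", {
  sim <- quick_cohort(seed = 33, n = 150, m_null = 10)
  cnt <- sim$genotypes$counts
  cnt[1:12, 3] <- NA
  G <- genotype_matrix(cnt, sim$genotypes$variants,
                       sample_ids = sim$genotypes$sample_ids)
  y <- log_standardize(sim$phenotypes$ykl40)
  covs <- covariates_of(sim$phenotypes)
  tab <- run_gwas(G, y, covs)
  expect_equal(tab$N[3], 138L)
  keep <- !is.na(cnt[, 3])
  orc <- fit_ols(y[keep], cbind(1, covs[keep, ], G = cnt[keep, 3]))
  k <- length(orc$coefficients)
  expect_equal(tab$BETA[3], unname(orc$coefficients[k]), tolerance = 1e-10)
  expect_equal(tab$P[3], unname(orc$p[k]), tolerance = 1e-10)
})

test_that("flipping the counted allele negates beta and keeps p", {
  sim <- quick_cohort(seed = 34, n = 100, m_null = 5)
  y <- log_standardize(sim$phenotypes$ykl40)
  tab1 <- run_gwas(sim$genotypes, y)
  flipped <- genotype_matrix(2L - sim$genotypes$counts, sim$genotypes$variants,
                             sample_ids = sim$genotypes$sample_ids)
  tab2 <- run_gwas(flipped, y)
  expect_equal(tab2$BETA, -tab1$BETA, tolerance = 1e-10)
  expect_equal(tab2$P, tab1$P, tolerance = 1e-10)
})

test_that("sample-order permutation leaves GWAS statistics unchanged", {
  sim <- quick_cohort(seed = 35, n = 90, m_null = 8)
  y <- log_standardize(sim$phenotypes$ykl40)
  covs <- covariates_of(sim$phenotypes)
  tab1 <- run_gwas(sim$genotypes, y, covs)
  set.seed(36)
  perm <- sample(90)
  Gp <- subset_genotypes(sim$genotypes, samples = perm)
  tab2 <- run_gwas(Gp, y[perm], covs[perm, , drop = FALSE])
  expect_equal(tab2$BETA, tab1$BETA, tolerance = 1e-10)
  expect_equal(tab2$P, tab1$P, tolerance = 1e-10)
})

test_that("monomorphic variants yield NA rows with a reason, never silence", {
  cnt <- cbind(a = rbinom(60, 2, 0.3), b = rep(1L, 60))
  cnt[1, 2] <- NA
  meta <- data.frame(chrom = "1", pos = 1:2, id = c("a", "b"),
                     ref = "A", alt = "G", counted = "G")
  set.seed(37)
  y <- rnorm(60)
  tab <- run_gwas(genotype_matrix(cnt, meta), y)
  expect_true(is.na(tab$P[2]))
  expect_equal(tab$REASON[2], "monomorphic")
  expect_equal(nrow(tab), 2L)
})

test_that("conditional analysis removes the causal signal and marks the index", {
  sim <- quick_cohort(seed = 40, m_null = 40)
  y <- log_standardize(sim$phenotypes$ykl40)
  covs <- covariates_of(sim$phenotypes)
  tab <- run_gwas(sim$genotypes, y, covs)
  expect_equal(tab$CLASS[tab$ID == "snp_causal"], "genome-wide")
  cond <- conditional_analysis(sim$genotypes, y, covs, "snp_causal")
  idx <- cond$ID == "snp_causal"
  expect_true(is.na(cond$P[idx]))
  expect_equal(cond$REASON[idx], "conditioned_on")
  expect_false(any(cond$CLASS[!idx] == "genome-wide", na.rm = TRUE))

  # conditioning on a null variant barely moves the causal p
  cond2 <- conditional_analysis(sim$genotypes, y, covs, "snp00005")
  p_before <- tab$P[tab$ID == "snp_causal"]
  p_after <- cond2$P[cond2$ID == "snp_causal"]
  expect_lt(abs(log10(p_after) - log10(p_before)), 1)

  expect_error(conditional_analysis(sim$genotypes, y, covs, "nope"),
               "unknown index variant")
})

test_that("genomic inflation matches its definition and scaling", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1.0)
  set.seed(39)
  p_unif <- runif(50000)
  expect_lt(abs(genomic_inflation(p_unif) - 1), 0.02)
  # chi-square statistics scaled by 1.3 -> lambda ~ 1.3
  chi <- qchisq(p_unif, 1, lower.tail = FALSE)
  p_scaled <- pchisq(1.3 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_scaled), 1.3, tolerance = 0.02)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("significance classes follow the GWAS thresholds", {
  expect_equal(classify_significance(1.76e-14), "genome-wide")
  expect_equal(classify_significance(6.26e-8), "suggestive")
  expect_equal(classify_significance(0.5), "ns")
  expect_equal(classify_significance(c(1e-9, 1e-6, 0.2)),
               c("genome-wide", "suggestive", "ns"))
  expect_error(classify_significance(0), "0, 1")
  expect_error(classify_significance(1.5), "0, 1")
})

test_that("causal-effect estimates are unbiased over replicates", {
  set.seed(40)
  est <- t(vapply(1:300, function(i) {
    sim <- simulate_cohort(sim_config(n_samples = 379, n_null_variants = 0,
                                      missing_rate = 0, seed = 40000 + i))
    y <- log_standardize(sim$phenotypes$ykl40)
    covs <- covariates_of(sim$phenotypes)
    tab <- run_gwas(sim$genotypes, y, covs)
    c(tab$BETA[1], sim$truth$beta)
  }, numeric(2)))
  # generative beta is on the unstandardized z scale; the fitted phenotype is
  # rescaled to unit SD, so compare on the standardized scale
  gen_beta <- est[1, 2]
  expect_lt(abs(mean(est[, 1]) - gen_beta),
            2 * sd(est[, 1]) / sqrt(nrow(est)) + 0.01 * gen_beta)
})
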