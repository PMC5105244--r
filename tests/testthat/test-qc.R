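test_that("compute_maf folds frequencies and ignores missing calls", {
  expect_identical(compute_maf(rep(0L, 20)), 0)
  # 100 samples: 10 het, 5 hom-alt, 85 hom-ref -> 20/200
  x <- c(rep(1L, 10), rep(2L, 5), rep(0L, 85))
  expect_equal(compute_maf(x), 0.10)
  expect_equal(compute_maf(c(x, rep(NA_integer_, 50))), 0.10)
  expect_error(compute_maf(rep(NA_integer_, 5)), "no non-missing")
})

test_that("compute_maf is invariant to swapping ref/alt labels", {
  set.seed(4)
  for (i in 1:20) {
    x <- sample(c(0:2, NA), 60, replace = TRUE)
    if (all(is.na(x))) next
    expect_equal(compute_maf(x), compute_maf(2L - x))
  }
})

test_that("HWE exact test matches its closed-form anchor points", {
  # modal configuration: every outcome at most as probable as observed
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  # all-heterozygote table, frozen from the enumeration oracle
  p0 <- hwe_exact_test(0, 100, 0)
  expect_lt(p0, 1e-6)
  expect_equal(p0, 1.5113908273055e-29, tolerance = 1e-10)
  expect_equal(hwe_exact_test(57, 14, 50), 5.5620473110957e-19,
               tolerance = 1e-10)
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
  expect_error(hwe_exact_test(0, 0, 0), ">= 1")
})

test_that("HWE exact test equals full enumeration over random tables", {
  set.seed(8)
  for (i in 1:300) {
    n <- sample(1:100, 1)               # up to 200 alleles
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact_test(naa, nab, nbb),
                 hwe_enumeration_oracle(naa, nab, nbb),
                 tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d)", naa, nab, nbb))
  }
})

test_that("variant filters exclude on call rate, MAF and HWE with reasons", {
  set.seed(10)
  n <- 200
  # enough clean variants that single missing calls leave samples above the
  # sample-level call-rate threshold (samples are filtered first)
  good <- replicate(100, rbinom(n, 2, 0.3))
  low_call <- rbinom(n, 2, 0.3); low_call[1:6] <- NA        # 97% call rate
  rare <- c(rep(1L, 7), rep(0L, n - 7))                     # MAF 0.0175
  hwe_bad <- rep(1L, n)                                     # all het
  cnt <- cbind(good, low_call, rare, hwe_bad)
  meta <- data.frame(chrom = "1", pos = seq_len(ncol(cnt)),
                     id = c(paste0("g", 1:100), "lowcall", "rare", "allhet"),
                     ref = "A", alt = "G", counted = "G")
  G <- genotype_matrix(cnt, meta)
  res <- filter_variants(G)
  rep_v <- res$report$variants
  expect_false(rep_v$pass[rep_v$id == "lowcall"])
  expect_match(rep_v$reason[rep_v$id == "lowcall"], "call_rate")
  expect_false(rep_v$pass[rep_v$id == "rare"])
  expect_match(rep_v$reason[rep_v$id == "rare"], "maf")
  expect_false(rep_v$pass[rep_v$id == "allhet"])
  expect_match(rep_v$reason[rep_v$id == "allhet"], "hwe")
  expect_identical(res$genotypes$variants$id, paste0("g", 1:100))
  # every excluded variant carries at least one reason
  expect_true(all(nzchar(rep_v$reason[!rep_v$pass])))
})

test_that("a clean simulated cohort passes QC untouched and filtering is idempotent", {
  sim <- quick_cohort(seed = 12, m_null = 200)
  res1 <- filter_variants(sim$genotypes)
  expect_true(all(res1$report$variants$pass))
  expect_true(all(res1$report$samples$pass))
  res2 <- filter_variants(res1$genotypes)
  expect_identical(res2$genotypes$counts, res1$genotypes$counts)
  expect_identical(res2$genotypes$variants, res1$genotypes$variants)
})

test_that("all-failing input yields an explicit empty-result signal", {
  G <- genotype_matrix(matrix(1L, nrow = 50, ncol = 2),
                       data.frame(chrom = "1", pos = 1:2, id = c("a", "b"),
                                  ref = "A", alt = "G", counted = "G"))
  expect_warning(res <- filter_variants(G), "no variants pass")
  expect_null(res$genotypes)
  expect_true(res$report$empty)
})

test_that("duplicate detection flags identical samples, not unrelated ones", {
  G <- simulate_genotypes(60, mafs = runif(2000, 0.1, 0.5),
                          missing_rate = 0, seed = 14)
  cnt <- G$counts
  cnt[60, ] <- cnt[1, ]                              # verbatim duplicate
  cnt[59, ] <- cnt[2, ]
  set.seed(15)
  cnt[59, sample(2000, 100)] <- NA                   # duplicate with 5% missing
  Gd <- genotype_matrix(cnt, G$variants, sample_ids = G$sample_ids)
  pairs <- detect_duplicates(Gd)
  key <- paste(pairs$sample_1, pairs$sample_2)
  expect_true("S0001 S0060" %in% key)
  expect_equal(pairs$sharing[key == "S0001 S0060"], 1.0)
  expect_true("S0002 S0059" %in% key)                # missing sites excluded
  expect_equal(nrow(pairs), 2L)                      # unrelated pairs < 0.95
  expect_warning(out <- detect_duplicates(subset_genotypes(G, samples = 1)),
                 "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("concordance between unrelated simulated samples stays below 0.95", {
  G <- simulate_genotypes(40, mafs = runif(10000, 0.05, 0.5),
                          missing_rate = 0, seed = 16)
  expect_equal(nrow(detect_duplicates(G)), 0L)
})

test_that("PCA separates divergent subpopulations on PC1", {
  set.seed(17)
  m <- 1000
  p1 <- runif(m, 0.1, 0.5)
  shift <- ifelse(rbinom(m, 1, 0.5) == 1, 0.3, -0.3)
  p2 <- pmin(0.95, pmax(0.05, p1 + shift))
  pop <- rep(c(0, 1), each = 75)
  cnt <- rbind(
    sapply(p1, function(p) rbinom(75, 2, p)),
    sapply(p2, function(p) rbinom(75, 2, p))
  )
  meta <- data.frame(chrom = "1", pos = seq_len(m), id = paste0("v", seq_len(m)),
                     ref = "A", alt = "G", counted = "G")
  G <- genotype_matrix(cnt, meta)
  pcs <- pca_population_structure(G, k = 2)
  expect_gt(abs(cor(pcs$scores[, 1], pop)), 0.9)
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
  expect_true(all(pcs$eigenvalues >= 0))
  # scores orthogonal
  s <- pcs$scores
  expect_lt(abs(sum(s[, 1] * s[, 2])) / (sqrt(sum(s[, 1]^2) * sum(s[, 2]^2))),
            1e-6)
})

test_that("PCA is invariant (up to sign) to variant permutation and drops monomorphics", {
  sim <- quick_cohort(seed = 18, n = 80, m_null = 300)
  G <- sim$genotypes
  pcs1 <- pca_population_structure(G, k = 2)
  set.seed(19)
  perm <- sample(ncol(G$counts))
  Gp <- subset_genotypes(G, variants = perm)
  pcs2 <- pca_population_structure(Gp, k = 2)
  for (k in 1:2) {
    expect_gt(abs(cor(pcs1$scores[, k], pcs2$scores[, k])), 1 - 1e-6)
  }
  # monomorphic column dropped rather than producing NaNs
  cnt <- cbind(G$counts, mono = 0L)
  meta <- rbind(G$variants, data.frame(chrom = "1", pos = 1L, id = "mono",
                                       ref = "A", alt = "G", counted = "G"))
  Gm <- genotype_matrix(cnt, meta, sample_ids = G$sample_ids)
  pcs3 <- pca_population_structure(Gm, k = 2)
  expect_true(all(is.finite(pcs3$scores)))
  expect_error(pca_population_structure(G, k = 81), "rank|samples")
})

test_that("homogeneous population shows no dominant eigenvalue", {
  G <- simulate_genotypes(300, mafs = runif(5000, 0.05, 0.5),
                          missing_rate = 0, seed = 21)
  pcs <- pca_population_structure(G, k = 100)
  expect_lt(pcs$eigenvalues[1] / mean(pcs$eigenvalues), 3)
})
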