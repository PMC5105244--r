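#' Minor allele frequency of an allele-count vector
#'
#' @param counts Vector of genotypes in \{0, 1, 2, NA\}.
#' @return `min(f, 1 - f)` where `f` is the counted-allele frequency among
#'   non-missing calls.
#' @export
compute_maf <- function(counts) {
  ok <- !is.na(counts)
  if (!any(ok)) stop("variant has no non-missing genotypes", call. = FALSE)
  x <- counts[ok]
  if (any(x < 0 | x > 2)) stop("genotype counts must be 0, 1 or 2", call. = FALSE)
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of genotype counts against Hardy-Weinberg
#' proportions given the allele counts (the Wigginton-Cutler-Abecasis
#' formulation, non-mid-p). The p-value is the sum of the conditional
#' probabilities of all heterozygote counts at least as improbable as the
#' observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype class counts (nonnegative,
#'   total >= 1). Vectors are recycled elementwise.
#' @return p-value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  nn <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(n_hom_ref, nn)
  n_het <- rep_len(n_het, nn)
  n_hom_alt <- rep_len(n_hom_alt, nn)
  vapply(seq_len(nn), function(i) {
    hwe_exact_one(n_hom_ref[i], n_het[i], n_hom_alt[i])
  }, numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(!is.finite(c(n_aa, n_ab, n_bb))) || any(c(n_aa, n_ab, n_bb) < 0)) {
    stop("genotype counts must be nonnegative", call. = FALSE)
  }
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  # work with the rarer allele
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized probabilities by the Wigginton recurrence, anchored at the
  # largest feasible heterozygote count
  k <- length(het_vals)
  probs <- numeric(k)
  probs[k] <- 1
  if (k > 1) {
    for (j in rev(seq_len(k - 1))) {
      het <- het_vals[j + 1]
      hom_r <- (n_rare - het) / 2
      hom_c <- n - het - hom_r
      # P(het - 2) / P(het) = het (het - 1) / (4 (hom_r + 1)(hom_c + 1))
      probs[j] <- probs[j + 1] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, het_vals)]
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Apply variant- and sample-level quality filters
#'
#' Samples are filtered on call rate first, then variants on call rate, MAF
#' and the Hardy-Weinberg exact test, mirroring standard array QC. Every
#' exclusion is recorded with its reason(s); retained variants keep their
#' input order.
#'
#' @param G A [genotype_matrix()].
#' @param call_rate_min Minimum call rate for variants and samples
#'   (exclude when call rate < threshold).
#' @param maf_min Minimum minor allele frequency (exclude when MAF < threshold).
#' @param hwe_alpha Hardy-Weinberg exact-test significance threshold
#'   (exclude when p < threshold).
#' @return A list with `genotypes` (the filtered matrix) and `report`
#'   (a `qc_report`: per-variant and per-sample tables with pass flags and
#'   failure reasons, plus the thresholds used). If every variant is removed,
#'   `genotypes` is `NULL` and the report's `empty` flag is set.
#' @export
filter_variants <- function(G, call_rate_min = 0.98, maf_min = 0.02,
                            hwe_alpha = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (call_rate_min < 0 || call_rate_min > 1 ||
      maf_min < 0 || maf_min > 0.5 ||
      hwe_alpha <= 0 || hwe_alpha >= 1) {
    stop("QC thresholds out of range", call. = FALSE)
  }
  cnt <- G$counts

  # sample-level call rate first
  s_call <- rowMeans(!is.na(cnt))
  s_pass <- s_call >= call_rate_min
  samples <- data.frame(sample_id = G$sample_ids, call_rate = s_call,
                        pass = s_pass,
                        reason = ifelse(s_pass, "", "call_rate"),
                        stringsAsFactors = FALSE)
  cnt <- cnt[s_pass, , drop = FALSE]

  m <- ncol(cnt)
  v_call <- colMeans(!is.na(cnt))
  usable <- v_call > 0
  maf <- rep(NA_real_, m)
  hwe_p <- rep(NA_real_, m)
  for (j in which(usable)) {
    x <- cnt[, j]
    x <- x[!is.na(x)]
    maf[j] <- compute_maf(x)
    hwe_p[j] <- hwe_exact_one(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }
  reasons <- vapply(seq_len(m), function(j) {
    r <- character(0)
    if (v_call[j] < call_rate_min) r <- c(r, "call_rate")
    if (!usable[j] || maf[j] < maf_min) r <- c(r, "maf")
    if (usable[j] && hwe_p[j] < hwe_alpha) r <- c(r, "hwe")
    paste(r, collapse = ";")
  }, character(1))
  v_pass <- reasons == ""
  variants <- data.frame(G$variants[c("id", "chrom", "pos")],
                         call_rate = v_call, maf = maf, hwe_p = hwe_p,
                         pass = v_pass, reason = reasons,
                         stringsAsFactors = FALSE)
  report <- structure(
    list(variants = variants, samples = samples, duplicate_pairs = NULL,
         thresholds = list(call_rate_min = call_rate_min, maf_min = maf_min,
                           hwe_alpha = hwe_alpha),
         empty = !any(v_pass)),
    class = "qc_report"
  )
  if (!any(v_pass)) {
    warning("no variants pass QC; returning NULL genotypes", call. = FALSE)
    return(list(genotypes = NULL, report = report))
  }
  out <- genotype_matrix(cnt[, v_pass, drop = FALSE],
                         G$variants[v_pass, , drop = FALSE],
                         sample_ids = rownames(cnt))
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d variants pass, %d/%d samples pass\n",
              sum(x$variants$pass), nrow(x$variants),
              sum(x$samples$pass), nrow(x$samples)))
  invisible(x)
}

#' Detect duplicate samples by genotype concordance
#'
#' Flags all unordered sample pairs whose fraction of identical non-missing
#' genotype calls is at least `sharing_min`. Sites missing in either member
#' of a pair are excluded from both numerator and denominator. This genotype
#' concordance screen targets duplicates and near-identical relatives; it is
#' not a kinship estimator.
#'
#' @param G A [genotype_matrix()].
#' @param sharing_min Minimum concordance fraction to report a pair.
#' @return Data frame with columns `sample_1`, `sample_2`, `sharing`.
#' @export
detect_duplicates <- function(G, sharing_min = 0.95) {
  stopifnot(inherits(G, "genotype_matrix"))
  empty <- data.frame(sample_1 = character(0), sample_2 = character(0),
                      sharing = numeric(0), stringsAsFactors = FALSE)
  if (nrow(G$counts) < 2) {
    warning("fewer than 2 samples; no pairs to compare", call. = FALSE)
    return(empty)
  }
  cnt <- G$counts
  obs <- !is.na(cnt)
  valid <- tcrossprod(obs * 1)          # pairwise non-missing overlap
  match_ct <- matrix(0, nrow(cnt), nrow(cnt))
  for (g in 0:2) {
    ind <- (cnt == g) & obs
    match_ct <- match_ct + tcrossprod(ind * 1)
  }
  sharing <- match_ct / pmax(valid, 1)
  sharing[valid == 0] <- NA_real_
  hits <- which(upper.tri(sharing) & !is.na(sharing) & sharing >= sharing_min,
                arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  data.frame(sample_1 = G$sample_ids[hits[, 1]],
             sample_2 = G$sample_ids[hits[, 2]],
             sharing = sharing[hits],
             stringsAsFactors = FALSE)
}

#' Principal components of population structure
#'
#' EIGENSTRAT-style PCA: each variant column is centered at twice its sample
#' allele frequency and scaled by the binomial standard deviation
#' `sqrt(2 p (1 - p))`; missing entries are mean-imputed (PCA only — the
#' association stage never imputes). Monomorphic variants are dropped before
#' standardization.
#'
#' @param G A [genotype_matrix()].
#' @param k Number of components to return.
#' @return A list of class `pca_structure` with `sample_ids`, `scores`
#'   (n x k, columns orthogonal), and `eigenvalues` (descending, length k).
#' @export
pca_population_structure <- function(G, k = 2) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$counts)
  if (n < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  X <- G$counts * 1.0
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  keep <- is.finite(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(keep)) stop("all variants monomorphic; PCA undefined", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  X <- sweep(X, 2, 2 * p_hat)
  X[is.na(X)] <- 0                       # mean imputation after centering
  X <- sweep(X, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) stop(sprintf("k = %d exceeds matrix rank %d", k, rank),
                     call. = FALSE)
  eig <- sv$d^2 / (ncol(X))              # per-variant-normalized covariance
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- G$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(sample_ids = G$sample_ids, scores = scores,
                 eigenvalues = eig[seq_len(k)]),
            class = "pca_structure")
}
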