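#' Run the full biomarker-GWAS pipeline
#'
#' Orchestrates simulate (or load) -> sample/variant QC -> duplicate check ->
#' PCA -> per-variant GWAS -> top-variant selection -> variance decomposition
#' -> genetic adjustment -> correlation comparison -> case/control test, and
#' writes each stage's table plus a JSON manifest with file digests so a
#' rerun under the same config is verifiably identical.
#'
#' @param config A [sim_config()], a config list, or a path to a YAML config
#'   file (see [read_sim_config()]).
#' @param out_dir Output directory (created if absent).
#' @param analyte Biomarker column to analyze.
#' @param target Target analyte for the correlation comparison.
#' @param covariate_cols Phenotype covariates entered into the GWAS and the
#'   status test (principal components are appended to the GWAS covariates).
#' @param n_pcs Number of population-structure PCs as GWAS covariates.
#' @param force_adjust Adjust on the top variant even if it is not
#'   genome-wide significant (a warning is logged either way).
#' @param log_file Optional path for `key=value` stage logs (also echoed to
#'   `stderr`).
#' @return A list of class `run_manifest`: config snapshot, seed, package
#'   version, per-stage output files with md5 digests, the top variant and
#'   its statistics, the variance decomposition, the comparison row, and the
#'   status-test row.
#' @export
run_pipeline <- function(config, out_dir = tempfile("csfqtl_run_"),
                         analyte = "ykl40", target = "ptau181",
                         covariate_cols = c("age", "gender", "batch"),
                         n_pcs = 2, force_adjust = FALSE, log_file = NULL) {
  t_start <- Sys.time()
  if (is.character(config) && length(config) == 1L) config <- read_sim_config(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logline <- function(stage, ...) {
    msg <- sprintf("stage=%s %s elapsed=%.2fs", stage,
                   paste(..., collapse = " "),
                   as.numeric(Sys.time() - t_start, units = "secs"))
    message(msg)
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  }
  files <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files[[name]] <<- path
    path
  }

  # --- simulate ---
  sim <- simulate_cohort(config)
  emit(sim$genotypes, "genotypes.vcf", write_vcf)
  emit(sim$phenotypes, "phenotypes.tsv", write_phenotype_tsv)
  logline("simulate", sprintf("n=%d m=%d", nrow(sim$genotypes$counts),
                              ncol(sim$genotypes$counts)))

  # --- QC ---
  qc <- filter_variants(sim$genotypes)
  if (is.null(qc$genotypes)) stop("QC removed every variant", call. = FALSE)
  qc$report$duplicate_pairs <- detect_duplicates(qc$genotypes)
  if (nrow(qc$report$duplicate_pairs)) {
    warning(sprintf("%d duplicate sample pair(s) detected",
                    nrow(qc$report$duplicate_pairs)), call. = FALSE)
  }
  emit(qc$report, "qc_report.tsv", write_qc_report)
  G <- qc$genotypes
  pheno <- sim$phenotypes[match(rownames(G$counts), sim$phenotypes$sample_id), ]
  logline("qc", sprintf("variants_pass=%d samples_pass=%d",
                        sum(qc$report$variants$pass), nrow(G$counts)))

  # --- PCA ---
  pcs <- pca_population_structure(G, k = n_pcs)
  logline("pca", sprintf("k=%d eig1=%.3f", n_pcs, pcs$eigenvalues[1]))

  # --- GWAS ---
  y <- log_standardize(pheno[[analyte]])
  sw <- normality_check(y)
  covs <- build_covariate_matrix(pheno, covariate_cols, extra = pcs$scores)
  assoc <- run_gwas(G, y, covs)
  emit(assoc, "association.tsv", function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE))
  emit(manhattan_table(assoc), "manhattan.tsv", function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE))
  lambda <- genomic_inflation(assoc$P[!is.na(assoc$P)])
  ord <- order(assoc$P, assoc$CHR, assoc$POS, na.last = TRUE)
  top <- assoc[ord[1], ]
  logline("gwas", sprintf("lambda=%.3f top=%s p=%.3g shapiro_p=%.3g",
                          lambda, top$ID, top$P, sw$p))

  # --- conditional analysis on the top variant ---
  cond <- conditional_analysis(G, y, covs, index_variant_id = top$ID)
  emit(cond, "conditional.tsv", function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE))
  logline("conditional", sprintf("remaining_gw=%d",
                                 sum(cond$CLASS == "genome-wide", na.rm = TRUE)))

  # --- adjustment ---
  if (is.na(top$CLASS) || top$CLASS != "genome-wide") {
    logline("adjust", sprintf("warning=no_genome_wide_hit top=%s", top$ID))
    if (!force_adjust) {
      stop("top variant ", top$ID, " is not genome-wide significant; ",
           "rerun with force_adjust = TRUE to adjust on it anyway",
           call. = FALSE)
    }
  }
  adj <- adjust_biomarker(pheno, G, analyte, top$ID, covariates = covs)
  pheno <- adj$pheno_table
  emit(pheno, "phenotypes_adjusted.tsv", write_phenotype_tsv)
  logline("adjust", sprintf("r2_cov=%.4f r2_snp=%.4f", adj$r2_covariates,
                            adj$r2_variant))

  # --- correlation comparison ---
  cmp <- compare_adjusted(pheno, analyte, adj$column_name, target)
  cmp_row <- data.frame(r_jk = cmp$r_jk, p_jk = cmp$p_jk, r_jh = cmp$r_jh,
                        p_jh = cmp$p_jh, Z = cmp$Z, p = cmp$p,
                        ci_low = cmp$ci_low, ci_high = cmp$ci_high,
                        decision = cmp$decision, n = cmp$n)
  emit(cmp_row, "comparison.tsv", function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE))
  logline("compare", sprintf("r_unadj=%.3f r_adj=%.3f p=%.3g",
                             cmp$r_jk, cmp$r_jh, cmp$p))

  # --- case/control status test ---
  st <- test_status_association(pheno, analyte, covariate_cols)
  st_row <- data.frame(beta = st$coefficients[["analyte"]],
                       se = st$se[["analyte"]], z = st$z[["analyte"]],
                       p = st$p[["analyte"]], n = st$n)
  emit(st_row, "status_test.tsv", function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE))
  logline("status", sprintf("beta=%.3f p=%.3g", st_row$beta, st_row$p))

  manifest <- structure(
    list(config = unclass(config), seed = config$seed,
         package_version = as.character(utils::packageVersion("csfqtl")),
         files = as.list(stats::setNames(unname(tools::md5sum(unlist(files))),
                                         names(files))),
         shapiro = sw, lambda = lambda,
         top_variant = list(id = top$ID, beta = top$BETA, se = top$SE,
                            p = top$P, class = top$CLASS),
         r2_covariates = adj$r2_covariates, r2_variant = adj$r2_variant,
         comparison = as.list(cmp_row), status_test = as.list(st_row),
         out_dir = out_dir),
    class = "run_manifest"
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest), "out_dir")],
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logline("done", sprintf("manifest=%s", manifest_path))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> seed=%d\n  top variant: %s (beta=%.3f, p=%.3g, %s)\n  R2: covariates=%.4f variant=%.4f, lambda=%.3f\n  comparison: r %.3f -> %.3f (Meng p=%.3g, %s)\n  status test: beta=%.3f p=%.3g\n",
    x$seed, x$top_variant$id, x$top_variant$beta, x$top_variant$p,
    x$top_variant$class, x$r2_covariates, x$r2_variant, x$lambda,
    x$comparison$r_jk, x$comparison$r_jh, x$comparison$p,
    x$comparison$decision, x$status_test$beta, x$status_test$p))
  invisible(x)
}

#' Manhattan-ready table
#'
#' CHR, POS, -log10(p), significance class, and a cumulative genome
#' coordinate for plotting; rows with missing p are dropped.
#'
#' @param assoc An `association_table` from [run_gwas()].
#' @return Data frame with columns CHR, POS, NEG_LOG10_P, CLASS, CUM_POS.
#' @export
manhattan_table <- function(assoc) {
  if (!nrow(assoc)) stop("empty association table", call. = FALSE)
  keep <- !is.na(assoc$P)
  df <- assoc[keep, , drop = FALSE]
  chr_order <- unique(df$CHR)
  offset <- 0
  cum <- numeric(nrow(df))
  for (ch in chr_order) {
    i <- df$CHR == ch
    cum[i] <- offset + df$POS[i]
    offset <- offset + max(df$POS[i])
  }
  data.frame(CHR = df$CHR, POS = df$POS,
             NEG_LOG10_P = -log10(df$P),
             CLASS = df$CLASS, CUM_POS = cum,
             stringsAsFactors = FALSE)
}
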