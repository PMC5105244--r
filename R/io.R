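#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal VCF with a single FORMAT field `GT`, unphased `/`
#' separated genotypes, and `./.` for missing calls. Allele counts are
#' rendered against the recorded ref/alt alleles (counted allele = alt:
#' 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`).
#'
#' @param G A [genotype_matrix()].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  cnt <- t(G$counts)                      # variants x samples
  gt <- matrix(gt_code[as.character(cnt)], nrow = nrow(cnt))
  gt[is.na(cnt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=csfqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF (v4.2) into alt-allele counts via the vcfR
#' reader; `./.` (or any genotype containing `.`) becomes missing. Counted
#' allele is ALT.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_counts <- function(s) {
    ifelse(is.na(s) | grepl("\\.", s), NA_integer_,
           vapply(strsplit(s, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  cnt <- t(apply(gt, 1, alt_counts))
  if (ncol(gt) == 1) cnt <- matrix(cnt, ncol = 1)  # guard 1-sample drop
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  meta <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     counted = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(cnt), meta, sample_ids = colnames(gt))
}

#' Write / read an allele-count TSV
#'
#' Samples x variants table: first column `sample_id`, remaining columns
#' named by variant id, values 0/1/2 with `NA` for missing. The variant
#' metadata travels in a sidecar `<path>.variants.tsv`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, G$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$variants, paste0(path, ".variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, -1, drop = FALSE])
  meta_path <- paste0(path, ".variants.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              colClasses = c(chrom = "character"),
                              stringsAsFactors = FALSE)
  } else {
    meta <- data.frame(chrom = "1", pos = seq_len(ncol(cnt)),
                       id = colnames(cnt), ref = "A", alt = "G", counted = "G",
                       stringsAsFactors = FALSE)
  }
  genotype_matrix(cnt, meta, sample_ids = df$sample_id)
}

#' Write / read the phenotype table TSV
#'
#' Header row `sample_id, ykl40, ptau181, tau, abeta42, ...` plus covariate
#' and status columns; `NA` for missing.
#'
#' @param pheno Phenotype data frame.
#' @param path TSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotype_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a QC report as TSV
#'
#' One row per *excluded* variant or sample with its failure reasons,
#' preceded by `#`-prefixed threshold lines.
#'
#' @param report A `qc_report` from [filter_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  con <- file(path, "w")
  on.exit(close(con))
  th <- report$thresholds
  writeLines(sprintf("# call_rate_min=%g maf_min=%g hwe_alpha=%g",
                     th$call_rate_min, th$maf_min, th$hwe_alpha), con)
  excl_v <- report$variants[!report$variants$pass, c("id", "reason")]
  excl_s <- report$samples[!report$samples$pass, c("sample_id", "reason")]
  out <- rbind(
    if (nrow(excl_v)) data.frame(type = "variant", id = excl_v$id,
                                 reason = excl_v$reason),
    if (nrow(excl_s)) data.frame(type = "sample", id = excl_s$sample_id,
                                 reason = excl_s$reason)
  )
  if (is.null(out)) out <- data.frame(type = character(0), id = character(0),
                                      reason = character(0))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
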