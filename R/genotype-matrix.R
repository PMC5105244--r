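#' Construct a genotype matrix
#'
#' The central genotype container: an integer matrix of counted-allele copies
#' (0, 1, 2, or `NA` for a missing call) with samples in rows and variants in
#' columns, plus per-variant metadata.
#'
#' @param counts Integer matrix, samples x variants, entries in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names variant ids (supplied via
#'   `sample_ids` / `variant_meta$id` if absent).
#' @param variant_meta Data frame with one row per variant and columns
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `counted`. `counted` names the allele
#'   whose copies are counted (the VCF ALT allele by convention here).
#' @param sample_ids Character vector of unique sample identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(counts, variant_meta, sample_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_len(nrow(counts)))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(variant_meta$id)) stop("variant ids must be unique", call. = FALSE)
  if (length(sample_ids) != nrow(counts)) {
    stop("length(sample_ids) must equal nrow(counts)", call. = FALSE)
  }
  if (nrow(variant_meta) != ncol(counts)) {
    stop("variant_meta rows must match ncol(counts)", call. = FALSE)
  }
  need <- c("chrom", "pos", "id", "ref", "alt", "counted")
  miss <- setdiff(need, names(variant_meta))
  if (length(miss)) {
    stop("variant_meta is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- counts[!is.na(counts)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(counts) <- list(sample_ids, variant_meta$id)
  variant_meta <- as.data.frame(variant_meta, stringsAsFactors = FALSE)
  rownames(variant_meta) <- NULL
  structure(
    list(counts = counts,
         variants = variant_meta[need],
         sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$counts))
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.3f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              100 * nmiss / length(x$counts)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x A [genotype_matrix()].
#' @param samples,variants Index vectors (logical, integer, or names) into
#'   samples and variants respectively; `NULL` keeps all.
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_len(nrow(x$counts))
  if (is.null(variants)) variants <- seq_len(ncol(x$counts))
  if (is.character(variants)) variants <- match(variants, x$variants$id)
  cnt <- x$counts[samples, variants, drop = FALSE]
  genotype_matrix(cnt, x$variants[variants, , drop = FALSE],
                  sample_ids = rownames(cnt))
}
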