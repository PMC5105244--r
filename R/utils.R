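#' csfqtl: quantitative-trait GWAS and genetic adjustment of CSF biomarkers
#'
#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# Keeps simulation functions referentially transparent in seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a per-stage RNG substream seed from a global seed; stays < 2^31.
substream_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, qc = 23L, pca = 37L, gwas = 53L,
               adjust = 71L, compare = 89L, status = 101L, null = 131L)
  off <- offsets[[stage]]
  (as.integer(seed) * 1009L + off) %% 2147483629L
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in (0, 1]", name), call. = FALSE)
  }
}
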