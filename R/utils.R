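# Internal helpers: deterministic seed substreams and config hashing.

# Derive a reproducible child seed from a root seed and a stage name.
# All randomness in the package flows from one root seed through named
# substreams so that stages can be re-run independently yet byte-identically.
seed_stream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L)) + 1L
}

# md5 of a canonical JSON rendering; used in run manifests.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column standard deviations (n-1 denominator) without an R-level loop;
# the preprocessing and resampling paths call this on wide matrices.
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}
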