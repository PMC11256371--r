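# Internal helpers shared across modules.

# Derive a child seed from a run seed and a fixed per-operation offset so that
# operations consume independent, reproducible RNG streams. Kept below 2^31.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}

# Seeded fold assignment for k-fold cross-validation.
make_folds <- function(n, n_folds, seed) {
  if (n < n_folds) {
    abort(sprintf("cannot split n = %d observations into %d folds", n, n_folds))
  }
  withr::with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

#' Write a run manifest as JSON
#'
#' A run manifest records everything needed to reproduce an analysis
#' bit-for-bit: input hashes, seeds, thresholds, the dimensions at each stage
#' and the package version. Timestamps are deliberately not recorded so that
#' two runs with the same seed produce byte-identical manifests.
#'
#' @param manifest A manifest list, e.g. from [dab()]'s `manifest` element.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
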