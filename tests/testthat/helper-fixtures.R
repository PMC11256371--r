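# Small deterministic fixtures built in code.

toy_counts <- function() {
  tibble::tibble(
    taxon_id = c("GenA", "GenB", "GenC", "GenD"),
    lineage = c(
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__FamA;g__GenA",
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__FamA;g__GenB",
      "k__Bacteria;p__Proteobacteria;c__Gamma;o__Pseudomonadales;f__FamB;g__GenC",
      "k__Eukaryota;p__Ascomycota;c__Euro;o__Euro;f__FamC;g__GenD"
    ),
    S1 = c(600, 300, 99, 1),
    S2 = c(100, 700, 200, 0),
    S3 = c(2000, 1500, 1480, 20)
  )
}

toy_meta <- function(n = 12, seed = 1) {
  meta <- dustdab::simulate_covariates(n, seed = seed)
  meta$pack_years[is.na(meta$pack_years)] <- 0
  meta
}

# minimal design wrapper for engine-level tests on hand-built matrices
fake_design <- function(x, y, q = 1) {
  structure(list(
    X = x, y = y, Z = NULL, Xr = x, yr = y,
    n = nrow(x), p = ncol(x), q = q,
    taxon_ids = colnames(x), sample_ids = rownames(x),
    column_means = rep(0, ncol(x)), column_sds = rep(1, ncol(x)),
    y_center = 0, y_scale = 1, dropped_taxa = character()
  ), class = "dab_design")
}

# brute-force OLS via normal equations, returning slopes and classical SEs
ols_oracle <- function(x, y, z = NULL) {
  w <- cbind(`(Intercept)` = 1, x, z)
  xtx <- crossprod(w)
  b <- solve(xtx, crossprod(w, y))
  r <- y - w %*% b
  sig2 <- sum(r^2) / (nrow(w) - ncol(w))
  se <- sqrt(sig2 * diag(solve(xtx)))
  idx <- 1 + seq_len(ncol(x))
  list(coef = b[idx], se = se[idx], sigma = sqrt(sig2))
}
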