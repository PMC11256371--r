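# Filtering, winsorization, compositional transform, outcome transforms and
# standardization.

make_counts <- function(m, kingdom = "Bacteria") {
  taxa <- colnames(m)
  tibble::tibble(
    taxon_id = taxa,
    lineage = sprintf("k__%s;p__P;c__C;o__O;f__F;g__%s", kingdom, taxa)
  ) |> dplyr::bind_cols(tibble::as_tibble(t(m), .name_repair = "minimal") |>
                          setNames(rownames(m)))
}

test_that("sample depth filter is strictly below-threshold", {
  m <- rbind(S1 = c(500, 499), S2 = c(500, 500), S3 = c(2500, 2500))
  colnames(m) <- c("A", "B")
  kept <- filter_counts(make_counts(m), filter_spec(1000, 0), verbose = FALSE)
  expect_setequal(dustdab:::count_sample_ids(kept), c("S2", "S3"))
})

test_that("taxon fraction filter boundary: exactly at threshold is retained", {
  # grand total 1e6; 0.0005% = 5 reads: 4 dropped, 5 retained
  m <- rbind(S1 = c(999991, 4, 5), S2 = c(0, 0, 0) + 0)
  colnames(m) <- c("big", "four", "five")
  kept <- filter_counts(make_counts(m), filter_spec(0, 5e-6), verbose = FALSE)
  expect_setequal(kept$taxon_id, c("big", "five"))
})

test_that("excluded kingdoms are removed and zero thresholds are identity", {
  counts <- toy_counts()
  kept <- filter_counts(counts, filter_spec(0, 0), verbose = FALSE)
  expect_setequal(kept$taxon_id, c("GenA", "GenB", "GenC"))  # GenD eukaryote
  kept2 <- filter_counts(counts, filter_spec(0, 0, excluded_kingdoms = character()),
                         verbose = FALSE)
  expect_setequal(kept2$taxon_id, counts$taxon_id)
  expect_equal(dustdab:::counts_matrix(kept2),
               dustdab:::counts_matrix(counts)[, kept2$taxon_id])
})

test_that("filtering is monotone in both thresholds", {
  cfg <- sim_config(n_samples = 60, n_taxa = 40, seed = 31)
  counts <- simulate_counts(cfg)
  dims <- function(spec) dim(dustdab:::counts_matrix(
    filter_counts(counts, spec, verbose = FALSE)))
  base <- dims(filter_spec(0, 0))
  tighter_s <- dims(filter_spec(quantile(rowSums(dustdab:::counts_matrix(counts)), 0.3), 0))
  tighter_t <- dims(filter_spec(0, 1e-4))
  expect_lte(tighter_s[1], base[1])
  expect_lte(tighter_t[2], base[2])
})

test_that("a table built with m samples below depth d loses exactly m", {
  set.seed(4)
  depths <- c(rep(500, 3), rep(5000, 7))
  m <- t(vapply(depths, function(d) as.numeric(rmultinom(1, d, rep(1, 6)/6)),
                numeric(6)))
  dimnames(m) <- list(paste0("S", 1:10), paste0("T", 1:6))
  kept <- filter_counts(make_counts(m), filter_spec(1000, 0), verbose = FALSE)
  expect_equal(length(dustdab:::count_sample_ids(kept)), 7)
})

test_that("winsorization caps the top five at the sixth largest", {
  m <- matrix(c(10, 9, 8, 7, 6, 5, 4), ncol = 1,
              dimnames = list(paste0("S", 1:7), "T1"))
  out <- dustdab:::winsorize_matrix(m, k_top = 5)
  expect_equal(as.numeric(out), c(5, 5, 5, 5, 5, 5, 4))

  ties <- matrix(rep(3, 7), ncol = 1, dimnames = list(paste0("S", 1:7), "T1"))
  expect_equal(dustdab:::winsorize_matrix(ties, 5), ties)
})

test_that("winsorization is idempotent, never increases, preserves low ranks", {
  cfg <- sim_config(n_samples = 40, n_taxa = 25, seed = 8)
  counts <- simulate_counts(cfg)
  w1 <- winsorize_counts(counts, 5)
  w2 <- winsorize_counts(w1, 5)
  expect_equal(w1, w2)
  m0 <- dustdab:::counts_matrix(counts)
  m1 <- dustdab:::counts_matrix(w1)
  expect_true(all(m1 <= m0))
  # below the cap, values are untouched
  for (j in 1:5) {
    cap <- sort(m0[, j], decreasing = TRUE)[6]
    expect_equal(m1[m0[, j] <= cap, j], m0[m0[, j] <= cap, j])
  }
  expect_error(winsorize_counts(toy_counts(), 5), "more than")
})

test_that("relative abundances sum to one per sample", {
  m <- matrix(c(2, 3, 5), nrow = 1, dimnames = list("S1", c("a", "b", "c")))
  rel <- relative_abundance(make_counts(m))
  expect_equal(unname(dustdab:::counts_matrix(rel)[1, ]), c(0.2, 0.3, 0.5))

  single <- matrix(c(5, 9), ncol = 1, dimnames = list(c("S1", "S2"), "only"))
  expect_equal(unname(dustdab:::counts_matrix(relative_abundance(make_counts(single)))),
               matrix(1, 2, 1), ignore_attr = TRUE)

  cfg <- sim_config(n_samples = 30, n_taxa = 20, seed = 12)
  rel2 <- dustdab:::counts_matrix(relative_abundance(simulate_counts(cfg)))
  expect_true(all(abs(rowSums(rel2) - 1) < 1e-12))

  zero <- matrix(c(1, 0), ncol = 1, dimnames = list(c("S1", "S2"), "t"))
  expect_error(relative_abundance(make_counts(zero)), "S2")
})

test_that("standardization centers and scales, drops constants, is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(0, 1, 5))
  rownames(x) <- paste0("S", 1:3)
  y <- c(10, 20, 40)
  expect_warning(d <- standardize_design(x, y), "constant")
  expect_equal(d$dropped_taxa, "b")
  expect_lt(max(abs(colMeans(d$X))), 1e-10)
  expect_lt(max(abs(apply(d$X, 2, sd) - 1)), 1e-10)
  expect_equal(unname(d$X[, "a"]), c(-1, 0, 1))
  expect_lt(abs(mean(d$y)), 1e-10)
  expect_lt(abs(sd(d$y) - 1), 1e-10)
  # idempotence on already-standardized input
  d2 <- standardize_design(d$X, d$y)
  expect_equal(d2$X[, ], d$X[, ], ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(standardize_design(x[, 1, drop = FALSE], rep(1, 3)),
               "zero variance")
})

test_that("FeNO transform imputes LOD/sqrt(2) = 3.5 then takes natural logs", {
  v <- transform_feno(c(2, 5, 12), lod = 5)
  expect_equal(v[1], log(3.5))
  expect_equal(v[2], log(5))
  expect_equal(v[3], log(12))
  # explicit censoring flags; two censored entries transform identically
  v2 <- transform_feno(c(NA, NA, 8), below_lod = c(TRUE, TRUE, FALSE))
  expect_equal(v2[1], v2[2])
  expect_equal(v2[1], log(3.5))
  expect_error(transform_feno(c(-1, 6), below_lod = c(FALSE, FALSE)),
               "negative")
})

test_that("covariate rosters differ by outcome as specified", {
  meta <- toy_meta(15)
  z_fev1 <- build_covariates(meta, "fev1")
  z_fvc <- build_covariates(meta, "fvc")
  z_feno <- build_covariates(meta, "feno")
  expect_equal(ncol(z_fvc), ncol(z_fev1) + 1)
  expect_true("weight" %in% colnames(z_fvc))
  expect_false("weight" %in% colnames(z_fev1))
  expect_false(any(c("age_sq", "height_sq") %in% colnames(z_feno)))
  expect_true(all(c("age_sq", "height_sq") %in% colnames(z_fev1)))
  z_seas <- build_covariates(meta, "fev1", season_sensitivity = TRUE)
  expect_equal(ncol(z_seas), ncol(z_fev1) + 1)
  expect_true("season_winter" %in% colnames(z_seas))
  expect_identical(colnames(build_covariates(meta, "fev1_fvc")),
                   colnames(z_fev1))
})
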