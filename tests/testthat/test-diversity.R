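# Rarefaction, alpha diversity, and covariate-adjusted association.

div_counts <- function(m) {
  taxa <- colnames(m)
  tibble::tibble(
    taxon_id = taxa,
    lineage = sprintf("k__Bacteria;p__P;c__C;o__O;f__F;g__%s", taxa)
  ) |> dplyr::bind_cols(tibble::as_tibble(t(m), .name_repair = "minimal") |>
                          setNames(rownames(m)))
}

test_that("rarefaction conserves depth, is seeded, and errors on short samples", {
  m <- rbind(S1 = c(10, 0, 0), S2 = c(40, 30, 30), S3 = c(5, 3, 2))
  colnames(m) <- c("a", "b", "c")
  counts <- div_counts(m)
  r <- rarefy_counts(counts, depth = 5, seed = 2)
  rm <- dustdab:::counts_matrix(r)
  expect_equal(unname(rowSums(rm)), c(5, 5, 5))
  expect_equal(unname(rm["S1", ]), c(5, 0, 0))  # single nonzero taxon
  expect_identical(r, rarefy_counts(counts, depth = 5, seed = 2))
  # depth = sample total is the identity on that sample
  r10 <- dustdab:::counts_matrix(rarefy_counts(counts, depth = 10, seed = 1))
  expect_equal(unname(r10["S1", ]), c(10, 0, 0))
  expect_error(rarefy_counts(counts, depth = 11), "S1")
  # auto depth = minimum sample total
  ra <- dustdab:::counts_matrix(rarefy_counts(counts, depth = "auto", seed = 1))
  expect_true(all(rowSums(ra) == 10))
})

test_that("rarefied counts have the hypergeometric mean", {
  m <- rbind(S1 = c(60, 30, 10))
  colnames(m) <- c("a", "b", "c")
  counts <- div_counts(m)
  draws <- vapply(1:200, function(s) {
    dustdab:::counts_matrix(rarefy_counts(counts, depth = 20, seed = s))[1, "a"]
  }, numeric(1))
  # E = 20 * 0.6 = 12; hypergeometric SD ~1.97, MC SD of the mean ~0.14
  expect_lt(abs(mean(draws) - 12), 3 * 1.97 / sqrt(200))
})

test_that("richness and Shannon match direct formula evaluation", {
  m <- rbind(S1 = rep(3, 10),                   # uniform over 10 taxa
             S2 = c(7, rep(0, 9)),              # single taxon
             S3 = c(1, 1, 2, rep(0, 7)),
             S4 = rep(0, 10))
  colnames(m) <- paste0("t", 1:10)
  div <- alpha_diversity(div_counts(m))
  expect_equal(div$richness, c(10L, 1L, 3L, 0L))
  expect_equal(div$shannon[1], log(10))
  expect_equal(div$shannon[2], 0)
  expect_equal(div$shannon[3],
               -(0.25 * log(0.25) + 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_equal(div$shannon_exp, exp(div$shannon))
  # permutation invariance and zero-taxon padding
  perm <- m[, sample(10)]
  colnames(perm) <- paste0("t", 1:10)
  expect_equal(alpha_diversity(div_counts(perm))$shannon, div$shannon)
  padded <- cbind(m, t11 = 0)
  expect_equal(alpha_diversity(div_counts(padded))$shannon, div$shannon)
  # effective species number lies in [1, S] for nonempty samples
  expect_true(all(div$shannon_exp[1:3] >= 1 &
                    div$shannon_exp[1:3] <= pmax(div$richness[1:3], 1)))
})

test_that("diversity association matches a brute-force OLS oracle", {
  meta <- toy_meta(120, seed = 6)
  set.seed(60)
  div <- tibble::tibble(sample_id = meta$sample_id,
                        richness = rpois(120, 200),
                        shannon = runif(120, 3, 5))
  div$shannon_exp <- exp(div$shannon)
  meta$fev1 <- 2000 + 2 * div$shannon_exp + rnorm(120, 0, 150)
  a <- associate_diversity(div, meta, "fev1", "shannon_exp")
  z <- build_covariates(meta, "fev1")
  oracle <- ols_oracle(cbind(m = div$shannon_exp), meta$fev1, z)
  expect_equal(a$estimate, unname(oracle$coef), tolerance = 1e-8)
  expect_equal(a$se, unname(oracle$se), tolerance = 1e-8)

  # noiseless limit: slope -> 2
  meta2 <- meta
  meta2$fev1 <- 2 * div$shannon_exp + 1e-9 * rnorm(120)
  a2 <- associate_diversity(div, meta2, "fev1", "shannon_exp")
  expect_equal(a2$estimate, 2, tolerance = 1e-6)
})

test_that("diversity slope p-values are uniform under the null", {
  meta <- toy_meta(150, seed = 3)
  div <- tibble::tibble(sample_id = meta$sample_id,
                        richness = 1L, shannon = 0,
                        shannon_exp = withr::with_seed(30, runif(150, 30, 90)))
  z <- build_covariates(meta, "fev1")
  pvals <- withr::with_seed(31, vapply(1:500, function(r) {
    meta$fev1 <- 2500 + 0.5 * meta$age + rnorm(150, 0, 400)
    associate_diversity(div, meta, "fev1", "shannon_exp")$p_value
  }, numeric(1)))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("run_diversity composes rarefaction, measures, and associations", {
  cfg <- sim_config(n_samples = 100, n_taxa = 40, seed = 23)
  sim <- simulate_dust_study(cfg, outcomes = "fev1")
  out <- run_diversity(sim$counts, sim$meta, outcomes = "fev1", seed = 5)
  expect_equal(nrow(out$diversity), 100)
  expect_equal(nrow(out$associations), 2)
  expect_true(all(out$associations$p_value >= 0 & out$associations$p_value <= 1))
})
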