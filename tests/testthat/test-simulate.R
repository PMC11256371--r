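# Synthetic dust-metagenome generator: determinism, marginal targets,
# and the planted-outcome model.

test_that("simulated counts are seed-deterministic and conserve drawn depths", {
  cfg <- sim_config(n_samples = 200, n_taxa = 100, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a, b)
  m <- dustdab:::counts_matrix(a)
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(unname(rowSums(m)), unname(attr(a, "depths")))
  expect_true(all(rowSums(m) >= 1))
})

test_that("equal composition at fixed depth gives near-equal cells", {
  cfg <- sim_config(n_samples = 2, n_taxa = 3, n_causal = 0,
                    concentration = 1e8,
                    depth_log_mean = log(300), depth_log_sd = 0, seed = 3)
  m <- dustdab:::counts_matrix(simulate_counts(cfg))
  expect_equal(unname(rowSums(m)), c(300, 300))
  # multinomial SD at p = 1/3, N = 300 is ~8; allow 5 SDs
  expect_true(all(abs(m - 100) < 41))
})

test_that("default-scale table matches the zero-fraction and dominance bands", {
  cfg <- sim_config(seed = 2)
  m <- dustdab:::counts_matrix(simulate_counts(cfg))
  expect_equal(dim(m), c(779, 389))
  zf <- mean(m == 0)
  expect_gt(zf, 0.15)
  expect_lt(zf, 0.40)
  top3 <- sum(sort(colSums(m), decreasing = TRUE)[1:3]) / sum(m)
  expect_gte(top3, 0.20)
  # depths heavily skewed: mean around 2e5, minimum near 1000
  d <- rowSums(m)
  expect_gt(mean(d), 5e4)
  expect_lt(min(d), 5e3)
})

test_that("zero fraction is monotone decreasing in Dirichlet concentration", {
  zf <- vapply(c(0.05, 0.5, 5), function(a) {
    cfg <- sim_config(n_samples = 150, n_taxa = 80, concentration = a,
                      seed = 11)
    mean(dustdab:::counts_matrix(simulate_counts(cfg)) == 0)
  }, numeric(1))
  expect_true(all(diff(zf) < 0))
})

test_that("simulated covariates match the study population marginals", {
  cov <- simulate_covariates(10000, seed = 5)
  expect_identical(cov, simulate_covariates(10000, seed = 5))
  expect_lt(abs(mean(cov$sex == "male") - 0.60), 0.02)
  expect_lt(abs(mean(cov$age) - 62), 0.5)
  expect_true(all(cov$pack_years[cov$smoking == "never"] == 0, na.rm = TRUE))
  expect_true(mean(cov$smoking == "never") > 0.6)
})

test_that("outcome generator: global null, noiseless limit, OLS recovery", {
  # global null: latent outcome is iid N(0,1)
  cfg0 <- sim_config(n_samples = 400, n_taxa = 50, n_causal = 0,
                     covariate_effects = c(0, 0, 0), noise_sd = 1, seed = 9)
  counts <- simulate_counts(cfg0)
  covars <- simulate_covariates(400, seed = 9)
  res0 <- simulate_outcomes(counts, covars, cfg0, outcome = "fev1")
  lat <- attr(res0$truth, "latent")
  expect_lt(abs(mean(lat)), 4 / sqrt(400))
  expect_equal(nrow(res0$truth), 0)

  # noiseless limit: latent correlates ~1 with the causal standardized taxon
  cfg1 <- sim_config(n_samples = 300, n_taxa = 40, n_causal = 1,
                     effect_sizes = 0.5, covariate_effects = c(0, 0, 0),
                     noise_sd = 1e-8, seed = 13)
  counts1 <- simulate_counts(cfg1)
  covars1 <- simulate_covariates(300, seed = 13)
  res1 <- simulate_outcomes(counts1, covars1, cfg1, outcome = "fev1")
  x <- dustdab:::counts_matrix(counts1)[covars1$sample_id, ]
  x <- dustdab:::winsorize_matrix(x, 5)
  xs <- scale(x / rowSums(x))
  r <- cor(attr(res1$truth, "latent"), xs[, res1$truth$taxon_id])
  expect_gt(abs(r), 0.999)

  # planted effects recovered by OLS on the true support at n = 1000
  cfg2 <- sim_config(n_samples = 1000, n_taxa = 50, n_causal = 3,
                     effect_sizes = c(0.5, -0.4, 0.3), seed = 17)
  counts2 <- simulate_counts(cfg2)
  covars2 <- simulate_covariates(1000, seed = 17)
  res2 <- simulate_outcomes(counts2, covars2, cfg2, outcome = "fev1")
  x2 <- dustdab:::counts_matrix(counts2)[covars2$sample_id, ]
  x2 <- dustdab:::winsorize_matrix(x2, 5)
  xs2 <- scale(x2 / rowSums(x2))
  zg <- scale(cbind(covars2$age, as.numeric(covars2$sex == "male"),
                    covars2$height))
  fit <- lm(attr(res2$truth, "latent") ~ xs2[, res2$truth$taxon_id] + zg)
  expect_true(all(abs(coef(fit)[2:4] - res2$truth$effect) < 0.05))
})

test_that("outcome generator rejects mismatched sample ids", {
  cfg <- sim_config(n_samples = 20, n_taxa = 10, n_causal = 1,
                    effect_sizes = 0.3, seed = 1)
  counts <- simulate_counts(cfg)
  covars <- simulate_covariates(20, seed = 1)
  covars$sample_id[1] <- "nope"
  expect_error(simulate_outcomes(counts, covars, cfg), "sample ids")
})

test_that("full study wrapper keeps FEV1 <= FVC by construction", {
  cfg <- sim_config(n_samples = 120, n_taxa = 30, seed = 21)
  sim <- simulate_dust_study(cfg, outcomes = c("fev1", "fvc", "fev1_fvc"))
  expect_true(all(sim$meta$fev1 <= sim$meta$fvc))
  expect_true(all(sim$meta$fev1_fvc > 0 & sim$meta$fev1_fvc <= 1))
  expect_named(sim$truth, c("fvc", "fev1_fvc"))
})
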