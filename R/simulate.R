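# Synthetic dust-metagenome generator.
#
# Emulates the empirical shape of a post-classification, post-decontamination
# genus-level count table from vacuumed bedroom dust: n ~ 779 samples,
# p ~ 389 genera, heavily skewed per-sample sequencing depths (log-normal,
# minimum near 975 reads, mean near 2e5), roughly a quarter of cells zero, and
# a few dominant genera jointly holding ~30% of all reads. Compositions are
# Dirichlet-multinomial with a two-knob concentration vector: a steep
# power-law "head" sets dominance, a constant baseline sets the zero fraction.

SIM_PHYLA <- c("Proteobacteria", "Actinobacteria", "Firmicutes",
               "Bacteroidetes", "Cyanobacteria", "Acidobacteria")
SIM_PHYLUM_PROB <- c(0.38, 0.32, 0.16, 0.10, 0.025, 0.015)

#' Configuration for the synthetic dust-metagenome study
#'
#' Defaults reproduce the shape of the post-filtering study table: 779
#' samples, 389 genus-level taxa, log-normal sequencing depths with mean
#' ~2e5 reads and minimum near 975, ~25% zero cells, and the three most
#' abundant taxa holding ~30% of all reads.
#'
#' @param n_samples,n_taxa Table dimensions.
#' @param n_causal Number of taxa with planted outcome effects.
#' @param effect_sizes Planted slopes on the centered/scaled relative-abundance
#'   scale, in outcome-noise units; length `n_causal`. Default alternates
#'   +/-0.4.
#' @param depth_log_mean,depth_log_sd Log-normal depth parameters (log reads).
#' @param concentration Dirichlet concentration: `NULL` for the default
#'   heavy-tailed vector `base + head * rank^-2`, a scalar (recycled), or a
#'   length-`n_taxa` vector.
#' @param concentration_base,concentration_head Knobs of the default
#'   concentration vector; the baseline controls the zero fraction, the head
#'   controls dominance.
#' @param noise_sd Outcome residual standard deviation.
#' @param covariate_effects Length-3 vector of effects of standardized (age,
#'   male sex, height) on the latent outcome.
#' @param seed Integer seed; together with fixed per-operation offsets it
#'   fully determines all generator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 779, n_taxa = 389, n_causal = 5,
                       effect_sizes = NULL,
                       depth_log_mean = 11.17, depth_log_sd = 1.43,
                       concentration = NULL,
                       concentration_base = 0.22, concentration_head = 35,
                       noise_sd = 1,
                       covariate_effects = c(-0.3, 0.2, 0.3),
                       seed = 1) {
  if (n_samples < 1 || n_taxa < 1) {
    abort("n_samples and n_taxa must be positive")
  }
  if (n_causal > n_taxa) abort("n_causal must not exceed n_taxa")
  if (is.null(effect_sizes)) {
    effect_sizes <- rep(c(0.4, -0.4), length.out = n_causal)
  }
  if (length(effect_sizes) != n_causal) {
    abort("effect_sizes must have length n_causal")
  }
  if (length(covariate_effects) != 3) {
    abort("covariate_effects must have length 3 (age, male sex, height)")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    n_causal = as.integer(n_causal), effect_sizes = effect_sizes,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    concentration = concentration,
    concentration_base = concentration_base,
    concentration_head = concentration_head,
    noise_sd = noise_sd, covariate_effects = covariate_effects,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_concentration <- function(config) {
  p <- config$n_taxa
  a <- config$concentration
  if (is.null(a)) {
    return(config$concentration_base +
             config$concentration_head * seq_len(p)^(-2))
  }
  if (length(a) == 1) return(rep(a, p))
  if (length(a) != p) abort("concentration must be scalar or length n_taxa")
  a
}

# synthetic but well-formed lineage strings (kingdom -> genus)
sim_lineages <- function(p) {
  # deterministic phylum assignment approximating observed phylum shares
  cum <- cumsum(SIM_PHYLUM_PROB) / sum(SIM_PHYLUM_PROB)
  u <- ((seq_len(p) * 0.6180339887) %% 1)  # low-discrepancy, seed-free
  phy <- SIM_PHYLA[findInterval(u, cum) + 1]
  fam <- sprintf("%s_fam%02d", substr(phy, 1, 4), 1 + (seq_len(p) - 1) %/% 5)
  genus <- sprintf("Genus_%03d", seq_len(p))
  lin <- sprintf("k__Bacteria;p__%s;c__%s_c;o__%s_o;f__%s;g__%s",
                 phy, phy, phy, fam, genus)
  setNames(lin, genus)
}

#' Simulate a taxon-by-sample count table
#'
#' Each sample's depth is log-normal (rounded, floored at 1 read); its counts
#' are multinomial draws at that depth from a sample-specific
#' Dirichlet-composition. Row sums equal the drawn depths exactly, and the
#' whole table is a deterministic function of `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A count table tibble (taxa as rows) with synthetic genus-level
#'   lineages; drawn depths are attached as `attr(, "depths")`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  p <- config$n_taxa
  alpha <- sim_concentration(config)
  m <- withr::with_seed(derive_seed(config$seed, 202), {
    depths <- pmax(1, round(rlnorm(n, config$depth_log_mean,
                                   config$depth_log_sd)))
    out <- matrix(0, n, p)
    for (i in seq_len(n)) {
      g <- rgamma(p, shape = alpha)
      out[i, ] <- as.numeric(rmultinom(1, depths[i], g / sum(g)))
    }
    out
  })
  lineages <- sim_lineages(p)
  rownames(m) <- sprintf("S%04d", seq_len(n))
  colnames(m) <- names(lineages)
  res <- counts_from_matrix(m, lineages)
  attr(res, "depths") <- setNames(rowSums(m), rownames(m))
  res
}

#' Simulate sample covariates
#'
#' Draws age, sex, height, weight, smoking status, pack-years, asthma, state,
#' ancestry and season with marginals matching the study population (age
#' 62 +/- 11 years, 60% male, 65/29/6% never/former/current smokers, 38%
#' asthma, 32% NC, 96% European ancestry, 23% winter collection). A small
#' fraction of pack-years values is missing, mirroring the two participants
#' excluded from the study analyses.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A sample-frame tibble (no outcome columns yet).
#' @export
simulate_covariates <- function(n, seed = 1) {
  if (n < 1) abort("n must be >= 1")
  withr::with_seed(derive_seed(seed, 101), {
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.65, 0.29, 0.06))
    pack_years <- ifelse(smoking == "never", 0,
                         rgamma(n, shape = 0.834, scale = 25.19))
    pack_years[runif(n) < 2 / 779] <- NA
    tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = rnorm(n, 62, 11),
      sex = factor(ifelse(runif(n) < 0.60, "male", "female"),
                   levels = META_LEVELS$sex),
      height = rnorm(n, 171, 10),
      weight = pmax(40, rnorm(n, 90, 21)),
      smoking = factor(smoking, levels = META_LEVELS$smoking),
      pack_years = pack_years,
      asthma = factor(ifelse(runif(n) < 0.38, "yes", "no"),
                      levels = META_LEVELS$asthma),
      state = factor(ifelse(runif(n) < 0.32, "NC", "IA"),
                     levels = META_LEVELS$state),
      ancestry = factor(ifelse(runif(n) < 0.96, "european", "other"),
                        levels = META_LEVELS$ancestry),
      season = factor(ifelse(runif(n) < 0.23, "winter", "other"),
                      levels = META_LEVELS$season),
      feno_below_lod = FALSE
    )
  })
}

# unit maps from the latent standardized outcome to reporting units
SIM_UNIT_MAPS <- list(
  fev1     = list(intercept = 2649, slope = 853),
  fvc      = list(intercept = 3620, slope = 1036),
  fev1_fvc = list(intercept = 0.73, slope = 0.10),
  feno     = list(intercept = 2.80, slope = 0.70)  # on the ln-ppb scale
)

#' Simulate an outcome with planted taxon effects
#'
#' The latent outcome is a linear model on the centered/scaled taxon
#' relative-abundance matrix -- after exactly the preprocessing the inference
#' applies (winsorization, compositional transform, standardization) -- plus
#' standardized covariate effects and Gaussian noise, so planted coefficients
#' live on the same scale the debiased Lasso estimates. The latent value is
#' then affinely mapped to the outcome's reporting units (ml for FEV1/FVC,
#' (0,1] for the ratio, ppb for FeNO via `exp()`; FeNO values below 5 ppb are
#' flagged below-LOD).
#'
#' @param counts A count table sharing sample ids with `covars`.
#' @param covars A sample frame, e.g. from [simulate_covariates()].
#' @param config A [sim_config()].
#' @param outcome One of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"feno"`.
#' @return A list with `meta` (the sample frame with the outcome filled in)
#'   and `truth` (a tibble of causal taxa and planted effects; the latent
#'   unit map, noise SD and covariate effects are carried as attributes).
#' @export
simulate_outcomes <- function(counts, covars, config, outcome = "fev1") {
  stopifnot(inherits(config, "sim_config"))
  outcome <- match.arg(outcome, names(SIM_UNIT_MAPS))
  m <- counts_matrix(counts)
  if (!setequal(rownames(m), covars$sample_id)) {
    abort("counts and covariates do not share the same sample ids")
  }
  m <- m[covars$sample_id, , drop = FALSE]
  n <- nrow(m)

  if (n >= 7) m <- winsorize_matrix(m, k_top = 5)
  rel <- m / rowSums(m)
  sds <- apply(rel, 2, sd)
  keep <- which(sds > 0)
  if (length(keep) < config$n_causal) {
    abort("fewer non-constant taxa than n_causal")
  }
  x_std <- scale(rel[, keep, drop = FALSE])

  zg <- cbind(age = covars$age,
              sex_male = as.numeric(covars$sex == "male"),
              height = covars$height)
  zg <- scale(zg)
  zg[is.nan(zg)] <- 0  # constant covariate at tiny n

  seed_op <- derive_seed(config$seed, 303 + match(outcome, names(SIM_UNIT_MAPS)))
  y <- withr::with_seed(seed_op, {
    causal <- sort(sample(length(keep), config$n_causal))
    ylat <- drop(zg %*% config$covariate_effects) +
      drop(x_std[, causal, drop = FALSE] %*% config$effect_sizes) +
      rnorm(n, 0, config$noise_sd)
    list(ylat = ylat, causal = causal)
  })
  causal_ids <- colnames(x_std)[y$causal]
  ylat <- y$ylat

  map <- SIM_UNIT_MAPS[[outcome]]
  meta <- covars
  if (outcome == "feno") {
    ppb <- exp(map$intercept + map$slope * ylat)
    meta$feno <- ppb
    meta$feno_below_lod <- ppb < 5
  } else if (outcome == "fev1_fvc") {
    meta$fev1_fvc <- pmin(pmax(map$intercept + map$slope * ylat, 0.05), 1)
  } else {
    # volumes floored at a physiological minimum (extreme latent tail only)
    meta[[outcome]] <- pmax(map$intercept + map$slope * ylat, 200)
  }

  truth <- tibble(taxon_id = causal_ids,
                  effect = config$effect_sizes,
                  outcome = outcome)
  attr(truth, "noise_sd") <- config$noise_sd
  attr(truth, "covariate_effects") <- config$covariate_effects
  attr(truth, "unit_map") <- map
  attr(truth, "latent") <- ylat
  list(meta = meta, truth = truth)
}

#' Simulate a complete synthetic dust study
#'
#' Convenience wrapper: covariates, counts, then outcomes. When both `fvc`
#' and `fev1_fvc` are requested together with `fev1`, FEV1 is derived as
#' `fvc * fev1_fvc` so that the physiological constraint FEV1 <= FVC holds by
#' construction (its planted truth is then inherited from the two parents).
#'
#' @param config A [sim_config()].
#' @param outcomes Character vector of outcomes to generate.
#' @return A list with `counts`, `meta` and `truth` (named list per outcome).
#' @export
simulate_dust_study <- function(config = sim_config(), outcomes = "fev1") {
  counts <- simulate_counts(config)
  meta <- simulate_covariates(config$n_samples, seed = config$seed)
  truth <- list()
  derive_fev1 <- all(c("fev1", "fvc", "fev1_fvc") %in% outcomes)
  direct <- if (derive_fev1) setdiff(outcomes, "fev1") else outcomes
  for (oc in direct) {
    res <- simulate_outcomes(counts, meta, config, outcome = oc)
    meta <- res$meta
    truth[[oc]] <- res$truth
  }
  if (derive_fev1) {
    meta$fev1 <- meta$fvc * meta$fev1_fvc
  }
  list(counts = counts, meta = meta, truth = truth)
}

#' Write the planted-truth sidecar
#'
#' @param truth A truth tibble from [simulate_outcomes()], or a named list of
#'   them from [simulate_dust_study()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (is.data.frame(truth)) truth <- list(truth)
  readr::write_tsv(dplyr::bind_rows(truth), path, progress = FALSE)
  invisible(path)
}
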