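# Simulation studies for the debiased-Lasso engine: type-I error calibration
# under the global null, confidence-interval coverage, and power to recover
# planted taxon effects through the full pipeline.
#
# Calibration and coverage condition on a single fixed Gaussian design: the
# nodewise precision estimate depends only on X, so it is computed once and
# reused across replicates, while the outcome (and the cross-validated
# penalty) is redrawn every replicate.

#' Type-I error calibration under the global null
#'
#' Draws a fixed standardized Gaussian design, estimates the nodewise
#' precision matrix once (per-column cross-validation), then for each
#' replicate draws an outcome independent of every predictor, selects the
#' Lasso penalty by fivefold cross-validation, and debiases. Reports the
#' pooled per-taxon rejection rate at the 0.05 level and a
#' Kolmogorov-Smirnov test of p-value uniformity.
#'
#' @param n,p Design dimensions.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param n_folds Cross-validation folds.
#' @return A list: `rejection_rate`, `ks_p` (pooled KS uniformity p-value),
#'   `p_values` (replicates x taxa matrix), and the study dimensions.
#' @export
sim_type1_calibration <- function(n = 400, p = 100, n_reps = 500, seed = 1,
                                  n_folds = 5) {
  x <- withr::with_seed(derive_seed(seed, 701),
                        matrix(rnorm(n * p), n, p,
                               dimnames = list(NULL, paste0("V", seq_len(p)))))
  x <- scale(x)
  nw <- nodewise_theta(x, lambda = "cv", n_folds = n_folds, seed = seed)

  pvals <- matrix(NA_real_, n_reps, p)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 10000 + r)
    y <- withr::with_seed(rs, rnorm(n))
    design <- standardize_design(x, y)
    cv <- choose_lambda(design, n_folds = n_folds, seed = rs)
    fit <- fit_lasso(design, cv$lambda)
    pvals[r, ] <- debias_lasso(fit, nw, design)$p_value
  }
  list(rejection_rate = mean(pvals < 0.05),
       ks_p = suppressWarnings(ks.test(as.numeric(pvals), "punif"))$p.value,
       p_values = pvals, n = n, p = p, n_reps = n_reps)
}

#' Confidence-interval coverage of the debiased Lasso
#'
#' Fixed standardized Gaussian design with `s` planted coefficients; each
#' replicate redraws unit-variance Gaussian noise, re-selects the penalty by
#' cross-validation and debiases. Coverage is the fraction of 95% intervals
#' `b +/- 1.96 se` containing the true coefficient, pooled over coordinates
#' and replicates, and split by null/non-null status.
#'
#' @param n,p Design dimensions.
#' @param s Number of non-null coefficients.
#' @param effects Planted values for the `s` non-null coordinates.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param n_folds Cross-validation folds.
#' @return A list with `coverage`, `coverage_null`, `coverage_nonnull` and
#'   the study dimensions.
#' @export
sim_ci_coverage <- function(n = 400, p = 100, s = 5,
                            effects = c(0.5, -0.5, 0.4, -0.4, 0.3),
                            n_reps = 500, seed = 1, n_folds = 5) {
  stopifnot(length(effects) == s)
  x <- withr::with_seed(derive_seed(seed, 801),
                        matrix(rnorm(n * p), n, p,
                               dimnames = list(NULL, paste0("V", seq_len(p)))))
  x <- scale(x)
  support <- withr::with_seed(derive_seed(seed, 802), sort(sample(p, s)))
  beta <- rep(0, p)
  beta[support] <- effects
  signal <- drop(x %*% beta)
  nw <- nodewise_theta(x, lambda = "cv", n_folds = n_folds, seed = seed)

  covered <- matrix(NA, n_reps, p)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 30000 + r)
    y <- signal + withr::with_seed(rs, rnorm(n))
    design <- standardize_design(x, y, scale_y = FALSE)
    cv <- choose_lambda(design, n_folds = n_folds, seed = rs)
    fit <- fit_lasso(design, cv$lambda)
    res <- debias_lasso(fit, nw, design)
    covered[r, ] <- abs(res$coefficient - beta) <= 1.96 * res$se
  }
  is_null <- !(seq_len(p) %in% support)
  list(coverage = mean(covered),
       coverage_null = mean(covered[, is_null]),
       coverage_nonnull = mean(covered[, !is_null]),
       n = n, p = p, s = s, n_reps = n_reps)
}

#' Power to recover planted effects through the full pipeline
#'
#' Each replicate simulates a complete synthetic study (Dirichlet-multinomial
#' counts, covariates, an outcome with planted standardized taxon effects)
#' and runs the entire differential-abundance chain via [dab()]. A planted
#' effect counts as detected when its taxon is significant at p < 0.05 with
#' the correct sign.
#'
#' @param n,p Study dimensions (samples, taxa).
#' @param effects Planted standardized effects (length = number of causal
#'   taxa).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param nodewise_lambda Nodewise penalty strategy passed to [dab()].
#' @return A list: `detection_rate` (pooled over planted effects and
#'   replicates), `all_detected_rate` (replicates where every planted effect
#'   was detected), `mean_false_positives`, and the study dimensions.
#' @export
sim_power <- function(n = 400, p = 100, effects = c(0.3, -0.3, 0.4),
                      n_reps = 200, seed = 1,
                      nodewise_lambda = "shared-cv") {
  s <- length(effects)
  detected <- matrix(NA, n_reps, s)
  fp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, 50000 + r)
    config <- sim_config(n_samples = n, n_taxa = p, n_causal = s,
                         effect_sizes = effects, seed = rs)
    sim <- simulate_dust_study(config, outcomes = "fev1")
    fit <- dab(sim$counts, sim$meta, "fev1", seed = rs, verbose = FALSE,
               nodewise_lambda = nodewise_lambda)
    res <- fit$results
    truth <- sim$truth$fev1
    hit <- vapply(seq_len(s), function(k) {
      row <- res[res$taxon_id == truth$taxon_id[k], ]
      nrow(row) == 1 && isTRUE(row$significant) &&
        sign(row$coefficient) == sign(truth$effect[k])
    }, logical(1))
    detected[r, ] <- hit
    fp[r] <- sum(res$significant & !(res$taxon_id %in% truth$taxon_id),
                 na.rm = TRUE)
  }
  list(detection_rate = mean(detected),
       all_detected_rate = mean(rowSums(detected) == s),
       mean_false_positives = mean(fp),
       n = n, p = p, s = s, n_reps = n_reps)
}
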