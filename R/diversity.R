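# Alpha diversity on rarefied counts and its covariate-adjusted association
# with continuous respiratory outcomes.

#' Rarefy a count table to a common depth
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric, via [vegan::rrarefy()]) to `depth`, removing
#' sequencing-depth bias before diversity is computed. Every rarefied sample
#' total equals `depth` exactly and the draw is deterministic given `seed`.
#'
#' @param counts A count table.
#' @param depth Target depth in reads, or `"auto"` for the minimum sample
#'   total.
#' @param seed Integer seed for the subsampling.
#' @return The rarefied count table.
#' @export
rarefy_counts <- function(counts, depth = "auto", seed = 1) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  tot <- rowSums(m)
  if (identical(depth, "auto")) depth <- min(tot)
  depth <- as.numeric(depth)
  short <- tot < depth
  if (any(short)) {
    abort(sprintf("rarefaction depth %g exceeds total reads of sample(s): %s",
                  depth, paste(rownames(m)[short], collapse = ", ")))
  }
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # transformed data); our inputs are validated integer counts, so muffle it
  r <- withr::with_seed(derive_seed(seed, 404), withCallingHandlers(
    vegan::rrarefy(m, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  counts_from_matrix(r, lineage_lookup(counts))
}

#' Per-sample alpha diversity
#'
#' Richness is the number of taxa observed (count > 0) in a sample; the
#' Shannon index H uses natural logarithms (nats), and its exponential
#' `exp(H)` -- the effective number of species -- is what enters association
#' models, countering the index's negative skew.
#'
#' @param counts A (typically rarefied) count table.
#' @return A tibble with `sample_id`, `richness`, `shannon`, `shannon_exp`.
#' @export
alpha_diversity <- function(counts) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  h <- vegan::diversity(m, index = "shannon")
  tibble(sample_id = rownames(m),
         richness = as.integer(vegan::specnumber(m)),
         shannon = as.numeric(h),
         shannon_exp = exp(as.numeric(h)))
}

#' Association of a diversity measure with an outcome
#'
#' Ordinary least squares of the outcome (FeNO ln-transformed with below-LOD
#' imputation) on the diversity measure plus the outcome's covariate roster,
#' on complete cases. Two-sided p-values use the t distribution; p < 0.05 is
#' the significance convention.
#'
#' @param div A diversity tibble from [alpha_diversity()].
#' @param meta A sample frame.
#' @param outcome One of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"feno"`.
#' @param measure `"richness"` or `"shannon_exp"`.
#' @param season_sensitivity Adjust additionally for season of collection.
#' @return A one-row tibble: outcome, measure, estimate, se, statistic,
#'   p_value, significant, n.
#' @export
associate_diversity <- function(div, meta, outcome,
                                measure = c("richness", "shannon_exp"),
                                season_sensitivity = FALSE) {
  measure <- match.arg(measure)
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  dat <- dplyr::inner_join(div, meta, by = "sample_id")
  if (nrow(dat) == 0) abort("no overlapping samples between div and meta")
  y <- if (outcome == "feno") {
    transform_feno(dat$feno, below_lod = dat$feno_below_lod)
  } else {
    dat[[outcome]]
  }
  z <- build_covariates(dat, outcome, season_sensitivity)
  x <- dat[[measure]]
  ok <- complete.cases(cbind(y, x, z))
  y <- y[ok]; x <- x[ok]; z <- z[ok, , drop = FALSE]
  if (length(y) <= ncol(z) + 2) abort("not enough complete cases to fit the model")

  fit <- lm(y ~ x + z)
  sm <- summary(fit)$coefficients["x", ]
  tibble(outcome = outcome, measure = measure,
         estimate = unname(sm[1]), se = unname(sm[2]),
         statistic = unname(sm[3]), p_value = unname(sm[4]),
         significant = unname(sm[4]) < 0.05, n = length(y))
}

#' Full diversity analysis
#'
#' Rarefies once with a recorded seed, computes per-sample richness and
#' Shannon diversity, and regresses each outcome on each measure with the
#' outcome's covariate roster.
#'
#' @param counts A filtered count table.
#' @param meta A sample frame.
#' @param outcomes Outcomes to analyze (default: all present in `meta`).
#' @param depth Rarefaction depth (`"auto"` = minimum sample total).
#' @param seed Integer seed for rarefaction.
#' @param season_sensitivity Adjust additionally for season.
#' @return A list with `diversity` (per-sample tibble) and `associations`
#'   (one row per outcome x measure).
#' @export
run_diversity <- function(counts, meta, outcomes = NULL, depth = "auto",
                          seed = 1, season_sensitivity = FALSE) {
  if (is.null(outcomes)) outcomes <- intersect(OUTCOME_NAMES, names(meta))
  rare <- rarefy_counts(counts, depth = depth, seed = seed)
  div <- alpha_diversity(rare)
  assoc <- purrr::map(outcomes, function(oc) {
    purrr::map(c("richness", "shannon_exp"), function(ms) {
      associate_diversity(div, meta, oc, ms,
                          season_sensitivity = season_sensitivity)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(diversity = div, associations = assoc)
}
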