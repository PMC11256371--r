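# End-to-end differential-abundance analysis: filter -> aggregate ->
# winsorize -> relative abundance -> standardize -> CV Lasso -> nodewise ->
# debias -> per-taxon tests.

#' Differential abundance of taxa for a continuous outcome
#'
#' Runs the full high-dimensional differential-abundance chain. Each taxon's
#' centered/scaled relative abundance is a predictor in a single Lasso
#' regression of the outcome (with unpenalized covariate adjustment); the
#' desparsified-Lasso correction then gives every taxon a coefficient,
#' standard error and two-sided p-value while controlling for all other taxa.
#' Significance uses p < 0.05 without multiplicity correction -- the joint
#' model already shrinks unimportant taxa -- but a BH-FDR column is included
#' for reference.
#'
#' @param counts A count table (see [read_count_table()]).
#' @param meta A sample frame (see [read_metadata()]).
#' @param outcome One of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"feno"`.
#' @param rank Taxonomic rank to aggregate to before testing (default
#'   `"genus"`).
#' @param seed Integer run seed; all stochastic stages (CV folds, nodewise
#'   folds) derive from it.
#' @param filter A [filter_spec()]; use zero thresholds to skip filtering.
#' @param k_top Winsorization order (top `k_top` counts per taxon capped at
#'   the next largest).
#' @param season_sensitivity Adjust additionally for season of collection.
#' @param nodewise_lambda Penalty selection for the nodewise regressions:
#'   `"shared-cv"` (default; cross-validates a column subset and shares the
#'   median penalty) or `"cv"` (per-column cross-validation), or a numeric
#'   value.
#' @param n_folds Cross-validation folds (default 5).
#' @param verbose Log one line per stage with dimensions.
#' @return A `dab_fit` with elements `results` (a tibble: phylum, family,
#'   genus, taxon_id, coefficient, se, z, p_value, p_adjust_bh, significant),
#'   `lambda`, `cv`, `sigma_hat`, `design` dimensions and a reproducibility
#'   `manifest`. Taxa dropped as constant after preprocessing appear with NA
#'   statistics.
#' @export
dab <- function(counts, meta, outcome, rank = "genus", seed = 1,
                filter = filter_spec(), k_top = 5,
                season_sensitivity = FALSE,
                nodewise_lambda = "shared-cv", n_folds = 5, verbose = TRUE) {
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  validate_counts(counts)
  counts_hash <- hash(counts)
  meta_hash <- hash(meta)
  say <- function(...) if (verbose) inform(sprintf(...))

  shared <- intersect(count_sample_ids(counts), meta$sample_id)
  if (length(shared) == 0) abort("counts and metadata share no samples")
  counts <- counts[c("taxon_id", "lineage", shared)]
  meta <- meta[match(shared, meta$sample_id), ]
  say("input: %d taxa x %d samples", nrow(counts), length(shared))

  filtered <- filter_counts(counts, filter, verbose = verbose)
  agg <- aggregate_rank(filtered, rank)
  say("aggregated to %s: %d taxa", rank, nrow(agg))

  # complete cases for this outcome's roster
  keep_samples <- count_sample_ids(agg)
  meta <- meta[match(keep_samples, meta$sample_id), ]
  y_raw <- if (outcome == "feno") {
    transform_feno(meta$feno, below_lod = meta$feno_below_lod)
  } else {
    meta[[outcome]]
  }
  z <- build_covariates(meta, outcome, season_sensitivity)
  ok <- complete.cases(cbind(y_raw, z))
  if (sum(!ok) > 0) say("dropping %d sample(s) with missing outcome/covariates",
                        sum(!ok))
  ids <- keep_samples[ok]
  agg <- agg[c("taxon_id", "lineage", ids)]
  y_raw <- y_raw[ok]
  z <- z[ok, , drop = FALSE]

  wins <- winsorize_counts(agg, k_top = k_top)
  rel <- relative_abundance(wins)
  design <- standardize_design(rel, y_raw, z)
  say("design: n = %d, p = %d (+%d constant taxa dropped), q = %d",
      design$n, design$p, length(design$dropped_taxa), design$q)

  cv <- choose_lambda(design, n_folds = n_folds, seed = seed)
  fit <- fit_lasso(design, cv$lambda)
  say("lasso: lambda = %.4g, support %d", cv$lambda, fit$s_hat)
  nw <- nodewise_theta(design$Xr, lambda = nodewise_lambda,
                       n_folds = n_folds, seed = seed)
  inference <- debias_lasso(fit, nw, design)

  lin <- lineage_lookup(agg)
  ranks <- parse_lineage(unname(lin[inference$taxon_id]))
  results <- dplyr::bind_cols(
    ranks[c("phylum", "family", "genus")], inference) |>
    dplyr::mutate(p_adjust_bh = stats::p.adjust(.data$p_value, "BH"),
                  .after = "p_value")

  dropped <- design$dropped_taxa
  if (length(dropped) > 0) {
    dr <- parse_lineage(unname(lin[dropped]))
    results <- dplyr::bind_rows(
      results,
      tibble(phylum = dr$phylum, family = dr$family, genus = dr$genus,
             taxon_id = dropped, coefficient = NA_real_, se = NA_real_,
             z = NA_real_, p_value = NA_real_, p_adjust_bh = NA_real_,
             significant = NA))
  }
  results <- dplyr::arrange(results, .data$phylum, .data$family, .data$genus)

  manifest <- list(
    package = "dustdab",
    version = as.character(packageVersion("dustdab")),
    seed = seed,
    outcome = outcome,
    rank = rank,
    season_sensitivity = season_sensitivity,
    filter = unclass(filter),
    k_top = k_top,
    n_folds = n_folds,
    nodewise_lambda = if (is.numeric(nodewise_lambda)) nodewise_lambda else
      as.character(nodewise_lambda),
    input = list(counts_hash = counts_hash, meta_hash = meta_hash,
                 n_taxa = nrow(counts), n_samples = length(shared)),
    stages = list(filtered = dim(counts_matrix(filtered)),
                  aggregated = nrow(agg),
                  complete_cases = design$n,
                  p_tested = design$p,
                  constant_taxa_dropped = length(dropped),
                  covariate_terms = design$q),
    lambda = cv$lambda,
    sigma_hat = attr(inference, "sigma_hat"),
    results_hash = hash(results)
  )

  structure(list(
    results = results, outcome = outcome, rank = rank,
    lambda = cv$lambda,
    cv = tibble(lambda = cv$grid, cvm = cv$cvm, cvsd = cv$cvsd),
    lasso = fit, nodewise_method = nw$method,
    sigma_hat = attr(inference, "sigma_hat"), df = attr(inference, "df"),
    n = design$n, p_tested = design$p, q = design$q,
    dropped_taxa = dropped, seed = seed, manifest = manifest
  ), class = "dab_fit")
}

#' @export
print.dab_fit <- function(x, ...) {
  nsig <- sum(x$results$significant, na.rm = TRUE)
  cat(sprintf("<dab_fit> outcome %s at %s level\n", x$outcome, x$rank))
  cat(sprintf("  n = %d samples, %d taxa tested, %d covariate terms\n",
              x$n, x$p_tested, x$q))
  cat(sprintf("  lambda = %.4g (5-fold CV), sigma_hat = %.3f\n",
              x$lambda, x$sigma_hat))
  cat(sprintf("  %d taxa differentially abundant at p < 0.05\n", nsig))
  invisible(x)
}

#' @rdname dab
#' @param x A `dab_fit`.
#' @param ... Unused.
#' @method tidy dab_fit
#' @export
tidy.dab_fit <- function(x, ...) {
  x$results
}

#' @rdname dab
#' @method glance dab_fit
#' @export
glance.dab_fit <- function(x, ...) {
  tibble(outcome = x$outcome, rank = x$rank, n = x$n, p_tested = x$p_tested,
         q = x$q, lambda = x$lambda, sigma_hat = x$sigma_hat,
         n_significant = sum(x$results$significant, na.rm = TRUE))
}

#' @rdname dab
#' @param object A `dab_fit`.
#' @method autoplot dab_fit
#' @export
autoplot.dab_fit <- function(object, ...) {
  plot_coefficient_heatmap(setNames(list(object$results), object$outcome))
}
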