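# Filtering, winsorization, compositional transform, outcome transforms and
# standardization: everything between the raw count table and the
# inference-ready design.

#' Filtering thresholds for samples and taxa
#'
#' @param min_sample_reads Samples with total reads strictly below this are
#'   dropped (default 1000).
#' @param min_taxon_fraction Taxa whose summed reads across retained samples
#'   are strictly below this fraction of the retained grand total are dropped.
#'   Default 5e-6, i.e. 0.0005%; taxa exactly at the threshold are retained.
#' @param excluded_kingdoms Kingdoms removed outright (default Eukaryota and
#'   viruses, which have limited reference-genome coverage).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_sample_reads = 1000,
                        min_taxon_fraction = 5e-6,
                        excluded_kingdoms = c("Eukaryota", "Viruses")) {
  if (min_sample_reads < 0 || min_taxon_fraction < 0) {
    abort("filter thresholds must be non-negative")
  }
  structure(list(min_sample_reads = min_sample_reads,
                 min_taxon_fraction = min_taxon_fraction,
                 excluded_kingdoms = excluded_kingdoms),
            class = "filter_spec")
}

#' Filter low-depth samples and rare taxa
#'
#' Applies, in order: (1) drop samples with total reads < `min_sample_reads`;
#' (2) drop taxa whose summed reads over the retained samples are
#' < `min_taxon_fraction` of the retained grand total; (3) drop taxa whose
#' lineage kingdom is excluded. Both thresholds are strict `<`, so boundary
#' samples/taxa are retained, and they are evaluated once (not iterated).
#'
#' @param counts A count table.
#' @param spec A [filter_spec()].
#' @param verbose Log the number removed at each step.
#' @return The filtered count table, with a `filter_log` attribute (a tibble
#'   of per-step removals).
#' @export
filter_counts <- function(counts, spec = filter_spec(), verbose = TRUE) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  log <- list()

  keep_s <- rowSums(m) >= spec$min_sample_reads
  log$samples_low_depth <- sum(!keep_s)
  m <- m[keep_s, , drop = FALSE]
  if (nrow(m) == 0) abort("all samples removed by the depth filter")

  grand <- sum(m)
  keep_t <- colSums(m) >= spec$min_taxon_fraction * grand
  log$taxa_rare <- sum(!keep_t)
  m <- m[, keep_t, drop = FALSE]

  lin <- lineage_lookup(counts)
  kingdom <- parse_lineage(unname(lin[colnames(m)]))$kingdom
  keep_k <- !(kingdom %in% spec$excluded_kingdoms)
  log$taxa_excluded_kingdom <- sum(!keep_k)
  m <- m[, keep_k, drop = FALSE]
  if (ncol(m) == 0) abort("all taxa removed by filtering")

  if (verbose) {
    inform(sprintf(
      "filter: removed %d low-depth sample(s), %d rare taxa, %d excluded-kingdom taxa; kept %d x %d",
      log$samples_low_depth, log$taxa_rare, log$taxa_excluded_kingdom,
      nrow(m), ncol(m)))
  }
  out <- counts_from_matrix(m, lin)
  attr(out, "filter_log") <- tibble(step = names(log),
                                    removed = unlist(log, use.names = FALSE))
  out
}

# winsorize columns (taxa) of a samples-by-taxa matrix: values above the
# (k_top+1)-th largest are capped at it; ties make the cap a no-op.
winsorize_matrix <- function(m, k_top = 5) {
  if (nrow(m) <= k_top + 1) {
    abort(sprintf("winsorization needs more than %d samples, got %d",
                  k_top + 1, nrow(m)))
  }
  for (j in seq_len(ncol(m))) {
    cap <- sort(m[, j], decreasing = TRUE)[k_top + 1]
    m[m[, j] > cap, j] <- cap
  }
  m
}

#' Winsorize extreme counts per taxon
#'
#' For each taxon, the `k_top` largest counts across samples are set to the
#' (`k_top` + 1)-th largest, damping the influence of extreme sequence-read
#' outliers on the regression. The operation never increases a cell and is
#' idempotent; when the cap ties with larger order statistics it is a no-op
#' on the tied cells.
#'
#' @param counts A count table with more than `k_top + 1` samples.
#' @param k_top Number of top values to cap per taxon (default 5).
#' @return The winsorized count table.
#' @export
winsorize_counts <- function(counts, k_top = 5) {
  validate_counts(counts)
  m <- winsorize_matrix(counts_matrix(counts), k_top = k_top)
  counts_from_matrix(m, lineage_lookup(counts))
}

#' Convert counts to within-sample relative abundances
#'
#' Each sample's counts are divided by that sample's total (the winsorized
#' total if winsorization was applied upstream), so per-sample abundances sum
#' to one.
#'
#' @param counts A count table with positive sample totals.
#' @return A tibble in count-table layout whose cells are fractions.
#' @export
relative_abundance <- function(counts) {
  validate_counts(counts)
  m <- counts_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("zero total reads in sample(s): %s",
                  paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  counts_from_matrix(m / tot, lineage_lookup(counts))
}

#' Transform FeNO measurements
#'
#' Below-LOD entries are imputed as LOD/sqrt(2) rounded to one decimal
#' (3.5 ppb at the default LOD of 5 ppb), then all values are natural-log
#' transformed for normality.
#'
#' @param values FeNO in ppb.
#' @param below_lod Logical flags for censored entries; by default, values
#'   strictly below `lod` are treated as censored.
#' @param lod Limit of detection in ppb (default 5).
#' @return The ln-ppb vector.
#' @export
transform_feno <- function(values, below_lod = NULL, lod = 5) {
  if (is.null(below_lod)) below_lod <- !is.na(values) & values < lod
  if (any(!below_lod & !is.na(values) & values < 0)) {
    abort("negative measured FeNO value")
  }
  imputed <- round(lod / sqrt(2), 1)
  values[below_lod] <- imputed
  log(values)
}

OUTCOME_NAMES <- c("fev1", "fvc", "fev1_fvc", "feno")

# covariate roster per outcome; FVC additionally adjusts for weight, FeNO
# drops the quadratic age and height terms
outcome_roster <- function(outcome, season_sensitivity = FALSE) {
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  base <- c("age", "age_sq", "sex_male", "height", "height_sq",
            "smoking_former", "smoking_current", "pack_years", "asthma_yes",
            "state_nc", "ancestry_noneuropean")
  if (outcome == "fvc") base <- append(base, "weight", after = 5)
  if (outcome == "feno") base <- setdiff(base, c("age_sq", "height_sq"))
  if (season_sensitivity) base <- c(base, "season_winter")
  base
}

#' Build the covariate matrix for an outcome
#'
#' Pulmonary-function models adjust for age, age squared, sex, height, height
#' squared, smoking status (former and current, each relative to never),
#' pack-years, asthma status, state of residence (NC, relative to IA) and
#' ancestry (non-European, relative to European); FVC additionally for
#' weight; FeNO models drop the quadratic age and height terms. In
#' sensitivity mode, a winter-season indicator is appended.
#'
#' @param meta A sample frame.
#' @param outcome One of `"fev1"`, `"fvc"`, `"fev1_fvc"`, `"feno"`.
#' @param season_sensitivity Append the season-of-collection indicator.
#' @return A numeric matrix with one named column per covariate term.
#' @export
build_covariates <- function(meta, outcome, season_sensitivity = FALSE) {
  roster <- outcome_roster(outcome, season_sensitivity)
  terms <- list(
    age = meta$age,
    age_sq = meta$age^2,
    sex_male = as.numeric(meta$sex == "male"),
    height = meta$height,
    height_sq = meta$height^2,
    weight = meta$weight,
    smoking_former = as.numeric(meta$smoking == "former"),
    smoking_current = as.numeric(meta$smoking == "current"),
    pack_years = meta$pack_years,
    asthma_yes = as.numeric(meta$asthma == "yes"),
    state_nc = as.numeric(meta$state == "NC"),
    ancestry_noneuropean = as.numeric(meta$ancestry == "other"),
    season_winter = as.numeric(meta$season == "winter")
  )
  z <- do.call(cbind, terms[roster])
  rownames(z) <- meta$sample_id
  z
}

#' Build the standardized regression design
#'
#' Centers and scales the taxon relative-abundance block `X` and the outcome
#' `y` to mean 0 and SD 1 (sample SD, divisor n-1); constant columns are
#' dropped with a warning. The covariate block `Z` is kept on its natural
#' scale and, together with an intercept, is projected out of both `X` and
#' `y` (Frisch-Waugh residualization), which makes the downstream penalized
#' fit equivalent to one in which covariates are unpenalized.
#'
#' @param x Samples-by-taxa matrix of relative abundances (or a count-table
#'   tibble of fractions).
#' @param y Outcome vector, already on its analysis scale.
#' @param z Optional covariate matrix from [build_covariates()].
#' @param scale_y Center/scale the outcome (default TRUE). Simulation studies
#'   that compare estimates against a known coefficient vector keep the
#'   outcome unscaled.
#' @return A `dab_design` object with the standardized blocks, the
#'   residualized blocks `Xr`, `yr`, and the centering/scaling vectors needed
#'   for back-transformation.
#' @export
standardize_design <- function(x, y, z = NULL, scale_y = TRUE) {
  if (is.data.frame(x)) x <- counts_matrix(x)
  if (anyNA(x) || anyNA(y) || (!is.null(z) && anyNA(z))) {
    abort("design inputs contain missing values; drop incomplete cases upstream")
  }
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  if (sd(y) == 0) abort("outcome has zero variance")

  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d constant taxon column(s): %s", length(dropped),
                 paste(head(dropped, 5), collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  x_std <- scale(x)
  y_center <- mean(y)
  y_scale <- if (scale_y) sd(y) else 1
  y_std <- (y - y_center) / y_scale

  m <- cbind(`(Intercept)` = rep(1, nrow(x_std)), z)
  qr_m <- qr(m)
  if (qr_m$rank < ncol(m)) abort("covariate matrix is rank deficient")
  xr <- qr.resid(qr_m, x_std)
  yr <- qr.resid(qr_m, y_std)

  structure(list(
    X = x_std, y = y_std, Z = z, Xr = xr, yr = yr,
    n = nrow(x_std), p = ncol(x_std), q = ncol(m),
    taxon_ids = colnames(x_std), sample_ids = rownames(x_std),
    column_means = attr(x_std, "scaled:center"),
    column_sds = attr(x_std, "scaled:scale"),
    y_center = y_center, y_scale = y_scale,
    dropped_taxa = dropped
  ), class = "dab_design")
}

#' @export
print.dab_design <- function(x, ...) {
  cat(sprintf("<dab_design> n = %d samples, p = %d taxa, q = %d covariate terms (incl. intercept)\n",
              x$n, x$p, x$q))
  if (length(x$dropped_taxa) > 0) {
    cat(sprintf("  %d constant taxon column(s) dropped\n", length(x$dropped_taxa)))
  }
  invisible(x)
}
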