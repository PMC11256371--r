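# Presentation-layer summaries: composition overviews, the coefficient
# heatmap and cross-outcome overlap of significant taxa.

#' Rank-level composition summary
#'
#' @param counts A count table.
#' @param rank Taxonomic rank to summarize at (default `"phylum"`).
#' @param per_sample If `TRUE` (default), per-sample relative abundances (one
#'   row per sample x rank, summing to 1 within sample); otherwise overall
#'   shares of total reads.
#' @return A tibble of relative abundances.
#' @export
summarize_composition <- function(counts, rank = "phylum", per_sample = TRUE) {
  agg <- aggregate_rank(counts, rank)
  m <- counts_matrix(agg)
  if (per_sample) {
    tot <- rowSums(m)
    if (any(tot == 0)) abort("zero-total sample in composition summary")
    as_tibble(m / tot, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = rank,
                          values_to = "rel_abundance")
  } else {
    share <- colSums(m) / sum(m)
    tibble(!!rank := names(share), share = unname(share)) |>
      dplyr::arrange(dplyr::desc(.data$share))
  }
}

#' Coefficient heatmap across outcomes
#'
#' Taxa-by-outcome grid of signed debiased coefficients with a star marking
#' p < 0.05; rows are ordered by taxonomy (phylum, family, genus). Star
#' placement is exactly the `significant` flag of the result tables -- no
#' p-value is recomputed here.
#'
#' @param results_list Named list of result tibbles (one per outcome), as in
#'   `fit$results` from [dab()].
#' @param significant_only Keep only taxa significant for at least one outcome
#'   (default TRUE).
#' @return A ggplot object.
#' @export
plot_coefficient_heatmap <- function(results_list, significant_only = TRUE) {
  stopifnot(is.list(results_list), !is.null(names(results_list)))
  long <- purrr::imap(results_list, function(res, oc) {
    dplyr::mutate(res, outcome = oc)
  }) |> dplyr::bind_rows()
  if (nrow(long) == 0) {
    warn("empty results; skipping heatmap")
    return(invisible(NULL))
  }
  if (significant_only) {
    keep <- long |>
      dplyr::filter(.data$significant %in% TRUE) |>
      dplyr::pull(.data$taxon_id) |>
      unique()
    long <- dplyr::filter(long, .data$taxon_id %in% keep)
    if (nrow(long) == 0) {
      warn("no significant taxa; skipping heatmap")
      return(invisible(NULL))
    }
  }
  ord <- long |>
    dplyr::distinct(.data$phylum, .data$family, .data$genus, .data$taxon_id) |>
    dplyr::arrange(.data$phylum, .data$family, .data$genus)
  long$taxon_id <- factor(long$taxon_id, levels = rev(ord$taxon_id))
  labs <- setNames(paste(ord$phylum, ord$genus, sep = " / "), ord$taxon_id)

  ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome, y = .data$taxon_id,
                                     fill = .data$coefficient)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(
      data = dplyr::filter(long, .data$significant %in% TRUE),
      label = "*", size = 5, vjust = 0.75) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey95") +
    ggplot2::scale_y_discrete(labels = labs) +
    ggplot2::labs(x = NULL, y = NULL, fill = "coefficient",
                  title = "Debiased Lasso coefficients (* p < 0.05)") +
    ggplot2::theme_minimal()
}

#' Overlap of significant taxa across outcomes
#'
#' @param results_list Named list of result tibbles (one per outcome).
#' @return A tibble with one row per taxon significant for at least one
#'   outcome: the outcomes where it is significant and their count.
#' @export
cross_outcome_overlap <- function(results_list) {
  stopifnot(is.list(results_list), length(results_list) >= 2,
            !is.null(names(results_list)))
  sig <- purrr::imap(results_list, function(res, oc) {
    res |>
      dplyr::filter(.data$significant %in% TRUE) |>
      dplyr::select("phylum", "family", "genus", "taxon_id") |>
      dplyr::mutate(outcome = oc)
  }) |> dplyr::bind_rows()
  if (nrow(sig) == 0) {
    return(tibble(phylum = character(), family = character(),
                  genus = character(), taxon_id = character(),
                  outcomes = character(), n_outcomes = integer()))
  }
  sig |>
    dplyr::group_by(.data$phylum, .data$family, .data$genus, .data$taxon_id) |>
    dplyr::summarise(outcomes = paste(sort(.data$outcome), collapse = ","),
                     n_outcomes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_outcomes), .data$phylum, .data$genus)
}
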