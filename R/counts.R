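# The count-table container and taxonomy-lineage helpers.
#
# A count table is a plain tibble: `taxon_id`, `lineage`, then one numeric
# column per sample. Taxa are rows (the common orientation of classifier
# exports); internal numerics work on a samples-by-taxa matrix.

LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Validate a taxon count table
#'
#' Checks the count-table contract: unique taxon and sample identifiers, and a
#' non-negative integer count matrix.
#'
#' @param counts A tibble with columns `taxon_id`, `lineage`, then one numeric
#'   column per sample.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts)) abort("`counts` must be a data frame")
  if (!all(c("taxon_id", "lineage") %in% names(counts))) {
    abort("`counts` must have columns `taxon_id` and `lineage`")
  }
  samples <- setdiff(names(counts), c("taxon_id", "lineage"))
  if (length(samples) == 0) abort("`counts` has no sample columns")
  if (anyDuplicated(counts$taxon_id)) {
    abort(sprintf("duplicate taxon_id: %s",
                  paste(unique(counts$taxon_id[duplicated(counts$taxon_id)]),
                        collapse = ", ")))
  }
  if (anyDuplicated(samples)) abort("duplicate sample columns")
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric", s))
    if (anyNA(v)) abort(sprintf("sample column '%s' contains NA", s))
    if (any(v < 0)) abort(sprintf("negative count in sample '%s'", s))
    if (!all(is_wholenumber(v))) {
      abort(sprintf("non-integer count in sample '%s'", s))
    }
  }
  invisible(counts)
}

# samples-by-taxa integer matrix view of a counts tibble
counts_matrix <- function(counts) {
  samples <- setdiff(names(counts), c("taxon_id", "lineage"))
  m <- t(as.matrix(counts[samples]))
  dimnames(m) <- list(samples, counts$taxon_id)
  storage.mode(m) <- "double"
  m
}

# rebuild a counts tibble from a samples-by-taxa matrix plus lineage lookup
counts_from_matrix <- function(m, lineages) {
  taxa <- colnames(m)
  out <- tibble(taxon_id = taxa, lineage = unname(lineages[taxa]))
  body <- as_tibble(t(m), .name_repair = "minimal")
  names(body) <- rownames(m)
  dplyr::bind_cols(out, body)
}

lineage_lookup <- function(counts) {
  setNames(counts$lineage, counts$taxon_id)
}

count_sample_ids <- function(counts) {
  setdiff(names(counts), c("taxon_id", "lineage"))
}

#' Parse taxonomy lineage strings
#'
#' Accepts both greengenes-style prefixed strings
#' (`"k__Bacteria;p__Firmicutes;..."`) and bare semicolon-delimited strings;
#' ranks are positional (kingdom, phylum, class, order, family, genus,
#' species), so genus is always the sixth field.
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with one row per input and columns `kingdom` ... `species`
#'   (missing ranks are `NA`).
#' @export
parse_lineage <- function(lineage) {
  parts <- stringr::str_split(lineage, ";")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- stringr::str_remove(p, "^[kpcofgs]__")
    p[p == ""] <- NA_character_
    length(p) <- length(LINEAGE_RANKS)
    setNames(as.list(p), LINEAGE_RANKS)
  })
  dplyr::bind_rows(rows)
}

# truncate a lineage string at a rank, normalized to prefixed form
truncate_lineage <- function(lineage, rank) {
  k <- match(rank, LINEAGE_RANKS)
  if (is.na(k)) abort(sprintf("unknown rank '%s'", rank))
  tab <- parse_lineage(lineage)
  apply(as.matrix(tab[, seq_len(k), drop = FALSE]), 1, function(p) {
    p[is.na(p)] <- ""
    paste0(RANK_PREFIXES[seq_len(k)], p, collapse = ";")
  })
}

#' Aggregate counts to a taxonomic rank
#'
#' Counts of all classified descendants are summed within each taxon at the
#' requested rank before any transform, the standard remedy against
#' species-level sparsity.
#'
#' @param counts A count table (see [validate_counts()]).
#' @param rank Target rank, e.g. `"genus"` (default) or `"phylum"`.
#' @return A count table with one row per taxon at `rank`; `taxon_id` is the
#'   rank-level name (falling back to the truncated lineage when unnamed).
#' @export
aggregate_rank <- function(counts, rank = "genus") {
  validate_counts(counts)
  k <- match(rank, LINEAGE_RANKS)
  if (is.na(k)) abort(sprintf("unknown rank '%s'", rank))
  lin <- truncate_lineage(counts$lineage, rank)
  name <- parse_lineage(counts$lineage)[[rank]]
  id <- ifelse(is.na(name), lin, name)
  samples <- count_sample_ids(counts)
  counts |>
    dplyr::mutate(taxon_id = id, lineage = lin) |>
    dplyr::group_by(.data$taxon_id, .data$lineage) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum),
                     .groups = "drop")
}
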