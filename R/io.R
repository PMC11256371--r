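# Reading and writing count tables, sample metadata and result tables.

META_LEVELS <- list(
  sex      = c("female", "male"),
  smoking  = c("never", "former", "current"),
  asthma   = c("no", "yes"),
  state    = c("IA", "NC"),
  ancestry = c("european", "other"),
  season   = c("other", "winter")
)
META_NUMERIC <- c("fev1", "fvc", "fev1_fvc", "feno", "age", "height",
                  "weight", "pack_years")
META_REQUIRED <- c("sample_id", "age", "sex", "height", "weight", "smoking",
                   "pack_years", "asthma", "state", "ancestry", "season")

#' Read a taxon count table from TSV
#'
#' The canonical on-disk layout has taxa as rows with columns `taxon_id`,
#' `lineage`, then one column per sample. `orientation = "samples_rows"`
#' accepts the transposed layout (first column `sample_id`, one column per
#' taxon; lineages default to the bare taxon id).
#'
#' @param path TSV file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return A validated count table tibble.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (orientation == "samples_rows") {
    if (names(raw)[1] != "sample_id") {
      abort("samples_rows layout requires first column 'sample_id'")
    }
    m <- as.matrix(raw[-1])
    rownames(m) <- as.character(raw$sample_id)
    raw <- counts_from_matrix(m, setNames(colnames(m), colnames(m)))
  }
  if (!"lineage" %in% names(raw) && "taxon_id" %in% names(raw)) {
    raw$lineage <- raw$taxon_id
  }
  raw <- as_tibble(raw) |>
    dplyr::relocate("taxon_id", "lineage")
  validate_counts(raw)
  raw
}

#' Write a taxon count table to TSV
#'
#' @param counts A count table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata (outcomes and covariates) from TSV
#'
#' Enforces the sample-frame contract: typed columns, declared categorical
#' levels, FEV1/FVC in (0, 1], FEV1 <= FVC where both present, and FeNO
#' below-LOD sentinels (`"<LOD"`) accepted and flagged (value left unset).
#' Missing values must be explicit (`NA`), never silent zeros.
#'
#' @param path TSV file path.
#' @return A sample-frame tibble; FeNO censoring is recorded in the logical
#'   column `feno_below_lod`.
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  missing <- setdiff(META_REQUIRED, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- tibble(sample_id = as.character(raw$sample_id))
  if (anyDuplicated(out$sample_id)) abort("duplicate sample_id in metadata")

  if ("feno" %in% names(raw)) {
    sentinel <- !is.na(raw$feno) & stringr::str_detect(raw$feno, "^\\s*<\\s*LOD\\s*$")
    flag <- if ("feno_below_lod" %in% names(raw)) {
      tolower(raw$feno_below_lod) %in% c("true", "1", "yes")
    } else rep(FALSE, nrow(raw))
    out$feno_below_lod <- sentinel | flag
    raw$feno[sentinel] <- NA
  } else {
    out$feno_below_lod <- FALSE
  }

  for (col in META_NUMERIC) {
    if (!col %in% names(raw)) next
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s' (line %d)", col, bad[1] + 1))
    }
    out[[col]] <- v
  }
  for (col in names(META_LEVELS)) {
    v <- if (col == "state") toupper(raw[[col]]) else tolower(raw[[col]])
    unknown <- setdiff(unique(v[!is.na(v)]), META_LEVELS[[col]])
    if (length(unknown) > 0) {
      abort(sprintf("unknown level(s) in column '%s': %s", col,
                    paste(unknown, collapse = ", ")))
    }
    out[[col]] <- factor(v, levels = META_LEVELS[[col]])
  }
  validate_metadata(out)
  out
}

#' Validate a sample frame
#'
#' @param meta A sample-frame tibble (see [read_metadata()]).
#' @return `meta`, invisibly, if valid.
#' @export
validate_metadata <- function(meta) {
  if (!"sample_id" %in% names(meta)) abort("metadata needs a sample_id column")
  if ("fev1_fvc" %in% names(meta)) {
    bad <- which(!is.na(meta$fev1_fvc) &
                   (meta$fev1_fvc <= 0 | meta$fev1_fvc > 1))
    if (length(bad) > 0) {
      abort(sprintf("FEV1/FVC must lie in (0, 1]; violated for sample '%s'",
                    meta$sample_id[bad[1]]))
    }
  }
  if (all(c("fev1", "fvc") %in% names(meta))) {
    bad <- which(!is.na(meta$fev1) & !is.na(meta$fvc) & meta$fev1 > meta$fvc)
    if (length(bad) > 0) {
      abort(sprintf("FEV1 exceeds FVC for sample '%s'", meta$sample_id[bad[1]]))
    }
  }
  if ("feno" %in% names(meta) && any(!is.na(meta$feno) & meta$feno < 0)) {
    abort("negative FeNO measurement")
  }
  invisible(meta)
}

#' Write a sample frame to TSV
#'
#' @param meta A sample-frame tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

# p-values printed with three decimals, scientific below 1e-3 (e.g. "2.1e-04")
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-3, formatC(p, format = "e", digits = 1),
                sprintf("%.3f", p)))
}

#' Write a differential-abundance result table to TSV
#'
#' Rows are sorted by (phylum, family, genus); coefficients are printed with
#' three decimals and p-values with three decimals, switching to scientific
#' notation below 10^-3.
#'
#' @param results A result tibble with columns `phylum`, `family`, `genus`,
#'   `coefficient`, `se`, `z`, `p_value`, `significant` (as from [dab()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(all(c("phylum", "family", "genus", "coefficient", "se", "z",
                  "p_value", "significant") %in% names(results)))
  out <- results |>
    dplyr::arrange(.data$phylum, .data$family, .data$genus) |>
    dplyr::mutate(
      coefficient = ifelse(is.na(.data$coefficient), "NA",
                           sprintf("%.3f", .data$coefficient)),
      se = ifelse(is.na(.data$se), "NA", sprintf("%.4g", .data$se)),
      z = ifelse(is.na(.data$z), "NA", sprintf("%.4g", .data$z)),
      p_value = format_pvalue(.data$p_value)
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
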