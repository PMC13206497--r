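# TSV conventions: matrices are written with the row-identifier in the first
# column and one column per sample; sample metadata (sample_id, day,
# replicate, group) lives in a sidecar "<stem>_samples.tsv" so the matrix
# stays rectangular and diff-friendly. Values are printed with up to 12
# significant digits, which round-trips cleanly through decimal text.

meta_path_for <- function(path) {
  sub("(\\.[^.]*)?$", "_samples.tsv", path)
}

write_matrix_tsv <- function(values, id_col, path) {
  df <- as_tibble(values, rownames = id_col)
  df <- mutate(df, across(-all_of(id_col), ~ signif(.x, 12)))
  readr::write_tsv(df, path, progress = FALSE)
}

read_sample_meta <- function(meta_path, sample_ids) {
  if (!file.exists(meta_path)) {
    abort(sprintf("sample metadata file not found: %s", meta_path))
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  unmatched <- setdiff(sample_ids, meta$sample_id)
  if (length(unmatched)) {
    abort(sprintf("missing metadata for sample(s): %s",
                  paste(unmatched, collapse = ", ")))
  }
  meta
}

#' Read and write abundance tables
#'
#' `read_abundance()` expects a TSV whose first column holds taxon names and
#' whose remaining columns are samples, with per-sample metadata in a sidecar
#' `<stem>_samples.tsv` (columns sample_id, day, replicate, group).
#' `write_abundance()` produces both files. Values written with 12 significant
#' digits round-trip exactly.
#'
#' @param path Path to the matrix TSV.
#' @param level Taxonomic level tag, `"species"` or `"genus"`.
#' @param normalized Whether the stored values are relative abundances.
#' @param meta_path Optional explicit sidecar path; defaults to
#'   `<stem>_samples.tsv` next to `path`.
#' @return `read_abundance()` returns an [abundance_table()];
#'   `write_abundance()` returns `path` invisibly.
#' @export
read_abundance <- function(path, level = "species", normalized = FALSE,
                           meta_path = meta_path_for(path)) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("abundance TSV needs a taxon column plus >= 1 sample.")
  taxa <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) abort("non-numeric entries in abundance matrix.")
  rownames(values) <- taxa
  meta <- read_sample_meta(meta_path, colnames(values))
  abundance_table(values, meta, level = level, normalized = normalized)
}

#' @rdname read_abundance
#' @param table An [abundance_table()].
#' @export
write_abundance <- function(table, path, meta_path = meta_path_for(path)) {
  stopifnot(inherits(table, "abundance_table"))
  write_matrix_tsv(table$values, "taxon", path)
  readr::write_tsv(table$samples, meta_path, progress = FALSE)
  invisible(path)
}

#' Read and write volatile concentration tables
#'
#' The matrix TSV carries columns `compound`, `class`, then one column per
#' sample (ug/L); sample metadata uses the same sidecar convention as
#' [read_abundance()].
#'
#' @inheritParams read_abundance
#' @return `read_volatiles()` returns a [volatile_table()].
#' @export
read_volatiles <- function(path, meta_path = meta_path_for(path)) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("compound", "class") %in% names(df))) {
    abort("volatile TSV needs `compound` and `class` columns.")
  }
  compounds <- df[, c("compound", "class")]
  values <- as.matrix(df[, setdiff(names(df), c("compound", "class")), drop = FALSE])
  rownames(values) <- df$compound
  meta <- read_sample_meta(meta_path, colnames(values))
  volatile_table(values, compounds, meta)
}

#' @rdname read_volatiles
#' @param table A [volatile_table()].
#' @export
write_volatiles <- function(table, path, meta_path = meta_path_for(path)) {
  stopifnot(inherits(table, "volatile_table"))
  df <- bind_cols(table$compounds,
                  as_tibble(signif(table$values, 12), .name_repair = "minimal"))
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(table$samples, meta_path, progress = FALSE)
  invisible(path)
}

#' Read and write long-format indicator series
#'
#' Long TSV with columns `indicator`, `day`, `replicate`, `value` (units per
#' [indicator_units()]).
#'
#' @param path Path to the TSV.
#' @return A tibble of indicator observations.
#' @export
read_indicators <- function(path) {
  validate_indicators(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' @rdname read_indicators
#' @param indicators Long indicator tibble.
#' @export
write_indicators <- function(indicators, path) {
  indicators <- validate_indicators(indicators)
  readr::write_tsv(mutate(indicators, value = signif(.data$value, 12)),
                   path, progress = FALSE)
  invisible(path)
}

#' Read and write omission-experiment measurements
#'
#' Long TSV with columns `group` (`"control"` or `"omit_<taxon>"`),
#' `indicator`, `replicate`, `value`.
#'
#' @param path Path to the TSV.
#' @return A tibble of omission measurements.
#' @export
read_omission <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("group", "indicator", "replicate", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("omission table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @rdname read_omission
#' @param measurements Long omission tibble.
#' @export
write_omission <- function(measurements, path) {
  readr::write_tsv(mutate(measurements, value = signif(.data$value, 12)),
                   path, progress = FALSE)
  invisible(path)
}

#' Internal-standard quantification of a volatile compound
#'
#' Concentration (ug/L) from GC peak areas by single-point internal-standard
#' calibration: `peak_area * istd_conc / istd_area`.
#'
#' @param peak_area Peak area of the compound (arbitrary units, >= 0).
#' @param istd_area Peak area of the internal standard (> 0).
#' @param istd_conc Concentration of the internal standard in ug/L.
#' @return Concentration in ug/L; vectorised over its arguments.
#' @export
#' @examples
#' quantify_volatile(200, 100, 50) # 100 ug/L
quantify_volatile <- function(peak_area, istd_area, istd_conc) {
  if (any(!is.finite(istd_area)) || any(istd_area <= 0)) {
    abort("`istd_area` must be strictly positive.")
  }
  if (any(peak_area < 0)) abort("`peak_area` must be non-negative.")
  peak_area * istd_conc / istd_area
}

#' Protein relative utilization rate
#'
#' Percentage of total nitrogen recovered as amino acid content:
#' `(AA / TN) * 100`.
#'
#' @param amino_acid_content Amino acid content in g/L (>= 0).
#' @param total_nitrogen Total nitrogen content in g/L (> 0).
#' @return Percentage; vectorised.
#' @export
#' @examples
#' protein_utilization(0.8, 1.6) # 50
protein_utilization <- function(amino_acid_content, total_nitrogen) {
  if (any(!is.finite(total_nitrogen)) || any(total_nitrogen <= 0)) {
    abort("`total_nitrogen` must be strictly positive.")
  }
  amino_acid_content / total_nitrogen * 100
}
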