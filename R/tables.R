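#' Taxon-by-sample abundance table
#'
#' Bundles a non-negative taxon-by-sample matrix with per-sample metadata
#' (day, replicate, group), a taxonomic level tag and a flag recording whether
#' columns have been closed to relative abundances. Sample metadata must carry
#' one row per matrix column, keyed by `sample_id`.
#'
#' @param values Numeric matrix, taxa in rows, samples in columns. Row names
#'   are taxon names (unique), column names are sample ids.
#' @param samples Data frame with columns `sample_id`, `day`, `replicate` and
#'   optionally `group`; one row per sample, `day >= 0`.
#' @param level Taxonomic level tag, `"species"` or `"genus"`.
#' @param normalized Logical; `TRUE` when each column sums to 1.
#'
#' @return An object of class `abundance_table`.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4, 1, 1, 2), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), day = c(0, 5), replicate = 1L)
#' abundance_table(m, meta)
abundance_table <- function(values, samples, level = "species", normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (taxa x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have taxon row names and sample column names.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf("duplicate taxon names: %s",
                  paste(unique(rownames(values)[duplicated(rownames(values))]),
                        collapse = ", ")))
  }
  if (anyNA(values)) abort("abundance values must not contain missing values.")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative abundance at taxon '%s', sample '%s'.",
                  rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "day", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("sample metadata lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in metadata.")
  unmatched <- setdiff(colnames(values), samples$sample_id)
  if (length(unmatched)) {
    abort(sprintf("missing metadata for sample(s): %s",
                  paste(unmatched, collapse = ", ")))
  }
  if (any(samples$day < 0)) abort("`day` must be non-negative.")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  level <- arg_match0(level, c("species", "genus"))
  normalized <- isTRUE(normalized)
  if (normalized) {
    sums <- colSums(values)
    if (any(abs(sums - 1) > 1e-9)) {
      abort("`normalized = TRUE` but some columns do not sum to 1 within 1e-9.")
    }
  }
  structure(
    list(values = values, samples = samples, level = level,
         normalized = normalized),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples (%s level, %s)\n",
              nrow(x$values), ncol(x$values), x$level,
              if (x$normalized) "relative abundances" else "raw values"))
  cat(sprintf("  days %s; %d replicate(s)\n",
              paste(sort(unique(x$samples$day)), collapse = ", "),
              max(x$samples$replicate)))
  invisible(x)
}

#' @rdname abundance_table
#' @param x An `abundance_table`.
#' @param ... Unused.
#' @export
tidy.abundance_table <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "taxon") %>%
    tidyr::pivot_longer(-"taxon", names_to = "sample_id", values_to = "abundance")
  left_join(long, x$samples, by = "sample_id")
}

#' Compound-by-sample volatile concentration table
#'
#' Concentrations are in micrograms per litre. Each compound carries a
#' chemical class label from the seven-class vocabulary used for fermentation
#' aroma profiling: alcohol, phenol, pyrazine, aldehyde, ketone, ester, acid.
#'
#' @param values Numeric matrix, compounds in rows, samples in columns;
#'   non-negative.
#' @param compounds Data frame with columns `compound` and `class`.
#' @param samples Sample metadata as in [abundance_table()].
#'
#' @return An object of class `volatile_table`.
#' @export
volatile_table <- function(values, compounds, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (compounds x samples).")
  }
  compounds <- as_tibble(compounds)
  if (!all(c("compound", "class") %in% names(compounds))) {
    abort("`compounds` needs columns `compound` and `class`.")
  }
  if (nrow(compounds) != nrow(values)) {
    abort("`compounds` must have one row per matrix row.")
  }
  bad_class <- setdiff(unique(compounds$class), volatile_classes())
  if (length(bad_class)) {
    abort(sprintf("unknown volatile class(es): %s (allowed: %s)",
                  paste(bad_class, collapse = ", "),
                  paste(volatile_classes(), collapse = ", ")))
  }
  if (anyNA(values) || any(values < 0)) {
    abort("volatile concentrations must be non-negative and complete.")
  }
  rownames(values) <- compounds$compound
  samples <- as_tibble(samples)
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  unmatched <- setdiff(colnames(values), samples$sample_id)
  if (length(unmatched)) {
    abort(sprintf("missing metadata for sample(s): %s",
                  paste(unmatched, collapse = ", ")))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  structure(
    list(values = values, compounds = compounds, samples = samples),
    class = "volatile_table"
  )
}

#' @export
print.volatile_table <- function(x, ...) {
  cls <- table(x$compounds$class)
  cat(sprintf("<volatile_table> %d compounds x %d samples (ug/L)\n",
              nrow(x$values), ncol(x$values)))
  cat("  ", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname volatile_table
#' @param x A `volatile_table`.
#' @param ... Unused.
#' @export
tidy.volatile_table <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "compound") %>%
    tidyr::pivot_longer(-"compound", names_to = "sample_id",
                        values_to = "concentration")
  long %>%
    left_join(x$compounds, by = "compound") %>%
    left_join(x$samples, by = "sample_id")
}

#' The seven-class volatile vocabulary
#'
#' @return Character vector of allowed volatile compound classes.
#' @export
volatile_classes <- function() {
  c("alcohol", "phenol", "pyrazine", "aldehyde", "ketone", "ester", "acid")
}

#' Recognised fermentation quality indicators
#'
#' Long indicator tables use these names: glutamic acid (g/L), umami amino
#' acids (g/L), 4-ethylguaiacol (ug/L), lactic acid (g/L), reducing sugars
#' (g/L), amino acid nitrogen (g/L), total nitrogen (g/L) and pH (unitless).
#'
#' @return Named character vector mapping indicator name to unit.
#' @export
indicator_units <- function() {
  c(glutamic_acid = "g/L", umami_aa = "g/L", x4eg = "ug/L",
    lactic_acid = "g/L", reducing_sugar = "g/L", amino_nitrogen = "g/L",
    total_nitrogen = "g/L", pH = "unitless")
}

# Validate a long indicator tibble: indicator, day, replicate, value.
validate_indicators <- function(indicators) {
  indicators <- as_tibble(indicators)
  need <- c("indicator", "day", "replicate", "value")
  missing_cols <- setdiff(need, names(indicators))
  if (length(missing_cols)) {
    abort(sprintf("indicator table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(indicators) == 0) abort("indicator table has no observations.")
  ph <- indicators$value[indicators$indicator == "pH"]
  if (length(ph) && (any(ph <= 0) || any(ph >= 14))) {
    abort("pH values must lie strictly inside (0, 14).")
  }
  indicators
}

#' Close an abundance table to relative abundances
#'
#' Divides every sample column by its sum so columns sum to 1. The operation
#' is idempotent: a table already flagged as normalized is returned unchanged,
#' and re-closing columns that sum to 1 leaves them fixed.
#'
#' @param table An [abundance_table()] with at least one positive value per
#'   sample.
#' @return The table with `normalized = TRUE`.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4), ncol = 1, dimnames = list(paste0("t", 1:3), "s1"))
#' meta <- tibble::tibble(sample_id = "s1", day = 0, replicate = 1L)
#' normalize_relative(abundance_table(m, meta))$values
normalize_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$normalized) {
    return(table)
  }
  sums <- colSums(table$values)
  if (any(sums <= 0)) {
    abort(sprintf("sample(s) with all-zero abundance: %s",
                  paste(colnames(table$values)[sums <= 0], collapse = ", ")))
  }
  table$values <- sweep(table$values, 2, sums, "/")
  table$normalized <- TRUE
  table
}
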