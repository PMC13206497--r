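#' Dominance screen: abundance and prevalence criterion
#'
#' For each taxon of a normalized table, computes the mean relative abundance
#' over all samples and the prevalence (fraction of samples with abundance
#' strictly above `presence_epsilon`). A taxon passes the dominance criterion
#' when mean relative abundance exceeds `dominance_abundance_threshold`
#' (strictly; default 1%) AND prevalence is at least
#' `dominance_prevalence_threshold` (default 80% of samples). Taxa are also
#' classified by mean relative abundance: `dominant` (>= 10%), `sub_dominant`
#' (1% <= RA < 10%), `minor` (< 1%).
#'
#' @param table A normalized [abundance_table()].
#' @param config An [analysis_config()].
#' @return A tibble of class `dominance_report`, sorted by mean relative
#'   abundance (descending), with columns `taxon`, `mean_ra`, `prevalence`,
#'   `passes` and `class`.
#' @export
#' @examples
#' sim <- simulate_fermentation(generator_config(seed = 1))
#' dominance_screen(sim$abundance)
dominance_screen <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$normalized) {
    abort("dominance screening requires a normalized (relative-abundance) table.")
  }
  v <- table$values
  report <- tibble(
    taxon = rownames(v),
    mean_ra = unname(rowMeans(v)),
    prevalence = unname(rowMeans(v > config$presence_epsilon))
  ) %>%
    mutate(
      passes = .data$mean_ra > config$dominance_abundance_threshold &
        .data$prevalence >= config$dominance_prevalence_threshold,
      class = dplyr::case_when(
        .data$mean_ra >= 0.10 ~ "dominant",
        .data$mean_ra >= 0.01 ~ "sub_dominant",
        TRUE ~ "minor"
      )
    ) %>%
    arrange(desc(.data$mean_ra))
  class(report) <- c("dominance_report", class(report))
  report
}

#' @rdname dominance_screen
#' @param x A `dominance_report`.
#' @param ... Unused.
#' @export
glance.dominance_report <- function(x, ...) {
  tibble(
    n_taxa = nrow(x),
    n_passing = sum(x$passes),
    n_dominant = sum(x$class == "dominant"),
    n_sub_dominant = sum(x$class == "sub_dominant")
  )
}

#' @rdname dominance_screen
#' @param report A `dominance_report`.
#' @param path Output TSV path.
#' @export
write_dominance <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}
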