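# ggplot2 front-ends. Each result type gets an autoplot() method so figures
# compose with the usual grammar; plot_* helpers cover the raw tables.

#' Stacked community composition over time
#'
#' @param abundance A normalized [abundance_table()].
#' @param top_n Number of most abundant taxa shown individually; the rest are
#'   lumped as "other".
#' @return A ggplot object.
#' @export
plot_community <- function(abundance, top_n = 12) {
  d <- tidy(abundance) %>%
    group_by(.data$day, .data$taxon) %>%
    summarise(abundance = mean(.data$abundance), .groups = "drop")
  keep <- d %>% group_by(.data$taxon) %>%
    summarise(m = mean(.data$abundance), .groups = "drop") %>%
    arrange(desc(.data$m)) %>% dplyr::slice_head(n = top_n) %>% pull("taxon")
  d <- mutate(d, taxon = ifelse(.data$taxon %in% keep, .data$taxon, "other"))
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$abundance,
                                  fill = .data$taxon)) +
    ggplot2::geom_col(position = "fill", width = 3) +
    ggplot2::labs(x = "fermentation day", y = "relative abundance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Indicator trajectories with replicate points
#'
#' @param indicators Long indicator tibble.
#' @return A ggplot object.
#' @export
plot_indicators <- function(indicators) {
  indicators <- validate_indicators(indicators)
  ggplot2::ggplot(indicators,
                  ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "fermentation day", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dominance_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean_ra, .data$prevalence,
                                       colour = .data$class,
                                       shape = .data$passes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean relative abundance", y = "prevalence",
                  colour = "class", shape = "passes criterion") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correlation_network <- function(object, ...) {
  deg <- object$degree
  ggplot2::ggplot(deg, ggplot2::aes(stats::reorder(.data$node, .data$degree),
                                    .data$degree)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "degree",
                  title = sprintf("%s network: %d edges", object$kind,
                                  nrow(object$edges))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_segmentation <- function(object, ...) {
  sc <- as_tibble(object$pca$scores[, 1:min(2, ncol(object$pca$scores)),
                                    drop = FALSE])
  names(sc)[1] <- "PC1"
  if (ncol(sc) == 1) sc$PC2 <- 0 else names(sc)[2] <- "PC2"
  sc <- bind_cols(object$assignment, sc)
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$phase)) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$day), vjust = -1,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(colour = "phase") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.indicator_assignment <- function(object, ...) {
  ggplot2::ggplot(object$assignment,
                  ggplot2::aes(.data$pc1_loading,
                               stats::reorder(.data$indicator,
                                              .data$pc1_loading),
                               fill = .data$side)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PC1 loading (rate of change)", y = NULL,
                  fill = "phase side") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$day, .data$mean,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = filter(object$cells, .data$significant),
                        shape = 8, show.legend = FALSE) +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "fermentation day", y = "group mean", colour = NULL) +
    ggplot2::theme_minimal()
}
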