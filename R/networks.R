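new_correlation_network <- function(nodes, edges, kind) {
  deg <- rep(0L, length(nodes))
  names(deg) <- nodes
  if (nrow(edges)) {
    tab <- table(c(edges$item_a, edges$item_b))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(
    list(
      nodes = nodes,
      edges = edges,
      degree = tibble(node = nodes, degree = unname(deg)),
      kind = kind
    ),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network: %s> %d nodes, %d edges\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @rdname build_cooccurrence
#' @param x A `correlation_network`.
#' @param ... Unused.
#' @export
tidy.correlation_network <- function(x, ...) x$edges

#' @rdname build_cooccurrence
#' @export
glance.correlation_network <- function(x, ...) {
  tibble(kind = x$kind, n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         max_degree = max(c(0L, x$degree$degree)))
}

#' Taxon co-occurrence network from pairwise Spearman correlations
#'
#' Tests every taxon pair across all samples (Spearman on relative
#' abundances), applies Benjamini-Hochberg correction over the full family of
#' taxon-pair tests, and keeps edges passing the chosen threshold set. The
#' `"analysis"` network — on which hub taxa are defined — uses
#' |rho| > `edge_r_threshold` and q < `edge_q_threshold`; the stricter
#' `"display"` network uses |rho| > `display_r_threshold` and raw
#' p < `display_p_threshold`. Taxa with constant abundance are excluded from
#' testing with a warning; nodes retain degree 0.
#'
#' @param table A normalized [abundance_table()] with at least 4 samples and
#'   2 taxa.
#' @param config An [analysis_config()].
#' @param kind `"analysis"` or `"display"`.
#' @return A `correlation_network` object: node list, edge tibble
#'   (`item_a`, `item_b`, `rho`, `p`, `q`), per-node degree tibble and kind.
#' @export
build_cooccurrence <- function(table, config = analysis_config(),
                               kind = c("analysis", "display")) {
  stopifnot(inherits(table, "abundance_table"))
  kind <- arg_match(kind)
  if (!table$normalized) abort("co-occurrence requires a normalized table.")
  if (nrow(table$values) < 2) abort("fewer than 2 taxa: nothing to correlate.")
  if (ncol(table$values) < 4) abort("need at least 4 samples.")
  tested <- correlate_pairs(t(table$values))
  tested <- filter(tested, !is.na(.data$rho))
  tested$q <- bh_fdr(tested$p)
  edges <- if (kind == "analysis") {
    filter(tested, abs(.data$rho) > config$edge_r_threshold,
           .data$q < config$edge_q_threshold)
  } else {
    filter(tested, abs(.data$rho) > config$display_r_threshold,
           .data$p < config$display_p_threshold)
  }
  net <- new_correlation_network(rownames(table$values), edges, kind)
  net$tested <- tested
  net
}

#' Hub taxa of a co-occurrence network
#'
#' Taxa whose degree strictly exceeds `hub_degree_threshold` (default 9
#' links) in the analysis network.
#'
#' @param network An analysis-kind `correlation_network`.
#' @param config An [analysis_config()].
#' @return Character vector of hub taxon names (may be empty).
#' @export
hub_taxa <- function(network, config = analysis_config()) {
  stopifnot(inherits(network, "correlation_network"))
  if (network$kind != "analysis") {
    abort("hub detection is defined on the analysis-kind network.")
  }
  network$degree$node[network$degree$degree > config$hub_degree_threshold]
}

#' Flavor-associated taxa from taxon-volatile correlations
#'
#' Tests every taxon x compound pair (Spearman across matched samples),
#' applies Benjamini-Hochberg correction over the taxon-volatile family (a
#' separate family from the co-occurrence tests), and flags a taxon as
#' flavor-associated when at least `flavor_min_volatiles` compounds pass
#' |rho| > `flavor_r_threshold`, p < `flavor_p_threshold` and
#' q < `flavor_q_threshold`.
#'
#' @param abundance A normalized [abundance_table()].
#' @param volatiles A [volatile_table()] over the same samples.
#' @param config An [analysis_config()].
#' @return A list with `network` (taxon-volatile `correlation_network` whose
#'   edges are the passing pairs), `taxa` (character vector of qualifying
#'   taxa) and `counts` (tibble of passing-compound counts per taxon).
#' @export
flavor_associated_taxa <- function(abundance, volatiles,
                                   config = analysis_config()) {
  stopifnot(inherits(abundance, "abundance_table"),
            inherits(volatiles, "volatile_table"))
  a_ids <- colnames(abundance$values)
  v_ids <- colnames(volatiles$values)
  unmatched <- c(setdiff(a_ids, v_ids), setdiff(v_ids, a_ids))
  if (length(unmatched)) {
    abort(sprintf("sample mismatch between tables: %s",
                  paste(unique(unmatched), collapse = ", ")))
  }
  vv <- volatiles$values[, a_ids, drop = FALSE]
  tested <- correlate_pairs(t(abundance$values), t(vv))
  tested <- filter(tested, !is.na(.data$rho))
  tested$q <- bh_fdr(tested$p)
  passing <- filter(tested, abs(.data$rho) > config$flavor_r_threshold,
                    .data$p < config$flavor_p_threshold,
                    .data$q < config$flavor_q_threshold)
  counts <- passing %>%
    dplyr::count(.data$item_a, name = "n_volatiles") %>%
    rename(taxon = "item_a")
  counts <- tibble(taxon = rownames(abundance$values)) %>%
    left_join(counts, by = "taxon") %>%
    mutate(n_volatiles = tidyr::replace_na(.data$n_volatiles, 0L))
  qualifying <- counts$taxon[counts$n_volatiles >= config$flavor_min_volatiles]
  net <- new_correlation_network(
    c(rownames(abundance$values), rownames(vv)), passing, "taxon_volatile")
  net$tested <- tested
  list(network = net, taxa = qualifying, counts = counts)
}

#' Export a correlation network
#'
#' `write_network_edges()` writes the edge list as TSV (source, target, rho,
#' p, q) plus a degree table TSV; `write_network_graphml()` writes GraphML.
#'
#' @param network A `correlation_network`.
#' @param path Output path.
#' @param degree_path Optional path for the degree TSV.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path, degree_path = NULL) {
  edges <- network$edges %>%
    rename(source = "item_a", target = "item_b")
  readr::write_tsv(edges, path, progress = FALSE)
  if (!is.null(degree_path)) {
    readr::write_tsv(network$degree, degree_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_edges
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}
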