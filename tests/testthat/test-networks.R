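norm_tab <- function(m, ...) normalize_relative(make_abund(m, ...))

test_that("perfectly correlated taxa form an analysis edge; no self-loops", {
  set.seed(41)
  base <- sort(runif(12, 1, 10))
  m <- rbind(a = base, b = base * 2 + 0.5, c = runif(12), d = runif(12),
             e = runif(12))
  net <- build_cooccurrence(norm_tab(m))
  expect_true(any((net$edges$item_a == "a" & net$edges$item_b == "b") |
                    (net$edges$item_a == "b" & net$edges$item_b == "a")))
  expect_false(any(net$edges$item_a == net$edges$item_b))
  # degree equals incident edge count
  for (nd in net$nodes) {
    expect_equal(net$degree$degree[net$degree$node == nd],
                 sum(net$edges$item_a == nd) + sum(net$edges$item_b == nd))
  }
})

test_that("edge sets shrink as the correlation threshold rises", {
  set.seed(42)
  m <- matrix(rlnorm(15 * 12), 15, 12)
  m[1:5, ] <- m[1:5, ] + matrix(rep(sort(runif(12, 0, 8)), each = 5), 5, 12)
  tab <- norm_tab(m)
  edge_key <- function(net) paste(net$edges$item_a, net$edges$item_b)
  e05 <- edge_key(build_cooccurrence(tab, analysis_config(edge_r_threshold = 0.5)))
  e06 <- edge_key(build_cooccurrence(tab, analysis_config(edge_r_threshold = 0.6)))
  e08 <- edge_key(build_cooccurrence(tab, analysis_config(edge_r_threshold = 0.8)))
  expect_true(all(e06 %in% e05))
  expect_true(all(e08 %in% e06))
})

test_that("hub detection applies the strict degree rule", {
  # star around taxon h: 10 satellites correlated with h (and each other)
  set.seed(43)
  sig <- sort(runif(12, 1, 20))
  m <- rbind(h = sig,
             do.call(rbind, lapply(1:10, function(i) sig * runif(1, 0.5, 2) +
                                     rnorm(12, 0, 0.01))),
             do.call(rbind, lapply(1:5, function(i) runif(12))))
  rownames(m) <- c("h", sprintf("sat%02d", 1:10), sprintf("noise%d", 1:5))
  net <- build_cooccurrence(norm_tab(m))
  hubs <- hub_taxa(net, analysis_config())
  expect_true("h" %in% hubs) # degree 10 > 9
  # brute-force recount at several thresholds
  for (thr in c(0L, 3L, 9L, 10L)) {
    got <- hub_taxa(net, analysis_config(hub_degree_threshold = thr))
    manual <- net$degree$node[net$degree$degree > thr]
    expect_setequal(got, manual)
  }
  # boundary: a node with degree exactly 9 is not a hub
  deg9 <- net$degree$node[net$degree$degree == 9]
  if (length(deg9)) expect_false(any(deg9 %in% hubs))
  expect_error(hub_taxa(build_cooccurrence(norm_tab(m), kind = "display")),
               "analysis")
})

test_that("flavor association needs five passing volatiles", {
  set.seed(44)
  n <- 16
  sig <- sort(runif(n, 1, 10)) # monotone trajectory, strong correlations
  osc <- rep(c(1, 5), length.out = n) + runif(n, 0, 0.2)
  m <- rbind(six = sig, four = osc, pad = runif(n))
  vol <- matrix(runif(10 * n, 5, 8), 10, n)
  for (k in 1:6) vol[k, ] <- 10 + 50 * sig / max(sig) + rnorm(n, 0, 0.3)
  for (k in 7:10) vol[k, ] <- 10 + 50 * osc / max(osc) + rnorm(n, 0, 0.3)
  abund <- norm_tab(m)
  vt <- make_volatiles(vol)
  res <- flavor_associated_taxa(abund, vt)
  expect_true("six" %in% res$taxa)
  expect_false("four" %in% res$taxa) # only 4 planted links: below the minimum
  expect_gte(res$counts$n_volatiles[res$counts$taxon == "six"], 5)
  expect_lte(res$counts$n_volatiles[res$counts$taxon == "four"], 4)
  # lowering the minimum admits the four-link taxon
  res3 <- flavor_associated_taxa(abund, vt,
                                 analysis_config(flavor_min_volatiles = 3))
  expect_true("four" %in% res3$taxa)
})

test_that("sample mismatches between tables are reported by id", {
  m <- matrix(runif(20, 1, 2), 4, 5)
  abund <- norm_tab(m)
  vol <- make_volatiles(matrix(runif(35), 7, 5))
  colnames(vol$values)[5] <- "weird"
  vol$samples$sample_id[5] <- "weird"
  expect_error(flavor_associated_taxa(abund, vol), "weird")
})

test_that("networks export to edge-list TSV and GraphML", {
  set.seed(45)
  sig <- sort(runif(12))
  m <- rbind(a = sig, b = sig + 0.01, c = runif(12), d = runif(12))
  net <- build_cooccurrence(norm_tab(m))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_edges(net, tsv)
  write_network_graphml(net, gml)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
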