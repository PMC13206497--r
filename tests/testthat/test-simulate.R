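test_that("zero noise gives identical replicate columns; closure always holds", {
  sim <- simulate_fermentation(generator_config(noise_sd = 0, seed = 5))
  v <- sim$abundance$values
  meta <- sim$abundance$samples
  for (d in unique(meta$day)) {
    cols <- meta$sample_id[meta$day == d]
    expect_equal(v[, cols[1]], v[, cols[2]])
    expect_equal(v[, cols[1]], v[, cols[3]])
  }
  expect_equal(unname(colSums(v)), rep(1, ncol(v)), tolerance = 1e-9)
  noisy <- simulate_fermentation(generator_config(seed = 6))
  expect_equal(unname(colSums(noisy$abundance$values)),
               rep(1, ncol(noisy$abundance$values)), tolerance = 1e-9)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  a <- simulate_fermentation(generator_config(seed = 99))
  b <- simulate_fermentation(generator_config(seed = 99))
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(a$volatiles$values, b$volatiles$values)
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$truth$producer_links, b$truth$producer_links)
  c <- simulate_fermentation(generator_config(seed = 100))
  expect_false(identical(a$abundance$values, c$abundance$values))
})

test_that("planted truth is internally consistent", {
  sim <- simulate_fermentation(generator_config(seed = 7))
  tr <- sim$truth
  expect_length(tr$core_taxa, 9)
  expect_true(all(tr$core_taxa %in% rownames(sim$abundance$values)))
  expect_true(all(tr$producer_links$taxon %in% rownames(sim$abundance$values)))
  expect_true(all(tr$producer_links$compound %in% rownames(sim$volatiles$values)))
  expect_true(all(diff(tr$changepoints) > 0))
  expect_true(all(tr$changepoints > 0 & tr$changepoints < 40))
  expect_equal(length(tr$clique_memberships), 3)
  expect_true(all(lengths(tr$clique_memberships) ==
                    generator_config()$clique_size))
  # every core taxon has the planted number of producer links
  links_per_core <- table(tr$producer_links$taxon)[tr$core_taxa]
  expect_true(all(links_per_core == generator_config()$n_producer_links))
})

test_that("infeasible configurations are rejected before simulation", {
  expect_error(generator_config(n_core = 200), "exceed")
  expect_error(generator_config(clique_size = 100), "roster")
  expect_error(generator_config(noise_sd = -1), "non-negative")
})

test_that("planted clique members correlate above the edge threshold", {
  # direct recomputation with stats::cor on the generated tables
  mean_rho <- sapply(1:20, function(s) {
    sim <- simulate_fermentation(generator_config(seed = s))
    sapply(sim$truth$clique_memberships, function(members) {
      r <- cor(t(sim$abundance$values[members, ]), method = "spearman")
      mean(r[upper.tri(r)])
    })
  })
  expect_gt(mean(mean_rho), 0.6)
})

test_that("omission simulation plants exact effects at zero noise", {
  core <- simulate_fermentation(generator_config(seed = 1))$truth$core_taxa
  eff0 <- tibble::tibble(taxon = core, umami_effect = 0, eg_effect = 0)
  om <- simulate_omission(core, effects = eff0, noise_sd = 0, seed = 2)
  ctrl <- om$value[om$group == "control" & om$indicator == "umami_aa"][1]
  expect_true(all(om$value[om$indicator == "umami_aa"] == ctrl))

  eff <- tibble::tibble(taxon = core, umami_effect = 27.2, eg_effect = 0)
  om2 <- simulate_omission(core, effects = eff, noise_sd = 0, seed = 2)
  omitted <- om2$value[om2$group == paste0("omit_", core[1]) &
                         om2$indicator == "umami_aa"]
  expect_equal(unique(omitted), 10 * (1 - 0.272))
  res <- omission_analysis(om2)
  expect_equal(res$percent_change[res$taxon == core[1] &
                                    res$indicator == "umami_aa"], 27.2)

  expect_error(
    simulate_omission(core,
                      effects = tibble::tibble(taxon = core,
                                               umami_effect = 150,
                                               eg_effect = 0)),
    "negative")
  expect_error(simulate_omission(core, effects = eff0[-1, ]), "no omission effect")
})

test_that("group-indicator simulation plants a ramping multiplicative effect", {
  g <- simulate_group_indicators(c("control", "boost"),
                                 group_effects = c(boost = 20),
                                 noise_sd = 0, seed = 3)
  final <- max(g$day)
  m_ctrl <- mean(g$value[g$group == "control" & g$day == final])
  m_boost <- mean(g$value[g$group == "boost" & g$day == final])
  expect_equal(m_boost / m_ctrl, 1.2, tolerance = 1e-12)
  d0 <- g$value[g$day == 0]
  expect_equal(length(unique(d0)), 1) # no effect at day 0
  expect_error(simulate_group_indicators(c("a", "b")), "control")
})

test_that("simulated datasets round-trip through a directory", {
  sim <- simulate_fermentation(generator_config(seed = 8))
  dir <- withr::local_tempdir()
  simulate_to_dir(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("abundance.tsv", "volatiles.tsv", "indicators.tsv",
           "omission.tsv", "truth.json")))))
  back <- read_abundance(file.path(dir, "abundance.tsv"), normalized = TRUE)
  expect_equal(back$values, sim$abundance$values, tolerance = 1e-10)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$core_taxa, sim$truth$core_taxa)
  expect_equal(tr$changepoints, sim$truth$changepoints)
})
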