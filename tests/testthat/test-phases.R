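test_that("pca_scores handles degenerate structure and fixes orientation", {
  set.seed(61)
  v <- rnorm(10)
  two <- cbind(a = v, b = 2 * v + 1)
  res <- pca_scores(two)
  expect_equal(res$var_explained[1], 1)
  # reconstruction from all components reproduces the standardized matrix
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  res2 <- pca_scores(x)
  recon <- res2$scores %*% t(res2$loadings)
  expect_equal(recon, scale(x), tolerance = 1e-8, ignore_attr = TRUE)
  # constant variable dropped with a warning
  expect_warning(pca_scores(cbind(x, k = rep(3, 10))), "constant")
  # PC1 oriented so the earliest-day observation scores non-negatively
  days <- 1:10
  res3 <- pca_scores(x, days = days)
  expect_gte(res3$scores[1, 1], 0)
  res4 <- pca_scores(-x, days = days)
  expect_gte(res4$scores[1, 1], 0)
})

test_that("segmentation finds exact plateau boundaries and the DP optimum", {
  # four clean plateaus: boundaries must fall exactly at the changes
  traj <- tibble::tibble(
    day = seq(0, 40, by = 5),
    v1 = c(5, 5, 1, 1, 3, 3, 8, 8, 8),
    v2 = c(0, 0, 4, 4, 1, 1, 6, 6, 6)
  )
  seg <- segment_phases(traj, k = 4)
  expect_equal(seg$boundaries, c(7.5, 17.5, 27.5))
  expect_equal(seg$labels,
               c("immediate_early", "early", "middle", "late"))
  expect_equal(seg$assignment$phase,
               rep(seg$labels, times = c(2, 2, 2, 3)))

  # exact optimality versus brute-force enumeration on random instances
  set.seed(62)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    y <- matrix(rnorm(2 * n), n, 2)
    dp <- syncomcore:::segment_dp(y, k)
    expect_equal(dp$cost, oracle_segment_cost(y, k), tolerance = 1e-9)
  }
})

test_that("segmentation is invariant to uniform rescaling and rejects bad k", {
  set.seed(63)
  traj <- tibble::tibble(day = seq(0, 40, by = 5))
  for (v in letters[1:5]) traj[[v]] <- rnorm(9)
  seg1 <- segment_phases(traj, k = 4)
  scaled <- dplyr::mutate(traj, dplyr::across(-day, ~ .x * 1000))
  seg2 <- segment_phases(scaled, k = 4)
  expect_equal(seg1$boundaries, seg2$boundaries)
  expect_error(segment_phases(traj, k = 10), "exceeds")
  expect_error(segment_phases(traj[c(2, 1, 3:9), ], k = 3), "increasing")
})

test_that("indicators split into early and late by rate-of-change loading", {
  sim <- simulate_fermentation(generator_config(seed = 64))
  seg <- segment_phases(community_trajectory(sim$abundance), k = 4)
  ia <- assign_indicators(sim$indicators, seg)
  a <- ia$assignment
  expect_identical(a$side[a$indicator == "glutamic_acid"], "early")
  expect_identical(a$side[a$indicator == "x4eg"], "late")
  expect_true(all(a$side %in% c("early", "late")))

  # mirrored pair gets opposite sides; constant indicator is excluded
  days <- seq(0, 40, by = 5)
  base <- 1 / (1 + exp(-(days - 10) / 4))
  mk <- function(name, vals) tibble::tibble(indicator = name, day = days,
                                            replicate = 1L, value = vals)
  mirrored <- dplyr::bind_rows(
    mk("up", 5 + 3 * base), mk("down", 5 - 3 * base),
    mk("late_riser", 1 / (1 + exp(-(days - 30) / 2))),
    mk("flat", rep(2, 9)))
  seg2 <- segment_phases(
    tibble::tibble(day = days, a = c(1, 1, 2, 2, 3, 3, 4, 4, 4),
                   b = c(4, 4, 2, 2, 1, 1, 0, 0, 0)), k = 4)
  ia2 <- suppressWarnings(assign_indicators(mirrored, seg2))
  a2 <- ia2$assignment
  expect_false("flat" %in% a2$indicator)
  expect_true(all(c("up", "down") %in% a2$indicator))
  expect_false(a2$side[a2$indicator == "up"] == a2$side[a2$indicator == "down"])

  # too few observations are excluded with a warning (alongside the
  # constant-indicator warning from the PCA)
  short <- dplyr::bind_rows(mirrored,
                            mk("sparse", rep(NA, 9))[1:2, ] |>
                              dplyr::mutate(value = c(1, 2)))
  w <- capture_warnings(assign_indicators(short, seg2))
  expect_true(any(grepl("sparse", w)))
})

test_that("taxa map to the phases where their associated classes are most active", {
  days <- seq(0, 40, by = 5)
  early_sig <- c(2, 8, 10, 9, 7, 5, 3.5, 2.5, 2) # early bloom, then decline
  late_sig <- c(1, 1, 1, 1.1, 1.2, 1.5, 4, 8, 12) # changes late
  # a large constant ballast taxon keeps compositional closure from
  # distorting the focal trajectories
  m <- rbind(early_taxon = early_sig, late_taxon = late_sig,
             flat_taxon = rep(3, 9) + c(0.01, -0.01, 0, 0.01, -0.01, 0,
                                        0.01, -0.01, 0),
             twin = early_sig,
             ballast = rep(300, 9))
  abund <- normalize_relative(make_abund(m, days = days))
  vol <- matrix(0, 6, 9)
  for (k in 1:3) vol[k, ] <- 5 + 10 * early_sig + rnorm(9, 0, 0.01)
  for (k in 4:6) vol[k, ] <- 5 + 10 * late_sig + rnorm(9, 0, 0.01)
  vt <- make_volatiles(vol, classes = rep(c("acid", "phenol"), each = 3),
                       days = days)
  ind <- tidyr::expand_grid(indicator = c("glutamic_acid", "lactic_acid"),
                            day = days) |>
    dplyr::mutate(replicate = 1L, value = rep(early_sig, 2))
  seg <- segment_phases(tibble::tibble(day = days, a = early_sig, b = late_sig),
                        k = 4)
  res <- suppressWarnings(taxa_phase_correspondence(
    abund, vt, ind, core = c("early_taxon", "late_taxon", "flat_taxon", "twin"),
    seg))
  mapping <- res$mapping
  early_phases <- mapping$phase[mapping$taxon == "early_taxon"]
  expect_true(all(early_phases %in% c("immediate_early", "early")))
  expect_true(length(early_phases) > 0)
  expect_true("late" %in% mapping$phase[mapping$taxon == "late_taxon"])
  # a taxon uncorrelated with everything maps nowhere
  expect_false("flat_taxon" %in% mapping$taxon)
  # identical trajectories give identical phase sets
  expect_setequal(mapping$phase[mapping$taxon == "twin"], early_phases)
  # empty core gives an empty mapping
  empty <- taxa_phase_correspondence(abund, vt, ind, character(0), seg)
  expect_equal(nrow(empty$mapping), 0)
  expect_error(
    taxa_phase_correspondence(abund, vt, ind, "missing_taxon", seg),
    "missing_taxon")
})
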