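test_that("dominance screen applies the abundance and prevalence rules", {
  # taxon absent everywhere; taxon at 2% in 9/10 samples; one dominant
  m <- rbind(
    absent = rep(0, 10),
    low = c(rep(0.02, 9), 0),
    big = c(rep(0.98, 9), 1)
  )
  colnames(m) <- sprintf("s%02d", 1:10)
  tab <- make_abund(m, normalized = TRUE)
  rep <- dominance_screen(tab)
  absent <- rep[rep$taxon == "absent", ]
  expect_equal(absent$prevalence, 0)
  expect_identical(absent$class, "minor")
  expect_false(absent$passes)
  low <- rep[rep$taxon == "low", ]
  expect_equal(low$prevalence, 0.9)
  expect_true(low$passes) # mean RA 1.8% > 1%, present in 90% >= 80%
  expect_identical(low$class, "sub_dominant")
  expect_identical(rep[rep$taxon == "big", ]$class, "dominant")
  # sorted by mean RA descending
  expect_equal(rep$taxon, c("big", "low", "absent"))
})

test_that("dominance flags match a brute-force recomputation on random tables", {
  set.seed(31)
  cfg <- analysis_config()
  for (i in 1:10) {
    tab <- normalize_relative(make_abund(matrix(rpois(96, 3), 8, 12)))
    rep <- dominance_screen(tab, cfg)
    for (k in seq_len(nrow(rep))) {
      v <- tab$values[rep$taxon[k], ]
      pass <- FALSE
      if (mean(v) > cfg$dominance_abundance_threshold) {
        present <- 0
        for (s in seq_along(v)) if (v[s] > cfg$presence_epsilon) present <- present + 1
        if (present / length(v) >= cfg$dominance_prevalence_threshold) pass <- TRUE
      }
      expect_identical(rep$passes[k], pass)
    }
    # classes partition taxa
    expect_true(all(rep$class %in% c("dominant", "sub_dominant", "minor")))
    expect_equal(nrow(rep), nrow(tab$values))
  }
})

test_that("raising either dominance threshold never adds a flagged taxon", {
  set.seed(32)
  for (i in 1:5) {
    tab <- normalize_relative(make_abund(matrix(rpois(60, 2), 6, 10)))
    base <- dominance_screen(tab, analysis_config())
    stricter_a <- dominance_screen(
      tab, analysis_config(dominance_abundance_threshold = 0.05))
    stricter_p <- dominance_screen(
      tab, analysis_config(dominance_prevalence_threshold = 0.95))
    expect_true(all(stricter_a$taxon[stricter_a$passes] %in%
                      base$taxon[base$passes]))
    expect_true(all(stricter_p$taxon[stricter_p$passes] %in%
                      base$taxon[base$passes]))
  }
})

test_that("unnormalized tables are rejected", {
  expect_error(dominance_screen(make_abund(matrix(1:4, 2, 2))), "normalized")
})
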