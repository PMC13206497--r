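test_that("candidate_core is the strict triple intersection", {
  expect_identical(candidate_core(c("a", "b"), character(0), c("a")),
                   character(0))
  set.seed(51)
  pool <- sprintf("t%02d", 1:30)
  for (i in 1:10) {
    dom <- sample(pool, 12); hub <- sample(pool, 15); fla <- sample(pool, 10)
    got <- candidate_core(dom, hub, fla)
    manual <- character(0)
    for (tx in dom) if (tx %in% hub && tx %in% fla) manual <- c(manual, tx)
    expect_identical(got, manual)
  }
})

test_that("omission analysis computes percent changes and Tukey significance", {
  set.seed(52)
  mk <- function(group, mean, n = 3, sd = 0.2) {
    tibble::tibble(group = group, indicator = "umami_aa",
                   replicate = seq_len(n), value = rnorm(n, mean, sd))
  }
  d <- dplyr::bind_rows(mk("control", 10), mk("omit_a", 6), mk("omit_b", 10))
  res <- omission_analysis(d)
  a <- res[res$taxon == "a", ]
  expect_true(a$significant)
  expect_gt(a$percent_change, 20)
  b <- res[res$taxon == "b", ]
  expect_false(b$significant)
  # identical groups: zero percent change, not significant
  same <- dplyr::bind_rows(
    tibble::tibble(group = "control", indicator = "umami_aa",
                   replicate = 1:3, value = c(9.8, 10, 10.2)),
    tibble::tibble(group = "omit_c", indicator = "umami_aa",
                   replicate = 1:3, value = c(9.8, 10, 10.2)))
  res2 <- omission_analysis(same)
  expect_equal(res2$percent_change, 0)
  expect_false(res2$significant)
  # welch alternative agrees on the clear-cut case
  res_w <- omission_analysis(d, method = "welch")
  expect_true(res_w$significant[res_w$taxon == "a"])
})

test_that("omission analysis enforces its preconditions", {
  d <- tibble::tibble(group = "omit_a", indicator = "umami_aa",
                      replicate = 1:3, value = 1:3)
  expect_error(omission_analysis(d), "control")
  d2 <- dplyr::bind_rows(
    tibble::tibble(group = "control", indicator = "umami_aa",
                   replicate = 1:2, value = c(1, 2)),
    tibble::tibble(group = "omit_a", indicator = "umami_aa",
                   replicate = 1L, value = 1))
  expect_error(omission_analysis(d2), "2 replicates")
})

test_that("pruning keeps taxa significant on >= 1 indicator, retains untested", {
  om <- tibble::tibble(
    taxon = rep(c("a", "b", "c"), each = 2),
    indicator = rep(c("umami_aa", "x4eg"), 3),
    significant = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  expect_message(
    final <- prune_core(c("a", "b", "c", "untested"), om),
    "untested")
  expect_setequal(final, c("a", "c", "untested"))
  # vacuous case: nothing significant, only untested taxa survive
  om0 <- dplyr::mutate(om, significant = FALSE)
  expect_setequal(suppressMessages(prune_core(c("a", "b", "untested"), om0)),
                  "untested")
  expect_identical(prune_core(character(0), om), character(0))
  # random flags equal a brute-force filter
  set.seed(53)
  for (i in 1:10) {
    flags <- tibble::tibble(taxon = rep(letters[1:6], 2),
                            indicator = rep(c("u", "e"), each = 6),
                            significant = sample(c(TRUE, FALSE), 12, TRUE))
    cand <- letters[1:8]
    got <- suppressMessages(prune_core(cand, flags))
    manual <- cand[vapply(cand, function(tx) {
      s <- flags$significant[flags$taxon == tx]
      length(s) == 0 || any(s)
    }, logical(1))]
    expect_identical(got, manual)
  }
})

test_that("identify_core nests its sets and flags coherently", {
  sim <- simulate_fermentation(generator_config(seed = 54))
  om <- simulate_omission(sim$truth, seed = 55)
  rep <- suppressWarnings(
    identify_core(sim$abundance, sim$volatiles, omission = om))
  expect_true(all(rep$final_core %in% rep$candidate_core))
  dom_set <- rep$flags$taxon[rep$flags$dominant]
  hub_set <- rep$flags$taxon[rep$flags$hub]
  fla_set <- rep$flags$taxon[rep$flags$flavor_associated]
  expect_true(all(rep$candidate_core %in% dom_set))
  expect_true(all(rep$candidate_core %in% hub_set))
  expect_true(all(rep$candidate_core %in% fla_set))
  g <- glance(rep)
  expect_equal(g$n_final, length(rep$final_core))
  expect_equal(nrow(tidy(rep)), nrow(sim$abundance$values))
})
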