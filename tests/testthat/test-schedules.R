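test_that("shorthand parses to dated inoculation events", {
  s <- parse_schedule("W→L→P+T→Z+C")
  ev <- s$events
  expect_equal(ev$code[ev$day == 0], "W")
  expect_equal(ev$code[ev$day == 5], "L")
  expect_setequal(ev$code[ev$day == 10], c("P", "T"))
  expect_setequal(ev$code[ev$day == 25], c("Z", "C"))
  # bacteria at 1e8 CFU/g, yeasts at 1e7
  expect_true(all(ev$dose[ev$code %in% c("W", "L", "P", "T")] == 1e8))
  expect_true(all(ev$dose[ev$code %in% c("Z", "C")] == 1e7))
  # ASCII arrows accepted
  expect_equal(format_schedule(parse_schedule("W->L->P+T->Z+C")),
               "W→L→P+T→Z+C")
})

test_that("all seven published schedules round-trip exactly", {
  for (s in reference_syncom_schedules()) {
    expect_identical(format_schedule(parse_schedule(s)), s)
  }
})

test_that("invalid shorthands fail with the offending token", {
  expect_error(parse_schedule("W→W→P+T→Z+C"), "'W'.*more than once")
  expect_error(parse_schedule("W→Q→P+T→Z+C"), "Q")
  expect_error(parse_schedule("W→L→P+T"), "3 slot")
  expect_error(parse_schedule("W→L→P+T→Z+C", slot_days = c(0, 5, 5, 25)),
               "increasing")
})

test_that("random valid schedules round-trip through parse/format", {
  set.seed(71)
  codes <- strain_codes()$code
  for (i in 1:200) {
    k <- sample(2:4, 1)
    picked <- sample(codes, sample(k:min(6, length(codes)), 1))
    groups <- split(picked, sort(rep_len(seq_len(k), length(picked))))
    shorthand <- paste(vapply(groups, paste, "", collapse = "+"),
                       collapse = "→")
    slot_days <- sort(sample(0:40, k))
    expect_identical(
      format_schedule(parse_schedule(shorthand, slot_days = slot_days)),
      shorthand)
  }
})

test_that("enumeration is exhaustive, deduplicated and deterministic", {
  scheds <- enumerate_schedules()
  expect_length(scheds, 12)
  expect_false(anyDuplicated(names(scheds)) > 0)
  expect_identical(names(scheds), sort(names(scheds)))
  expect_identical(names(scheds), names(enumerate_schedules()))

  # brute-force oracle: all (starter, subset) assignments, canonicalised
  manual <- character(0)
  for (st in c("W", "L")) {
    rest <- setdiff(c("W", "L", "P", "T"), st)
    subsets <- unlist(lapply(1:2, function(sz) combn(rest, sz, simplify = FALSE)),
                      recursive = FALSE)
    for (s2 in subsets) {
      s3 <- setdiff(rest, s2)
      if (length(s3) == 0) next
      manual <- c(manual, paste(
        c(st, paste(sort(s2), collapse = "+"), paste(sort(s3), collapse = "+"),
          "C+Z"), collapse = "→"))
    }
  }
  expect_setequal(names(scheds), unique(manual))

  # the seven published rows all appear (as canonical set-schedules)
  canon <- vapply(reference_syncom_schedules(), function(s) {
    syncomcore:::canonical_shorthand(parse_schedule(s))
  }, character(1))
  expect_true(all(canon %in% names(scheds)))

  # restricting the starter restricts the first slot
  w_only <- enumerate_schedules(starters = "W")
  expect_true(all(vapply(w_only, function(s) {
    s$events$code[s$events$day == 0] == "W"
  }, logical(1))))
  # unsatisfiable constraints give an empty list, not an error
  expect_length(enumerate_schedules(starters = "Z"), 0)
})

test_that("group comparison reports ratios, contrasts and rankings", {
  set.seed(72)
  g <- simulate_group_indicators(
    c("control", "better", "same"),
    group_effects = c(better = 25), days = c(20, 40),
    noise_sd = 0.03, seed = 73)
  cmp <- compare_groups(g)
  cells <- cmp$cells
  final <- cells[cells$day == 40, ]
  expect_gt(final$ratio_to_control[final$group == "better"], 1.1)
  expect_true(final$significant[final$group == "better"])
  expect_false(final$significant[final$group == "same"])
  expect_equal(cmp$ranking$group[cmp$ranking$rank == 1], "better")
  # two-way ANOVA table carries group, day and interaction terms
  expect_setequal(setdiff(unique(cmp$anova$term), "Residuals"),
                  c("group", "fday", "group:fday"))

  # identical groups: all ratios 1, nothing significant
  same <- dplyr::bind_rows(lapply(c("control", "g1"), function(gr) {
    tibble::tibble(group = gr, indicator = "glutamic_acid",
                   day = rep(c(0, 40), each = 3), replicate = rep(1:3, 2),
                   value = rep(c(1, 8), each = 3) + rep(c(-0.1, 0, 0.1), 2))
  }))
  cmp2 <- compare_groups(same)
  expect_equal(cmp2$cells$ratio_to_control, rep(1, 4))
  expect_false(any(cmp2$cells$significant))

  expect_error(compare_groups(dplyr::filter(g, group != "control")),
               "control")
})

test_that("a 8.5 versus 8.0 glutamate outcome reports a 1.0625 ratio", {
  d <- dplyr::bind_rows(
    tibble::tibble(group = "control", indicator = "glutamic_acid", day = 40,
                   replicate = 1:3, value = c(7.9, 8.0, 8.1)),
    tibble::tibble(group = "syncom", indicator = "glutamic_acid", day = 40,
                   replicate = 1:3, value = c(8.4, 8.5, 8.6)))
  cmp <- compare_groups(d)
  expect_equal(cmp$cells$ratio_to_control[cmp$cells$group == "syncom"],
               8.5 / 8.0, tolerance = 1e-12)
})
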