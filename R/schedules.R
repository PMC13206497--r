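#' Default strain code table for SynCom schedules
#'
#' One-letter codes for the core strains used in temporal inoculation
#' shorthand, with full names and default inoculation doses (1e8 CFU/g for
#' bacteria, 1e7 CFU/g for yeasts).
#'
#' @return Tibble with columns `code`, `species`, `kingdom`, `dose`.
#' @export
strain_codes <- function() {
  tibble(
    code = c("W", "L", "P", "T", "Z", "C", "Pa", "S"),
    species = c("Weissella_paramesenteroides", "Lactiplantibacillus_plantarum",
                "Pediococcus_pentosaceus", "Tetragenococcus_halophilus",
                "Zygosaccharomyces_rouxii", "Candida_orthopsilosis",
                "Pediococcus_acidilactici", "Staphylococcus_epidermidis"),
    kingdom = c("bacteria", "bacteria", "bacteria", "bacteria", "fungi",
                "fungi", "bacteria", "bacteria"),
    dose = c(1e8, 1e8, 1e8, 1e8, 1e7, 1e7, 1e8, 1e8)
  )
}

#' Parse and format temporal inoculation schedules
#'
#' Shorthand grammar: arrow-separated slots inoculated on successive
#' `slot_days`; `+`-joined codes within a slot are inoculated together.
#' `"W→L→P+T→Z+C"` with slots (0, 5, 10, 25) therefore means W on day 0,
#' L on day 5, P and T together on day 10, and the yeasts Z and C on day 25.
#' Both `→` and ASCII `->` are accepted. Within-slot strain order is
#' preserved so `format_schedule(parse_schedule(s))` round-trips exactly.
#'
#' @param shorthand Schedule string, e.g. `"W→L→P+T→Z+C"`.
#' @param slot_days Strictly increasing inoculation days, one per arrow
#'   group. Default `c(0, 5, 10, 25)`.
#' @param codes Strain code table, see [strain_codes()].
#' @return `parse_schedule()` returns an object of class `syncom_schedule`
#'   with an `events` tibble (`day`, `code`, `species`, `dose`);
#'   `format_schedule()` returns the shorthand string.
#' @export
#' @examples
#' sched <- parse_schedule("W→L→P+T→Z+C")
#' format_schedule(sched)
parse_schedule <- function(shorthand, slot_days = c(0, 5, 10, 25),
                           codes = strain_codes()) {
  if (is.unsorted(slot_days, strictly = TRUE) || any(slot_days < 0)) {
    abort("`slot_days` must be non-negative and strictly increasing.")
  }
  norm <- gsub("->", "→", shorthand, fixed = TRUE)
  groups <- stringr::str_split_1(norm, "→")
  groups <- stringr::str_trim(groups)
  if (length(groups) != length(slot_days)) {
    abort(sprintf("schedule '%s' has %d slot(s) but %d slot day(s) given.",
                  shorthand, length(groups), length(slot_days)))
  }
  seen <- character(0)
  events <- purrr::map2_dfr(groups, slot_days, function(grp, day) {
    toks <- stringr::str_trim(stringr::str_split_1(grp, "\\+"))
    if (any(toks == "")) abort(sprintf("empty strain token in slot '%s'.", grp))
    unknown <- setdiff(toks, codes$code)
    if (length(unknown)) {
      abort(sprintf("unknown strain code(s): %s", paste(unknown, collapse = ", ")))
    }
    dup <- intersect(toks, seen)
    dup <- c(dup, toks[duplicated(toks)])
    if (length(dup)) {
      abort(sprintf("strain '%s' inoculated more than once.", dup[1]))
    }
    seen <<- c(seen, toks)
    tibble(day = day, code = toks,
           species = codes$species[match(toks, codes$code)],
           dose = codes$dose[match(toks, codes$code)])
  })
  structure(list(events = events, slot_days = slot_days),
            class = "syncom_schedule")
}

#' @rdname parse_schedule
#' @param schedule A `syncom_schedule`.
#' @param arrow Separator to use when formatting. Default `"→"`.
#' @export
format_schedule <- function(schedule, arrow = "→") {
  stopifnot(inherits(schedule, "syncom_schedule"))
  groups <- vapply(schedule$slot_days, function(d) {
    paste(schedule$events$code[schedule$events$day == d], collapse = "+")
  }, character(1))
  paste(groups, collapse = arrow)
}

#' @export
print.syncom_schedule <- function(x, ...) {
  cat(sprintf("<syncom_schedule> %s\n", format_schedule(x)))
  print(x$events)
  invisible(x)
}

#' @rdname parse_schedule
#' @param x A `syncom_schedule`.
#' @param ... Unused.
#' @export
tidy.syncom_schedule <- function(x, ...) x$events

# canonical shorthand: within-slot codes sorted, used for deduplication
canonical_shorthand <- function(schedule) {
  groups <- vapply(schedule$slot_days, function(d) {
    paste(sort(schedule$events$code[schedule$events$day == d]), collapse = "+")
  }, character(1))
  paste(groups, collapse = "→")
}

#' Enumerate constraint-valid temporal SynCom schedules
#'
#' Design rules mirroring the temporal-assembly experiment: the fermentation
#' starts with a single LAB starter (W or L) on the first slot day; the
#' remaining LAB are distributed over the second and third slots (each slot
#' non-empty); the two yeasts are fixed at the final slot. Within-slot order
#' is canonical (alphabetical); the output is deduplicated and sorted by
#' shorthand, so the enumeration is deterministic.
#'
#' @param starters Allowed starter codes. Default `c("W", "L")`.
#' @param lab LAB codes to distribute over the first three slots.
#'   Default `c("W", "L", "P", "T")`.
#' @param yeasts Yeast codes fixed at the final slot. Default `c("Z", "C")`.
#' @param slot_days Inoculation days. Default `c(0, 5, 10, 25)`.
#' @param codes Strain code table.
#' @return Named list of `syncom_schedule` objects (names are canonical
#'   shorthands); empty list when the constraints are unsatisfiable.
#' @export
#' @examples
#' length(enumerate_schedules()) # 12 distinct schedules
enumerate_schedules <- function(starters = c("W", "L"),
                                lab = c("W", "L", "P", "T"),
                                yeasts = c("Z", "C"),
                                slot_days = c(0, 5, 10, 25),
                                codes = strain_codes()) {
  out <- list()
  for (st in intersect(starters, lab)) {
    rest <- setdiff(lab, st)
    if (length(rest) < 2) next # both middle slots must be non-empty
    n <- length(rest)
    for (mask in seq_len(2^n - 2)) { # proper non-empty subsets for slot 2
      in_slot2 <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      slot2 <- sort(rest[in_slot2])
      slot3 <- sort(rest[!in_slot2])
      shorthand <- paste(
        c(st, paste(slot2, collapse = "+"), paste(slot3, collapse = "+"),
          paste(sort(yeasts), collapse = "+")),
        collapse = "→"
      )
      sched <- parse_schedule(shorthand, slot_days, codes)
      out[[canonical_shorthand(sched)]] <- sched
    }
  }
  if (length(out) == 0) return(list())
  out[order(names(out))]
}

#' The published seven-row temporal assembly design
#'
#' Shorthand strings of the seven SynCom groups evaluated in the temporal
#' assembly experiment the package's defaults emulate (LAB over days 0/5/10,
#' yeasts on day 25). Two rows differ only in within-slot order and are the
#' same schedule as sets.
#'
#' @return Character vector of seven shorthand strings.
#' @export
reference_syncom_schedules <- function() {
  c("W→L→P+T→Z+C",
    "W→P→L+T→Z+C",
    "W→T→L+P→Z+C",
    "W→T+P→L→Z+C",
    "L→W→P+T→Z+C",
    "L→W→T+P→Z+C",
    "L→P→T+W→Z+C")
}

#' Compare fermentation outcomes across schedule groups
#'
#' Per indicator: a two-way ANOVA (group x day) over all measurements, then
#' per-day group means, ratios to the control group and Tukey HSD contrasts
#' against control; finally a ranking of groups by final-day mean.
#'
#' @param measurements Long tibble with columns `group`, `indicator`, `day`,
#'   `replicate`, `value`; at least 2 replicates per group and day.
#' @param control_group Name of the control group. Default `"control"`.
#' @param config An [analysis_config()]; `omission_alpha` is the contrast
#'   significance level.
#' @return Object of class `group_comparison`: `anova` (two-way ANOVA
#'   table per indicator), `cells` (per indicator/day/group mean,
#'   `ratio_to_control`, `p_vs_control`, `significant`), and `ranking`
#'   (final-day group ranking per indicator).
#' @export
compare_groups <- function(measurements, control_group = "control",
                           config = analysis_config()) {
  need <- c("group", "indicator", "day", "replicate", "value")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols)) {
    abort(sprintf("measurements lack column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!control_group %in% measurements$group) {
    abort(sprintf("control group '%s' absent from measurements.", control_group))
  }
  cell_counts <- dplyr::count(measurements, .data$group, .data$indicator,
                              .data$day)
  if (any(cell_counts$n < 2)) {
    abort("every group needs >= 2 replicates at every compared timepoint.")
  }
  indicators <- unique(measurements$indicator)
  anova_tbl <- purrr::map_dfr(indicators, function(ind) {
    d <- filter(measurements, .data$indicator == ind) %>%
      mutate(group = factor(.data$group), fday = factor(.data$day))
    # a single compared timepoint degenerates to a one-way layout
    fml <- if (nlevels(d$fday) > 1) value ~ group * fday else value ~ group
    fit <- aov(fml, data = d)
    sm <- summary(fit)[[1]]
    tibble(indicator = ind,
           term = stringr::str_trim(rownames(sm)),
           df = sm$Df, statistic = sm$`F value`, p_value = sm$`Pr(>F)`)
  })
  cells <- purrr::map_dfr(indicators, function(ind) {
    purrr::map_dfr(sort(unique(measurements$day)), function(dd) {
      d <- filter(measurements, .data$indicator == ind, .data$day == dd)
      d$group <- stats::relevel(factor(d$group), ref = control_group)
      means <- d %>% group_by(.data$group) %>%
        summarise(mean = mean(.data$value), .groups = "drop")
      ctrl <- means$mean[means$group == control_group]
      other <- setdiff(levels(d$group), control_group)
      p <- rep(NA_real_, length(other))
      if (length(other)) {
        tk <- suppressWarnings(TukeyHSD(aov(value ~ group, data = d)))$group
        p <- as.numeric(tk[match(paste0(other, "-", control_group),
                                 rownames(tk)), "p adj"])
      }
      tibble(indicator = ind, day = dd,
             group = c(control_group, other),
             mean = means$mean[match(c(control_group, other), means$group)],
             ratio_to_control = .data$mean / ctrl,
             p_vs_control = c(NA_real_, p)) %>%
        mutate(significant = !is.na(.data$p_vs_control) &
                 .data$p_vs_control < config$omission_alpha)
    })
  })
  final_day <- max(measurements$day)
  ranking <- cells %>%
    filter(.data$day == final_day) %>%
    group_by(.data$indicator) %>%
    arrange(desc(.data$mean), .by_group = TRUE) %>%
    mutate(rank = dplyr::row_number()) %>%
    ungroup() %>%
    select("indicator", "group", "mean", "ratio_to_control", "rank")
  structure(list(anova = anova_tbl, cells = cells, ranking = ranking,
                 control_group = control_group, final_day = final_day),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> control '%s', final day %g\n",
              x$control_group, x$final_day))
  print(x$ranking)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$cells

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  x$anova %>%
    filter(.data$term != "Residuals") %>%
    select("indicator", "term", "statistic", "p_value")
}
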