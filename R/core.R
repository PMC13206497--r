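#' Candidate core taxa: triple-criterion intersection
#'
#' A taxon is a candidate core member when it passes all three screening
#' criteria: dominance (abundance + prevalence), network hubness, and
#' flavor association. The combination rule is strict set intersection.
#'
#' @param dominance A `dominance_report` (from [dominance_screen()]) or a
#'   character vector of taxa passing the dominance criterion.
#' @param hubs Character vector of hub taxa (from [hub_taxa()]).
#' @param flavor Character vector of flavor-associated taxa (from
#'   [flavor_associated_taxa()]`$taxa`).
#' @return Character vector of candidate core taxa, ordered as in
#'   `dominance`.
#' @export
candidate_core <- function(dominance, hubs, flavor) {
  dominant <- if (inherits(dominance, "dominance_report")) {
    dominance$taxon[dominance$passes]
  } else {
    as.character(dominance)
  }
  dominant[dominant %in% hubs & dominant %in% flavor]
}

#' Omission-experiment analysis
#'
#' Compares each omission group (`"omit_<taxon>"`) against the control on
#' every measured indicator: percent change of the group mean relative to the
#' control mean, with significance from one-way ANOVA across all groups
#' followed by Tukey's HSD contrast against control at `omission_alpha`
#' (`method = "welch"` substitutes Welch t-tests with Benjamini-Hochberg
#' correction).
#'
#' @param measurements Long tibble with columns `group`, `indicator`,
#'   `replicate`, `value`; the control group must be named `"control"` and
#'   every group needs at least 2 replicates.
#' @param config An [analysis_config()].
#' @param method `"tukey"` (default) or `"welch"`.
#' @return A tibble of class `omission_results`: `taxon`, `indicator`,
#'   `control_mean`, `omitted_mean`, `percent_change`, `p_value`,
#'   `significant`.
#' @export
omission_analysis <- function(measurements, config = analysis_config(),
                              method = c("tukey", "welch")) {
  method <- arg_match(method)
  need <- c("group", "indicator", "replicate", "value")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols)) {
    abort(sprintf("measurements lack column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"control" %in% measurements$group) {
    abort("no 'control' group in the omission measurements.")
  }
  rep_counts <- dplyr::count(measurements, .data$group, .data$indicator)
  if (any(rep_counts$n < 2)) {
    bad <- rep_counts[rep_counts$n < 2, ]
    abort(sprintf("fewer than 2 replicates for group(s): %s",
                  paste(unique(bad$group), collapse = ", ")))
  }
  out <- purrr::map_dfr(unique(measurements$indicator), function(ind) {
    d <- filter(measurements, .data$indicator == ind)
    d$group <- stats::relevel(factor(d$group), ref = "control")
    means <- d %>% group_by(.data$group) %>%
      summarise(mean = mean(.data$value), .groups = "drop")
    ctrl_mean <- means$mean[means$group == "control"]
    omit_groups <- setdiff(levels(d$group), "control")
    pvals <- if (method == "tukey") {
      fit <- aov(value ~ group, data = d)
      tk <- suppressWarnings(TukeyHSD(fit))$group
      # contrasts are "<group>-control" with control as reference level
      p <- tk[match(paste0(omit_groups, "-control"), rownames(tk)), "p adj"]
      setNames(as.numeric(p), omit_groups)
    } else {
      p <- vapply(omit_groups, function(g) {
        tryCatch(stats::t.test(d$value[d$group == g],
                               d$value[d$group == "control"])$p.value,
                 error = function(e) NA_real_)
      }, numeric(1))
      setNames(p.adjust(p, method = "BH"), omit_groups)
    }
    tibble(
      taxon = sub("^omit_", "", omit_groups),
      indicator = ind,
      control_mean = ctrl_mean,
      omitted_mean = means$mean[match(omit_groups, means$group)],
      p_value = unname(pvals[omit_groups])
    )
  })
  out <- out %>%
    mutate(
      percent_change = ifelse(.data$control_mean > 0,
                              (.data$control_mean - .data$omitted_mean) /
                                .data$control_mean * 100, NA_real_),
      significant = !is.na(.data$p_value) & .data$p_value < config$omission_alpha
    ) %>%
    select("taxon", "indicator", "control_mean", "omitted_mean",
           "percent_change", "p_value", "significant")
  class(out) <- c("omission_results", class(out))
  out
}

#' Prune the candidate core with omission outcomes
#'
#' Drops candidates that are significant for none of the tested indicators;
#' keeps candidates significant for at least one. Candidates without any
#' omission data (e.g. the koji mold, which cannot be omitted from
#' koji-based fermentations) pass pruning by default, with a message.
#'
#' @param candidate Character vector of candidate core taxa.
#' @param omission An `omission_results` tibble (or any tibble with columns
#'   `taxon` and `significant`).
#' @return Character vector: the final core set.
#' @export
prune_core <- function(candidate, omission) {
  if (length(candidate) == 0) return(character(0))
  if (!all(c("taxon", "significant") %in% names(omission))) {
    abort("`omission` needs columns `taxon` and `significant`.")
  }
  untested <- setdiff(candidate, omission$taxon)
  if (length(untested)) {
    inform(sprintf("retained without omission data: %s",
                   paste(untested, collapse = ", ")))
  }
  keep <- vapply(candidate, function(tx) {
    rows <- omission$significant[omission$taxon == tx]
    length(rows) == 0 || any(rows)
  }, logical(1))
  candidate[keep]
}

#' Identify the core microbiome of a fermentation
#'
#' Runs the full selection pipeline: dominance screen, co-occurrence network
#' with hub detection, taxon-volatile association, strict triple
#' intersection, and (when omission measurements are supplied) omission-based
#' pruning to the final core.
#'
#' @param abundance An [abundance_table()]; closed to relative abundances
#'   automatically when raw.
#' @param volatiles A [volatile_table()] over the same samples.
#' @param omission Optional long omission tibble (see [omission_analysis()]);
#'   when `NULL` the final core equals the candidate core.
#' @param config An [analysis_config()].
#' @return An object of class `core_report`: per-taxon criterion flags
#'   (`flags`), the `dominance` report, the analysis `network`, the `flavor`
#'   association result, `candidate_core`, `omission_results` (or NULL) and
#'   `final_core`.
#' @export
#' @examples
#' sim <- simulate_fermentation(generator_config(seed = 7))
#' rep <- identify_core(sim$abundance, sim$volatiles,
#'                      omission = simulate_omission(sim$truth, seed = 8))
#' rep$final_core
identify_core <- function(abundance, volatiles, omission = NULL,
                          config = analysis_config()) {
  if (!abundance$normalized) abundance <- normalize_relative(abundance)
  dom <- dominance_screen(abundance, config)
  net <- build_cooccurrence(abundance, config, kind = "analysis")
  hubs <- hub_taxa(net, config)
  flav <- flavor_associated_taxa(abundance, volatiles, config)
  cand <- candidate_core(dom, hubs, flav$taxa)
  om_res <- NULL
  final <- cand
  if (!is.null(omission)) {
    om_res <- omission_analysis(omission, config)
    final <- prune_core(cand, om_res)
  }
  flags <- tibble(taxon = dom$taxon) %>%
    left_join(select(as_tibble(dom), "taxon", "mean_ra", "prevalence",
                     dominant = "passes"), by = "taxon") %>%
    mutate(
      hub = .data$taxon %in% hubs,
      flavor_associated = .data$taxon %in% flav$taxa,
      candidate = .data$taxon %in% cand,
      final = .data$taxon %in% final
    )
  structure(
    list(flags = flags, dominance = dom, network = net, flavor = flav,
         candidate_core = cand, omission_results = om_res,
         final_core = final, config = config),
    class = "core_report"
  )
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("<core_report> %d taxa screened\n", nrow(x$flags)))
  cat(sprintf("  dominant %d | hubs %d | flavor-associated %d\n",
              sum(x$flags$dominant), sum(x$flags$hub),
              sum(x$flags$flavor_associated)))
  cat(sprintf("  candidate core (%d): %s\n", length(x$candidate_core),
              paste(x$candidate_core, collapse = ", ")))
  cat(sprintf("  final core (%d): %s\n", length(x$final_core),
              paste(x$final_core, collapse = ", ")))
  invisible(x)
}

#' @rdname identify_core
#' @param x A `core_report`.
#' @param ... Unused.
#' @export
tidy.core_report <- function(x, ...) x$flags

#' @rdname identify_core
#' @export
glance.core_report <- function(x, ...) {
  tibble(
    n_taxa = nrow(x$flags),
    n_dominant = sum(x$flags$dominant),
    n_hub = sum(x$flags$hub),
    n_flavor = sum(x$flags$flavor_associated),
    n_candidate = length(x$candidate_core),
    n_final = length(x$final_core)
  )
}

#' @rdname identify_core
#' @param report A `core_report`.
#' @param path Base path; writes `<path>.json` and `<path>_flags.tsv`.
#' @export
write_core_report <- function(report, path) {
  readr::write_tsv(report$flags, paste0(path, "_flags.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      candidate_core = report$candidate_core,
      final_core = report$final_core,
      omission_results = report$omission_results,
      flags = report$flags
    ),
    paste0(path, ".json"), digits = NA
  )
  invisible(path)
}
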