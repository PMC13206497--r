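# Planted-truth fermentation simulator. The generated world mimics a 40-day
# soy-sauce-style brine fermentation: an early guild (lactic acid bacteria
# plus the koji mold) that dominates the first week and then declines, a
# salt-tolerant late-LAB guild that takes over mid-fermentation, and a yeast
# guild that blooms after the late changepoint. Guild members share a latent
# step signal (built from logistic transitions at the planted changepoints),
# which makes them a correlation clique; core members additionally get high
# abundance and planted volatile producer links, so they pass all three
# selection criteria in expectation. Decoy taxa pass one or two criteria only.

preserve_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

logistic_step <- function(t, center, width) stats::plogis((t - center) / width)

canonical_core_roster <- function() {
  tibble(
    taxon = c("Weissella_paramesenteroides", "Tetragenococcus_halophilus",
              "Zygosaccharomyces_rouxii", "Lactiplantibacillus_plantarum",
              "Pediococcus_pentosaceus", "Candida_orthopsilosis",
              "Aspergillus_oryzae", "Pediococcus_acidilactici",
              "Staphylococcus_epidermidis"),
    kingdom = c("bacteria", "bacteria", "fungi", "bacteria", "bacteria",
                "fungi", "fungi", "bacteria", "bacteria"),
    guild = c("early", "late_lab", "yeast", "early", "late_lab", "yeast",
              "early", "late_lab", "early")
  )
}

# Per-guild latent log-abundance signals as plateau values joined by logistic
# transitions at the planted changepoints (width ~1 day): four phase levels.
guild_signal <- function(guild, t, cps, width) {
  s <- vapply(cps, function(cp) logistic_step(t, cp, width), numeric(length(t)))
  if (is.null(dim(s))) s <- matrix(s, nrow = length(t))
  switch(guild,
    early    = 2.0 - 1.5 * s[, 1] - 1.5 * s[, 2] - 0.5 * s[, 3],
    late_lab = -1.5 + 1.5 * s[, 1] + 1.5 * s[, 2] + 0.3 * s[, 3],
    yeast    = -2.0 + 0.3 * s[, 2] + 3.5 * s[, 3],
    abort(sprintf("unknown guild '%s'", guild))
  )
}

indicator_mean_curves <- function(t) {
  list(
    glutamic_acid  = 0.5 + 7.5 * logistic_step(t, 10, 4),
    umami_aa       = 1.0 + 9.0 * logistic_step(t, 11, 4.5),
    x4eg           = 1.0 + 60 * logistic_step(t, 30, 2.5),
    lactic_acid    = 0.3 + (4 / 3) * (logistic_step(t, 3, 0.8) +
                                        logistic_step(t, 8, 0.8) +
                                        logistic_step(t, 15, 1.5)),
    reducing_sugar = 2.0 + 19 * logistic_step(t, 6, 2) -
      14 * logistic_step(t, 22, 3),
    amino_nitrogen = 0.2 + 1.0 * logistic_step(t, 12, 5),
    total_nitrogen = 1.6 + 0.2 * logistic_step(t, 10, 5),
    pH             = 6.2 - 1.4 * logistic_step(t, 6, 3)
  )
}

#' Simulate a fermentation dataset with planted ground truth
#'
#' Generates an abundance table, a volatile table and indicator series for a
#' multi-phase brine fermentation, together with a `synthetic_truth` record of
#' everything planted: the core taxa (guaranteed, in expectation, to pass the
#' dominance, hub and flavor-association criteria), the correlation guild
#' cliques, the taxon-volatile producer links, the changepoint days and the
#' early/late indicator sides. Decoy taxa that pass only one or two criteria
#' (flat abundant taxa; low-abundance clique fillers; independent volatile
#' producers, including one with just four links) keep the triple
#' intersection non-trivial.
#'
#' Replicates share each taxon's latent trajectory and differ only by
#' log-normal multiplicative noise (`noise_sd` on the log scale) applied
#' before compositional closure, so `noise_sd = 0` gives identical replicate
#' columns and every column always sums to 1.
#'
#' @param config A [generator_config()].
#' @return A list of class `fermentation_sim` with elements `abundance`
#'   (normalized [abundance_table()]), `volatiles` ([volatile_table()]),
#'   `indicators` (long tibble), `truth` (`synthetic_truth`) and `config`.
#' @export
#' @examples
#' sim <- simulate_fermentation(generator_config(seed = 42))
#' sim$truth$core_taxa
simulate_fermentation <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  restore <- preserve_rng(config$seed)
  on.exit(restore(), add = TRUE)

  n_tp <- config$n_timepoints
  days <- seq(0, config$total_days, length.out = n_tp)
  b_idx <- unique(pmin(pmax(floor((1:3) * n_tp / 4), 1L), n_tp - 1L))
  if (length(b_idx) < 3) abort("too few timepoints to plant four phases.")
  changepoints <- (days[b_idx] + days[b_idx + 1]) / 2
  phase_labels <- c("immediate_early", "early", "middle", "late")
  phase_of_tp <- phase_labels[1 + rowSums(outer(seq_len(n_tp), b_idx, ">"))]
  step_width <- config$total_days / 40

  ## ---- roster ------------------------------------------------------------
  core <- utils::head(canonical_core_roster(), min(config$n_core, 9L))
  if (config$n_core > 9) {
    extra <- config$n_core - 9L
    core <- bind_rows(core, tibble(
      taxon = sprintf("Core_sp_%02d", seq_len(extra)),
      kingdom = "bacteria",
      guild = rep(c("early", "late_lab", "yeast"), length.out = extra)
    ))
  }
  core$role <- "core"
  pool_b <- config$n_bacterial_taxa - sum(core$kingdom == "bacteria")
  pool_f <- config$n_fungal_taxa - sum(core$kingdom == "fungi")
  if (pool_b < 0 || pool_f < 0) {
    abort("roster smaller than the planted core for one kingdom.")
  }
  b_counter <- 0L; f_counter <- 0L
  take_b <- function(n) {
    n <- min(n, pool_b); pool_b <<- pool_b - n
    out <- sprintf("Bacterium_sp_%02d", b_counter + seq_len(n))
    b_counter <<- b_counter + n
    out
  }
  take_f <- function(n) {
    n <- min(n, pool_f); pool_f <<- pool_f - n
    out <- sprintf("Fungus_sp_%02d", f_counter + seq_len(n))
    f_counter <<- f_counter + n
    out
  }
  mk <- function(taxon, kingdom, guild, role) {
    if (length(taxon) == 0) return(NULL)
    tibble(taxon = taxon, kingdom = kingdom, guild = guild, role = role)
  }
  fillers <- bind_rows(
    mk(take_b(max(0L, config$clique_size - sum(core$guild == "early"))),
       "bacteria", "early", "filler"),
    mk(take_b(max(0L, config$clique_size - sum(core$guild == "late_lab"))),
       "bacteria", "late_lab", "filler"),
    mk(take_f(max(0L, config$clique_size - sum(core$guild == "yeast"))),
       "fungi", "yeast", "filler")
  )
  decoys <- bind_rows(
    mk(take_b(2L), "bacteria", NA_character_, "dominant_decoy"),
    mk(take_f(2L), "fungi", NA_character_, "dominant_decoy"),
    mk(take_b(2L), "bacteria", NA_character_, "flavor_decoy"),
    mk(take_f(1L), "fungi", NA_character_, "boundary_decoy")
  )
  background <- bind_rows(
    mk(take_b(pool_b), "bacteria", NA_character_, "background"),
    mk(take_f(pool_f), "fungi", NA_character_, "background")
  )
  roster <- bind_rows(core, fillers, decoys, background)
  n_taxa <- nrow(roster)

  ## ---- latent log-abundance trajectories ---------------------------------
  latent <- matrix(NA_real_, n_taxa, n_tp,
                   dimnames = list(roster$taxon, NULL))
  osc_levels <- seq(-1.2, 1.2, length.out = n_tp)
  for (i in seq_len(n_taxa)) {
    role <- roster$role[i]
    if (role %in% c("core", "filler")) {
      base <- if (role == "core") log(30) else log(1.5)
      load <- runif(1, 0.8, 1.2)
      latent[i, ] <- base +
        load * guild_signal(roster$guild[i], days, changepoints, step_width)
    } else if (role == "dominant_decoy") {
      next # planted after the rest: constant *relative* share
    } else if (role %in% c("flavor_decoy", "boundary_decoy")) {
      latent[i, ] <- log(2) + sample(osc_levels)
    } else {
      latent[i, ] <- log(runif(1, 0.2, 1.0)) + cumsum(rnorm(n_tp, 0, 0.35))
    }
  }
  # Dominant-only decoys hold a constant share of the community (dominance is
  # defined on relative abundance): pinning them to the trajectory of the
  # community total keeps them trend-free after compositional closure, so
  # they pass dominance but correlate with nothing.
  dom_idx <- which(roster$role == "dominant_decoy")
  if (length(dom_idx)) {
    total_others <- colSums(exp(latent[-dom_idx, , drop = FALSE]))
    for (i in dom_idx) {
      latent[i, ] <- log(runif(1, 0.02, 0.04) * total_others)
    }
  }

  ## ---- samples: replicate noise + compositional closure -------------------
  n_rep <- config$n_replicates
  sample_meta <- tidyr::expand_grid(day = days, replicate = seq_len(n_rep)) %>%
    mutate(sample_id = sprintf("d%g_r%d", .data$day, .data$replicate),
           group = "simulated") %>%
    select("sample_id", "day", "replicate", "group")
  latent_samples <- latent[, rep(seq_len(n_tp), each = n_rep), drop = FALSE]
  noise <- matrix(rnorm(n_taxa * ncol(latent_samples), 0, config$noise_sd),
                  n_taxa, ncol(latent_samples))
  raw <- exp(latent_samples + noise)
  colnames(raw) <- sample_meta$sample_id
  ra <- sweep(raw, 2, colSums(raw), "/")
  abundance <- abundance_table(ra, sample_meta, level = "species",
                               normalized = TRUE)

  ## ---- volatiles with planted producer links -----------------------------
  class_weights <- c(alcohol = 16, phenol = 6, pyrazine = 10, aldehyde = 21,
                     ketone = 26, ester = 47, acid = 9)
  n_per_class <- round(class_weights / sum(class_weights) * config$n_volatiles)
  shortfall <- config$n_volatiles - sum(n_per_class)
  n_per_class[which.max(n_per_class)] <-
    n_per_class[which.max(n_per_class)] + shortfall
  compounds <- tibble(
    class = rep(names(n_per_class), n_per_class)
  ) %>%
    group_by(.data$class) %>%
    mutate(compound = sprintf("%s_%02d", .data$class, dplyr::row_number())) %>%
    ungroup() %>%
    select("compound", "class")

  guild_classes <- list(
    early = c("acid", "aldehyde", "ketone"),
    late_lab = c("acid", "ester", "pyrazine"),
    yeast = c("alcohol", "phenol", "ester")
  )
  assigned <- logical(nrow(compounds))
  pick_compounds <- function(preferred, n) {
    cand <- which(!assigned & compounds$class %in% preferred)
    if (length(cand) < n) cand <- c(cand, which(!assigned & !(seq_along(assigned) %in% cand)))
    sel <- utils::head(cand, n)
    assigned[sel] <<- TRUE
    sel
  }
  producers <- roster %>%
    filter(.data$role %in% c("core", "flavor_decoy", "boundary_decoy"))
  links <- purrr::pmap_dfr(producers, function(taxon, kingdom, guild, role) {
    n_links <- if (role == "boundary_decoy") 4L else config$n_producer_links
    preferred <- if (role == "core") guild_classes[[guild]] else names(class_weights)
    sel <- pick_compounds(preferred, n_links)
    tibble(taxon = taxon, compound = compounds$compound[sel],
           effect = config$producer_effect * runif(length(sel), 0.8, 1.2))
  })

  baseline <- runif(nrow(compounds), 5, 30)
  conc <- matrix(rep(baseline, ncol(ra)), nrow(compounds), ncol(ra),
                 dimnames = list(compounds$compound, colnames(ra)))
  for (k in seq_len(nrow(links))) {
    conc[links$compound[k], ] <- conc[links$compound[k], ] +
      links$effect[k] * ra[links$taxon[k], ]
  }
  conc <- conc * exp(matrix(rnorm(length(conc), 0, config$noise_sd / 2),
                            nrow(conc), ncol(conc)))
  volatiles <- volatile_table(conc, compounds, sample_meta)

  ## ---- indicator series ---------------------------------------------------
  curves <- indicator_mean_curves(days)
  indicators <- purrr::imap_dfr(curves, function(mu, name) {
    tidyr::expand_grid(tp = seq_len(n_tp), replicate = seq_len(n_rep)) %>%
      mutate(indicator = name, day = days[.data$tp],
             value = if (name == "pH") {
               mu[.data$tp] + rnorm(n(), 0, config$noise_sd / 6)
             } else {
               mu[.data$tp] * exp(rnorm(n(), 0, config$noise_sd / 3))
             }) %>%
      select("indicator", "day", "replicate", "value")
  })

  truth <- structure(
    list(
      core_taxa = core$taxon,
      clique_memberships = split(
        roster$taxon[roster$role %in% c("core", "filler")],
        roster$guild[roster$role %in% c("core", "filler")]
      ),
      producer_links = links,
      changepoints = changepoints,
      phase_assignment = tibble(day = days, phase = phase_of_tp),
      # total_nitrogen is deliberately unlisted: its planted signal is nearly
      # flat, a decoy indicator whose side is noise-dominated by design
      early_indicators = c("glutamic_acid", "umami_aa", "lactic_acid",
                           "reducing_sugar", "amino_nitrogen"),
      late_indicators = c("x4eg", "pH"),
      roles = roster
    ),
    class = "synthetic_truth"
  )

  structure(
    list(abundance = abundance, volatiles = volatiles,
         indicators = indicators, truth = truth, config = config),
    class = "fermentation_sim"
  )
}

#' @export
print.fermentation_sim <- function(x, ...) {
  cat(sprintf("<fermentation_sim> seed %d: %d taxa, %d volatiles, %d samples\n",
              x$config$seed, nrow(x$abundance$values),
              nrow(x$volatiles$values), ncol(x$abundance$values)))
  cat(sprintf("  planted core (%d): %s\n", length(x$truth$core_taxa),
              paste(x$truth$core_taxa, collapse = ", ")))
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d core taxa, %d cliques, %d producer links\n",
              length(x$core_taxa), length(x$clique_memberships),
              nrow(x$producer_links)))
  cat(sprintf("  changepoints at day %s\n",
              paste(x$changepoints, collapse = ", ")))
  invisible(x)
}

#' Default planted omission effect sizes
#'
#' Percent decreases in umami amino acids and 4-ethylguaiacol caused by
#' omitting each core taxon, anchored on effect magnitudes typical of
#' leave-one-out fermentations (15-60%). Every planted core member is
#' functionally active on at least one indicator, so the full pipeline's
#' pruning step retains the planted core under default conditions.
#'
#' @param core_taxa Character vector of core taxon names.
#' @return Tibble with columns `taxon`, `umami_effect`, `eg_effect` (percent).
#' @export
default_omission_effects <- function(core_taxa) {
  umami <- c(27.2, 15.8, 25.9, 15.5)
  eg <- c(42.8, 45.6, 56.5)
  tibble(
    taxon = core_taxa,
    umami_effect = rep(umami, length.out = length(core_taxa)),
    eg_effect = rep(eg, length.out = length(core_taxa))
  )
}

#' Simulate omission-experiment measurements
#'
#' Draws replicate measurements of the two fermentation indicators (umami
#' amino acids, 4-ethylguaiacol) for a control group (full consortium) and one
#' omission group per taxon, with each omission group's mean reduced by its
#' planted percent effect. Noise is Gaussian with standard deviation
#' `noise_sd` times the control mean (so `noise_sd = 0.05` is "5% noise").
#'
#' @param truth A `synthetic_truth`, or a character vector of core taxa.
#' @param effects Tibble with columns `taxon`, `umami_effect`, `eg_effect`
#'   (percent decreases; may be negative for increases). Defaults to
#'   [default_omission_effects()] over the core taxa.
#' @param control_means Named vector: mean `umami_aa` (g/L) and `x4eg` (ug/L)
#'   of the control group.
#' @param n_replicates Replicates per group (>= 2 for testing). Default 3.
#' @param noise_sd Relative noise level. Default 0.05.
#' @param seed Integer seed.
#' @return Long tibble (`group`, `indicator`, `replicate`, `value`) with
#'   groups `"control"` and `"omit_<taxon>"`.
#' @export
simulate_omission <- function(truth,
                              effects = NULL,
                              control_means = c(umami_aa = 10, x4eg = 64),
                              n_replicates = 3L,
                              noise_sd = 0.05,
                              seed = 1L) {
  core_taxa <- if (inherits(truth, "synthetic_truth")) truth$core_taxa else truth
  if (is.null(effects)) effects <- default_omission_effects(core_taxa)
  missing_taxa <- setdiff(core_taxa, effects$taxon)
  if (length(missing_taxa)) {
    abort(sprintf("no omission effect defined for: %s",
                  paste(missing_taxa, collapse = ", ")))
  }
  restore <- preserve_rng(seed)
  on.exit(restore(), add = TRUE)
  effects <- filter(effects, .data$taxon %in% core_taxa)
  group_means <- bind_rows(
    tibble(group = "control", indicator = names(control_means),
           mean = unname(control_means)),
    tidyr::pivot_longer(effects, -"taxon", names_to = "which",
                        values_to = "effect") %>%
      mutate(indicator = ifelse(.data$which == "umami_effect",
                                "umami_aa", "x4eg"),
             group = paste0("omit_", .data$taxon),
             mean = unname(control_means[.data$indicator]) *
               (1 - .data$effect / 100)) %>%
      select("group", "indicator", "mean")
  )
  if (any(group_means$mean < 0)) {
    abort("planted effect implies a negative group mean.")
  }
  group_means %>%
    tidyr::expand_grid(replicate = seq_len(n_replicates)) %>%
    mutate(value = rnorm(n(), .data$mean,
                         noise_sd * unname(control_means[.data$indicator]))) %>%
    select("group", "indicator", "replicate", "value")
}

#' Simulate indicator series for schedule-comparison groups
#'
#' Produces replicate glutamate-like indicator trajectories for a set of
#' fermentation groups (e.g. SynCom schedules plus a control). Each group's
#' planted percent effect ramps linearly from zero at day 0 to its full value
#' at the final day, emulating a treatment whose benefit accrues over the
#' fermentation.
#'
#' @param groups Character vector of group names; must include
#'   `control_group`.
#' @param group_effects Named numeric vector of final-day percent effects
#'   (positive = higher than control); groups not named get 0.
#' @param control_group Name of the control group. Default `"control"`.
#' @param days Sampling days.
#' @param indicator Indicator name. Default `"glutamic_acid"`.
#' @param base_final Final-day control mean. Default 8 g/L.
#' @param n_replicates Replicates per group and day. Default 3.
#' @param noise_sd Relative noise level. Default 0.05.
#' @param seed Integer seed.
#' @return Long tibble (`group`, `indicator`, `day`, `replicate`, `value`).
#' @export
simulate_group_indicators <- function(groups,
                                      group_effects = NULL,
                                      control_group = "control",
                                      days = seq(0, 40, by = 5),
                                      indicator = "glutamic_acid",
                                      base_final = 8,
                                      n_replicates = 3L,
                                      noise_sd = 0.05,
                                      seed = 1L) {
  if (!control_group %in% groups) {
    abort(sprintf("`groups` must include the control group '%s'.", control_group))
  }
  restore <- preserve_rng(seed)
  on.exit(restore(), add = TRUE)
  base_curve <- base_final / 8 * (0.5 + 7.5 * logistic_step(days, 10, 4))
  ramp <- if (max(days) > 0) days / max(days) else rep(1, length(days))
  purrr::map_dfr(groups, function(g) {
    eff <- if (!is.null(group_effects) && g %in% names(group_effects)) {
      group_effects[[g]]
    } else 0
    mu <- base_curve * (1 + ramp * eff / 100)
    tidyr::expand_grid(tp = seq_along(days), replicate = seq_len(n_replicates)) %>%
      mutate(group = g, indicator = indicator, day = days[.data$tp],
             value = mu[.data$tp] *
               pmax(1 + rnorm(n(), 0, noise_sd), 0.01)) %>%
      select("group", "indicator", "day", "replicate", "value")
  })
}

#' Write a simulated dataset to a directory
#'
#' Writes `abundance.tsv`, `volatiles.tsv` (with sample sidecars),
#' `indicators.tsv`, `omission.tsv` and `truth.json` into `dir`.
#'
#' @param sim A `fermentation_sim`.
#' @param dir Output directory (created if absent).
#' @param omission Optional omission tibble; defaults to
#'   [simulate_omission()] under the simulation's seed.
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(sim, dir, omission = NULL) {
  stopifnot(inherits(sim, "fermentation_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance(sim$abundance, file.path(dir, "abundance.tsv"))
  write_volatiles(sim$volatiles, file.path(dir, "volatiles.tsv"))
  write_indicators(sim$indicators, file.path(dir, "indicators.tsv"))
  if (is.null(omission)) {
    omission <- simulate_omission(sim$truth, seed = sim$config$seed + 1L)
  }
  write_omission(omission, file.path(dir, "omission.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(
      core_taxa = truth$core_taxa,
      clique_memberships = truth$clique_memberships,
      producer_links = truth$producer_links,
      changepoints = truth$changepoints,
      phase_assignment = truth$phase_assignment,
      early_indicators = truth$early_indicators,
      late_indicators = truth$late_indicators,
      roles = truth$roles
    ),
    file.path(dir, "truth.json"),
    digits = NA
  )
  invisible(dir)
}

#' Read a planted-truth record written by [simulate_to_dir()]
#'
#' @param path Path to `truth.json`.
#' @return A `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      core_taxa = x$core_taxa,
      clique_memberships = x$clique_memberships,
      producer_links = as_tibble(x$producer_links),
      changepoints = x$changepoints,
      phase_assignment = as_tibble(x$phase_assignment),
      early_indicators = x$early_indicators,
      late_indicators = x$late_indicators,
      roles = as_tibble(x$roles)
    ),
    class = "synthetic_truth"
  )
}
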