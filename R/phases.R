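#' Principal component scores with a fixed orientation
#'
#' Correlation-matrix PCA (variables are z-standardized internally) with the
#' reflection ambiguity of PC1 pinned: when `days` is supplied, the sign of
#' PC1 is chosen so the earliest-day observation has a non-negative PC1
#' score. Constant variables are dropped with a warning.
#'
#' @param x Numeric matrix or data frame, observations in rows (>= 3),
#'   variables in columns (>= 2 after dropping constants).
#' @param days Optional numeric vector of observation days (length
#'   `nrow(x)`) used to orient PC1.
#' @return List with `scores` (obs x PCs), `loadings` (vars x PCs) and
#'   `var_explained` (fraction per component).
#' @export
pca_scores <- function(x, days = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 observations for PCA.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) abort("need at least 2 non-constant variables.")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- fit$x
  loadings <- fit$rotation
  if (!is.null(days)) {
    stopifnot(length(days) == nrow(scores))
    if (scores[which.min(days), 1] < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
  }
  list(
    scores = scores,
    loadings = loadings,
    var_explained = fit$sdev^2 / sum(fit$sdev^2)
  )
}

# Exact dynamic-programming segmentation of an ordered multivariate series
# into k contiguous segments minimizing total within-segment sum of squares.
# Ties are broken toward the earliest boundary. Returns 1-based indices of
# the last timepoint of each of the first k-1 segments.
segment_dp <- function(y, k) {
  y <- as.matrix(y)
  n <- nrow(y)
  cs <- apply(y, 2, cumsum)
  cs2 <- apply(y^2, 2, cumsum)
  seg_cost <- function(i, j) {
    s <- cs[j, ] - if (i > 1) cs[i - 1, ] else 0
    s2 <- cs2[j, ] - if (i > 1) cs2[i - 1, ] else 0
    sum(s2 - s^2 / (j - i + 1))
  }
  cost <- matrix(Inf, k, n)
  split_at <- matrix(NA_integer_, k, n)
  for (j in seq_len(n)) cost[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; best_i <- NA_integer_
        for (i in m:j) { # segment m runs i..j; earliest i wins ties
          cand <- cost[m - 1, i - 1] + seg_cost(i, j)
          if (cand < best - 1e-12) {
            best <- cand; best_i <- i
          }
        }
        cost[m, j] <- best
        split_at[m, j] <- best_i
      }
    }
  }
  ends <- integer(0)
  j <- n
  for (m in k:2) {
    i <- split_at[m, j]
    ends <- c(i - 1L, ends)
    j <- i - 1L
  }
  list(ends = ends, cost = cost[k, n])
}

#' Segment a fermentation time course into contiguous phases
#'
#' Projects the timepoint trajectories onto their first two principal
#' components and splits the ordered timepoints into `k` contiguous phases
#' minimizing the total within-segment sum of squared deviations in PC
#' space. The optimum is found exactly by dynamic programming over segment
#' boundaries, with ties broken toward the earliest boundary. Phase-boundary
#' days are reported as the midpoint between the last timepoint of one
#' segment and the first of the next.
#'
#' @param trajectory Data frame with a `day` column (strictly increasing) and
#'   one numeric column per variable (e.g. taxa mean relative abundances from
#'   [community_trajectory()]).
#' @param k Number of phases; must not exceed the number of timepoints.
#'   Default 4, labelled immediate_early / early / middle / late.
#' @return Object of class `phase_segmentation`: `boundaries` (interior
#'   days), `labels`, `assignment` (tibble day -> phase), and the achieved
#'   `cost`.
#' @export
#' @examples
#' sim <- simulate_fermentation(generator_config(seed = 3))
#' seg <- segment_phases(community_trajectory(sim$abundance), k = 4)
#' seg$boundaries
segment_phases <- function(trajectory, k = 4L) {
  trajectory <- as_tibble(trajectory)
  if (!"day" %in% names(trajectory)) abort("`trajectory` needs a `day` column.")
  days <- trajectory$day
  if (is.unsorted(days, strictly = TRUE)) {
    abort("timepoints must be in strictly increasing day order.")
  }
  n <- length(days)
  if (k > n) abort(sprintf("k = %d exceeds the %d timepoints.", k, n))
  vars <- as.matrix(select(trajectory, -"day"))
  pca <- pca_scores(vars, days = days)
  y <- pca$scores[, seq_len(min(2L, ncol(pca$scores))), drop = FALSE]
  dp <- segment_dp(y, k)
  labels <- if (k == 4L) {
    c("immediate_early", "early", "middle", "late")
  } else {
    sprintf("phase_%d", seq_len(k))
  }
  seg_id <- rep(seq_len(k), times = diff(c(0L, dp$ends, n)))
  boundaries <- (days[dp$ends] + days[dp$ends + 1L]) / 2
  structure(
    list(
      boundaries = boundaries,
      labels = labels,
      assignment = tibble(day = days, phase = labels[seg_id]),
      k = k,
      cost = dp$cost,
      pca = pca
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> %d phases, boundaries at day %s\n",
              x$k, paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

#' @rdname segment_phases
#' @param x A `phase_segmentation`.
#' @param ... Unused.
#' @export
tidy.phase_segmentation <- function(x, ...) x$assignment

#' Mean community trajectory over replicates
#'
#' Averages relative abundances over replicates within each day, yielding a
#' timepoint-by-taxon trajectory suitable for [segment_phases()].
#'
#' @param abundance A normalized [abundance_table()].
#' @return Tibble with `day` plus one column per taxon.
#' @export
community_trajectory <- function(abundance) {
  stopifnot(inherits(abundance, "abundance_table"))
  tidy(abundance) %>%
    group_by(.data$day, .data$taxon) %>%
    summarise(abundance = mean(.data$abundance), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "abundance") %>%
    arrange(.data$day)
}

#' Assign quality indicators to the early or late fermentation side
#'
#' Operationalizes "an indicator matters early (late)" as "the indicator
#' changes early (late)": each indicator's replicate-mean trajectory at the
#' segmentation timepoints is reduced to per-interval rates of change (first
#' differences divided by the day step), the interval-by-indicator rate
#' matrix is analysed by [pca_scores()] with PC1 oriented so the earliest
#' interval scores non-negatively, and indicators with a positive PC1 loading
#' (changing in the early-active direction) are assigned `early`, the rest
#' `late`. Indicators observed at fewer than 3 timepoints, or constant over
#' time, are excluded with a warning.
#'
#' @param indicators Long indicator tibble (`indicator`, `day`, `replicate`,
#'   `value`).
#' @param segmentation A [segment_phases()] result; assignment uses its
#'   timepoints.
#' @return Object of class `indicator_assignment`: tibble `assignment`
#'   (`indicator`, `side`, `pc1_loading`) plus `var_explained` for the first
#'   two components.
#' @export
assign_indicators <- function(indicators, segmentation) {
  indicators <- validate_indicators(indicators)
  stopifnot(inherits(segmentation, "phase_segmentation"))
  days <- segmentation$assignment$day
  traj <- indicators %>%
    filter(.data$day %in% days) %>%
    group_by(.data$indicator, .data$day) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  counts <- dplyr::count(traj, .data$indicator)
  too_few <- counts$indicator[counts$n < 3]
  if (length(too_few)) {
    warn(sprintf("excluding indicator(s) with < 3 observations: %s",
                 paste(too_few, collapse = ", ")))
    traj <- filter(traj, !.data$indicator %in% too_few)
  }
  wide <- tidyr::pivot_wider(traj, names_from = "indicator",
                             values_from = "value") %>%
    arrange(.data$day)
  m <- as.matrix(select(wide, -"day"))
  rates <- apply(m, 2, diff) / diff(wide$day)
  interval_start <- utils::head(wide$day, -1)
  pca <- pca_scores(rates, days = interval_start)
  assignment <- tibble(
    indicator = rownames(pca$loadings),
    side = unname(ifelse(pca$loadings[, 1] >= 0, "early", "late")),
    pc1_loading = unname(pca$loadings[, 1])
  )
  structure(
    list(
      assignment = assignment,
      var_explained = pca$var_explained[seq_len(min(2, length(pca$var_explained)))]
    ),
    class = "indicator_assignment"
  )
}

#' @export
print.indicator_assignment <- function(x, ...) {
  cat("<indicator_assignment>\n")
  cat(sprintf("  early: %s\n",
              paste(x$assignment$indicator[x$assignment$side == "early"],
                    collapse = ", ")))
  cat(sprintf("  late:  %s\n",
              paste(x$assignment$indicator[x$assignment$side == "late"],
                    collapse = ", ")))
  invisible(x)
}

#' @rdname assign_indicators
#' @param x An `indicator_assignment`.
#' @param ... Unused.
#' @export
tidy.indicator_assignment <- function(x, ...) x$assignment

# Per-timepoint class-mean z-scored trajectories: the seven volatile classes
# from the volatile table, plus amino_acids and organic_acids built from the
# indicator series.
metabolite_class_trajectories <- function(volatiles, indicators, days) {
  zscore <- function(v) if (sd(v) == 0) rep(NA_real_, length(v)) else (v - mean(v)) / sd(v)
  vol_means <- tidy(volatiles) %>%
    filter(.data$day %in% days) %>%
    group_by(.data$compound, .data$class, .data$day) %>%
    summarise(value = mean(.data$concentration), .groups = "drop") %>%
    group_by(.data$compound) %>%
    arrange(.data$day, .by_group = TRUE) %>%
    mutate(z = zscore(.data$value)) %>%
    ungroup()
  vol_class <- vol_means %>%
    group_by(.data$class, .data$day) %>%
    summarise(z = mean(.data$z, na.rm = TRUE), .groups = "drop")
  ind_members <- list(
    amino_acids = c("glutamic_acid", "umami_aa", "amino_nitrogen"),
    organic_acids = c("lactic_acid")
  )
  ind_means <- indicators %>%
    filter(.data$day %in% days) %>%
    group_by(.data$indicator, .data$day) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ind_class <- purrr::imap_dfr(ind_members, function(members, cls) {
    d <- ind_means %>%
      filter(.data$indicator %in% members) %>%
      group_by(.data$indicator) %>%
      arrange(.data$day, .by_group = TRUE) %>%
      mutate(z = zscore(.data$value)) %>%
      ungroup()
    if (nrow(d) == 0) return(NULL)
    d %>% group_by(.data$day) %>%
      summarise(z = mean(.data$z, na.rm = TRUE), .groups = "drop") %>%
      mutate(class = cls)
  })
  bind_rows(vol_class, select(ind_class, "class", "day", "z"))
}

#' Map core taxa to their active fermentation phases
#'
#' For every core taxon and metabolite class (the seven volatile classes plus
#' amino acids and organic acids derived from the indicator series), computes
#' the Spearman correlation between the taxon's mean relative-abundance
#' trajectory and the class-mean z-scored concentration trajectory across the
#' segmentation timepoints, with Benjamini-Hochberg correction over this
#' taxon-class family. A taxon is mapped to each phase in which one of its
#' significantly, positively associated classes shows its maximum mean
#' absolute rate of change.
#'
#' @param abundance A normalized [abundance_table()] containing all `core`
#'   taxa.
#' @param volatiles A [volatile_table()].
#' @param indicators Long indicator tibble.
#' @param core Character vector of core taxa.
#' @param segmentation A [segment_phases()] result.
#' @param config An [analysis_config()]; `flavor_q_threshold` gates the
#'   class associations.
#' @return Object of class `phase_correspondence`: `mapping` (tibble `taxon`,
#'   `phase`, sorted in phase order) and `associations` (per taxon-class
#'   rho/p/q and the class's most active phase).
#' @export
taxa_phase_correspondence <- function(abundance, volatiles, indicators, core,
                                      segmentation,
                                      config = analysis_config()) {
  stopifnot(inherits(segmentation, "phase_segmentation"))
  if (length(core) == 0) {
    return(structure(list(mapping = tibble(taxon = character(),
                                           phase = character()),
                          associations = tibble()),
                     class = "phase_correspondence"))
  }
  missing_taxa <- setdiff(core, rownames(abundance$values))
  if (length(missing_taxa)) {
    abort(sprintf("core taxa absent from abundance table: %s",
                  paste(missing_taxa, collapse = ", ")))
  }
  days <- segmentation$assignment$day
  phases <- segmentation$assignment$phase
  taxa_traj <- community_trajectory(abundance) %>%
    filter(.data$day %in% days)
  class_traj <- metabolite_class_trajectories(volatiles, indicators, days) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "z") %>%
    arrange(.data$day)
  classes <- setdiff(names(class_traj), "day")

  # most active phase per class: max mean |first difference| per unit day,
  # intervals attributed to the phase of their left endpoint; earliest phase
  # wins ties
  interval_phase <- phases[-length(phases)]
  active_phase <- vapply(classes, function(cl) {
    rate <- abs(diff(class_traj[[cl]]) / diff(class_traj$day))
    by_phase <- tapply(rate, factor(interval_phase, levels = unique(phases)),
                       mean)
    names(by_phase)[which.max(by_phase)]
  }, character(1))

  assoc <- tidyr::expand_grid(taxon = core, class = classes) %>%
    mutate(purrr::map2_dfr(.data$taxon, .data$class, function(tx, cl) {
      spearman(taxa_traj[[tx]], class_traj[[cl]])[, c("rho", "p")]
    }))
  assoc$q <- bh_fdr(assoc$p)
  assoc$active_phase <- active_phase[assoc$class]
  assoc$significant <- !is.na(assoc$q) & assoc$q < config$flavor_q_threshold &
    assoc$rho > 0
  mapping <- assoc %>%
    filter(.data$significant) %>%
    distinct(.data$taxon, phase = .data$active_phase) %>%
    mutate(phase = factor(.data$phase, levels = segmentation$labels)) %>%
    arrange(.data$phase, .data$taxon) %>%
    mutate(phase = as.character(.data$phase))
  structure(list(mapping = mapping, associations = assoc),
            class = "phase_correspondence")
}

#' @export
print.phase_correspondence <- function(x, ...) {
  cat(sprintf("<phase_correspondence> %d taxon-phase mappings\n",
              nrow(x$mapping)))
  if (nrow(x$mapping)) print(x$mapping, n = 20)
  invisible(x)
}

#' @rdname taxa_phase_correspondence
#' @param x A `phase_correspondence`.
#' @param ... Unused.
#' @export
tidy.phase_correspondence <- function(x, ...) x$mapping
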