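#' Analysis configuration
#'
#' Bundles every threshold used by the core-identification pipeline. Defaults
#' encode the screening rules commonly applied to fermentation communities:
#' dominance requires mean relative abundance above 1% in at least 80% of
#' samples; co-occurrence edges require |rho| > 0.6 at BH q < 0.05 (a stricter
#' |rho| > 0.8, p < 0.01 set is kept for display networks); hub taxa need
#' strictly more than 9 network links; flavor-associated taxa need significant
#' correlation (|rho| > 0.5, p < 0.05, q < 0.05) with at least five volatile
#' compounds.
#'
#' @param dominance_abundance_threshold Mean relative abundance a taxon must
#'   exceed (strictly) to pass the dominance criterion. Proportion, default 0.01.
#' @param dominance_prevalence_threshold Minimum fraction of samples in which
#'   the taxon must be present. Default 0.8.
#' @param presence_epsilon Relative abundance strictly above which a taxon
#'   counts as present in a sample. Default 0 (any non-zero abundance).
#' @param edge_r_threshold,edge_q_threshold Analysis-network edge thresholds:
#'   |rho| strictly above `edge_r_threshold` (default 0.6) and BH q below
#'   `edge_q_threshold` (default 0.05).
#' @param display_r_threshold,display_p_threshold Display-network edge
#'   thresholds: |rho| > 0.8 and raw p < 0.01 by default.
#' @param hub_degree_threshold Degree a node must strictly exceed to count as
#'   a hub. Non-negative integer, default 9.
#' @param flavor_r_threshold,flavor_p_threshold,flavor_q_threshold Taxon-volatile
#'   association thresholds (default |rho| > 0.5, p < 0.05, q < 0.05).
#' @param flavor_min_volatiles Minimum number of passing volatile compounds for
#'   a taxon to count as flavor-associated. Default 5.
#' @param n_phases Number of fermentation phases for segmentation. Default 4.
#' @param omission_alpha Significance level for omission-experiment post hoc
#'   tests. Default 0.05.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$hub_degree_threshold
analysis_config <- function(dominance_abundance_threshold = 0.01,
                            dominance_prevalence_threshold = 0.8,
                            presence_epsilon = 0,
                            edge_r_threshold = 0.6,
                            edge_q_threshold = 0.05,
                            display_r_threshold = 0.8,
                            display_p_threshold = 0.01,
                            hub_degree_threshold = 9L,
                            flavor_r_threshold = 0.5,
                            flavor_p_threshold = 0.05,
                            flavor_q_threshold = 0.05,
                            flavor_min_volatiles = 5L,
                            n_phases = 4L,
                            omission_alpha = 0.05,
                            rng_seed = NULL) {
  stop_unless_proportion <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                    name, paste(format(x), collapse = ", ")))
    }
  }
  stop_unless_proportion(dominance_abundance_threshold, "dominance_abundance_threshold")
  stop_unless_proportion(dominance_prevalence_threshold, "dominance_prevalence_threshold")
  stop_unless_proportion(presence_epsilon, "presence_epsilon")
  stop_unless_proportion(edge_q_threshold, "edge_q_threshold")
  stop_unless_proportion(display_p_threshold, "display_p_threshold")
  stop_unless_proportion(flavor_p_threshold, "flavor_p_threshold")
  stop_unless_proportion(flavor_q_threshold, "flavor_q_threshold")
  stop_unless_proportion(omission_alpha, "omission_alpha")
  for (nm in c("edge_r_threshold", "display_r_threshold", "flavor_r_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a correlation magnitude in [0, 1].", nm))
    }
  }
  if (!is.numeric(hub_degree_threshold) || length(hub_degree_threshold) != 1L ||
      hub_degree_threshold < 0 || hub_degree_threshold != floor(hub_degree_threshold)) {
    abort("`hub_degree_threshold` must be a non-negative integer.")
  }
  if (!is.numeric(flavor_min_volatiles) || flavor_min_volatiles < 1) {
    abort("`flavor_min_volatiles` must be a positive integer.")
  }
  if (!is.numeric(n_phases) || n_phases < 1) {
    abort("`n_phases` must be a positive integer.")
  }
  structure(
    list(
      dominance_abundance_threshold = dominance_abundance_threshold,
      dominance_prevalence_threshold = dominance_prevalence_threshold,
      presence_epsilon = presence_epsilon,
      edge_r_threshold = edge_r_threshold,
      edge_q_threshold = edge_q_threshold,
      display_r_threshold = display_r_threshold,
      display_p_threshold = display_p_threshold,
      hub_degree_threshold = as.integer(hub_degree_threshold),
      flavor_r_threshold = flavor_r_threshold,
      flavor_p_threshold = flavor_p_threshold,
      flavor_q_threshold = flavor_q_threshold,
      flavor_min_volatiles = as.integer(flavor_min_volatiles),
      n_phases = as.integer(n_phases),
      omission_alpha = omission_alpha,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  dominance: mean RA > %g, prevalence >= %g (presence > %g)\n",
              x$dominance_abundance_threshold, x$dominance_prevalence_threshold,
              x$presence_epsilon))
  cat(sprintf("  edges:     |rho| > %g, q < %g (display |rho| > %g, p < %g)\n",
              x$edge_r_threshold, x$edge_q_threshold,
              x$display_r_threshold, x$display_p_threshold))
  cat(sprintf("  hubs:      degree > %d\n", x$hub_degree_threshold))
  cat(sprintf("  flavor:    |rho| > %g, p < %g, q < %g, >= %d volatiles\n",
              x$flavor_r_threshold, x$flavor_p_threshold, x$flavor_q_threshold,
              x$flavor_min_volatiles))
  cat(sprintf("  phases: %d   omission alpha: %g\n", x$n_phases, x$omission_alpha))
  invisible(x)
}

#' Synthetic fermentation generator configuration
#'
#' Parameters of the planted-truth fermentation simulator. Defaults describe a
#' 40-day brine (moromi) fermentation sampled at 9 timepoints with 3 replicate
#' batches, a community of 55 bacterial and 28 fungal taxa, 128 volatile
#' compounds in seven chemical classes, and 9 planted core members organised
#' into three succession guilds (early LAB + koji mold, late LAB, late yeast).
#'
#' @param n_bacterial_taxa,n_fungal_taxa Roster sizes. Defaults 55 and 28.
#' @param n_timepoints Number of sampling days, spread evenly over
#'   `total_days`. Default 9.
#' @param total_days Fermentation length in days. Default 40.
#' @param n_replicates Replicate batches per timepoint. Default 3.
#' @param n_volatiles Number of volatile compounds. Default 128.
#' @param n_core Number of planted core taxa. Default 9.
#' @param clique_size Size of each planted correlation guild (core members
#'   plus low-abundance fillers sharing the guild latent signal). Default 12.
#' @param noise_sd Log-scale standard deviation of replicate noise applied to
#'   latent abundances and (scaled) to volatiles/indicators. Default 0.3.
#' @param producer_effect Slope linking a producer taxon's relative abundance
#'   to its volatile's concentration (micrograms/L per unit RA). Default 400.
#' @param n_producer_links Planted volatile links per core taxon. Default 6.
#' @param seed Integer RNG seed; the generator is bit-reproducible given it.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_bacterial_taxa = 55L,
                             n_fungal_taxa = 28L,
                             n_timepoints = 9L,
                             total_days = 40,
                             n_replicates = 3L,
                             n_volatiles = 128L,
                             n_core = 9L,
                             clique_size = 12L,
                             noise_sd = 0.3,
                             producer_effect = 400,
                             n_producer_links = 6L,
                             seed = 1L) {
  n_taxa <- n_bacterial_taxa + n_fungal_taxa
  if (n_core > n_taxa) abort("`n_core` cannot exceed the total number of taxa.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (n_timepoints < 2) abort("need at least 2 timepoints.")
  if (n_replicates < 1) abort("need at least 1 replicate.")
  if (clique_size > n_taxa) abort("`clique_size` cannot exceed the roster size.")
  structure(
    list(
      n_bacterial_taxa = as.integer(n_bacterial_taxa),
      n_fungal_taxa = as.integer(n_fungal_taxa),
      n_timepoints = as.integer(n_timepoints),
      total_days = total_days,
      n_replicates = as.integer(n_replicates),
      n_volatiles = as.integer(n_volatiles),
      n_core = as.integer(n_core),
      clique_size = as.integer(clique_size),
      noise_sd = noise_sd,
      producer_effect = producer_effect,
      n_producer_links = as.integer(n_producer_links),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d bacterial + %d fungal taxa, %d planted core, cliques of %d\n",
              x$n_bacterial_taxa, x$n_fungal_taxa, x$n_core, x$clique_size))
  cat(sprintf("  %d timepoints over %g days x %d replicates; %d volatiles\n",
              x$n_timepoints, x$total_days, x$n_replicates, x$n_volatiles))
  cat(sprintf("  noise_sd %g (log scale), producer effect %g, seed %d\n",
              x$noise_sd, x$producer_effect, x$seed))
  invisible(x)
}
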