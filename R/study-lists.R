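#' Worked-example screening outcome from a moromi fermentation survey
#'
#' `moromi_candidate_lists()` returns the three criterion lists produced by
#' screening a traditional 40-day soy sauce moromi fermentation (the survey
#' whose design the synthetic generator emulates): seventeen high-abundance
#' species, sixteen network hub species and fifteen flavor-associated
#' species. Their strict intersection is the nine-species candidate core.
#'
#' `moromi_omission_outcomes()` returns the matching leave-one-out
#' fermentation outcomes for the two quality indicators (umami amino acids
#' and 4-ethylguaiacol): percent decreases relative to the intact consortium
#' where reported, and per-taxon significance flags. The koji mold
#' (*Aspergillus oryzae*) has no omission group — koji cannot be made without
#' it — so it carries no rows and passes pruning by default. Feeding these
#' outcomes to [prune_core()] reduces the nine candidates to the seven-species
#' final core.
#'
#' @return `moromi_candidate_lists()`: a list with character vectors
#'   `high_abundance`, `hub` and `flavor`. `moromi_omission_outcomes()`: a
#'   tibble with columns `taxon`, `indicator`, `percent_change` (NA where the
#'   survey reported only direction/significance) and `significant`.
#' @export
#' @examples
#' lists <- moromi_candidate_lists()
#' cand <- candidate_core(lists$high_abundance, lists$hub, lists$flavor)
#' prune_core(cand, moromi_omission_outcomes())
moromi_candidate_lists <- function() {
  list(
    high_abundance = c(
      "Weissella_paramesenteroides", "Lactiplantibacillus_plantarum",
      "Lactococcus_lactis", "Tetragenococcus_halophilus",
      "Pediococcus_pentosaceus", "Pediococcus_acidilactici",
      "Staphylococcus_epidermidis", "Staphylococcus_gallinarum",
      "Bacillus_velezensis", "Weissella_cibaria",
      "Enterobacter_hormaechei", "Enterobacter_kobei",
      "Zygosaccharomyces_rouxii", "Candida_orthopsilosis",
      "Millerozyma_farinosa", "Aspergillus_oryzae",
      "Pichia_membranifaciens"
    ),
    hub = c(
      "Weissella_paramesenteroides", "Lactiplantibacillus_plantarum",
      "Lactobacillus_fermentum", "Lactococcus_lactis",
      "Tetragenococcus_halophilus", "Pediococcus_pentosaceus",
      "Pediococcus_acidilactici", "Staphylococcus_epidermidis",
      "Weissella_cibaria",
      "Zygosaccharomyces_rouxii", "Pichia_membranifaciens",
      "Candida_orthopsilosis", "Meyerozyma_guilliermondii",
      "Aspergillus_oryzae", "Millerozyma_farinosa",
      "Candida_psychrophila"
    ),
    flavor = c(
      "Weissella_paramesenteroides", "Lactiplantibacillus_plantarum",
      "Lactobacillus_fermentum", "Saccharopolyspora_thermophila",
      "Tetragenococcus_halophilus", "Pediococcus_pentosaceus",
      "Pediococcus_acidilactici", "Staphylococcus_epidermidis",
      "Bacillus_velezensis",
      "Zygosaccharomyces_rouxii", "Pichia_fermentans",
      "Candida_orthopsilosis", "Meyerozyma_guilliermondii",
      "Aspergillus_oryzae", "Candida_guilliermondii"
    )
  )
}

#' @rdname moromi_candidate_lists
#' @export
moromi_omission_outcomes <- function() {
  tibble(
    taxon = c(
      # umami amino acids
      "Weissella_paramesenteroides", "Pediococcus_pentosaceus",
      "Tetragenococcus_halophilus", "Lactiplantibacillus_plantarum",
      "Pediococcus_acidilactici", "Staphylococcus_epidermidis",
      "Zygosaccharomyces_rouxii", "Candida_orthopsilosis",
      # 4-ethylguaiacol
      "Weissella_paramesenteroides", "Pediococcus_pentosaceus",
      "Tetragenococcus_halophilus", "Lactiplantibacillus_plantarum",
      "Pediococcus_acidilactici", "Staphylococcus_epidermidis",
      "Zygosaccharomyces_rouxii", "Candida_orthopsilosis"
    ),
    indicator = rep(c("umami_aa", "x4eg"), each = 8L),
    percent_change = c(
      27.2, 15.8, 25.9, 15.5, NA, NA, NA, NA,
      NA, NA, NA, 42.8, NA, NA, 45.6, 56.5
    ),
    significant = c(
      TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
      TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE
    )
  )
}
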