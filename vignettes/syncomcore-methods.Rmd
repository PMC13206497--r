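---
title: "Methods: core-microbe selection, phase analysis and SynCom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-microbe selection, phase analysis and SynCom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomcore)
```

## The selection model

`syncomcore` identifies the core members of a fermentation community by
requiring three independent lines of evidence, then validating the survivors
functionally. The underlying assumptions are worth stating plainly, because
each criterion fails in a different way on its own:

* **Dominance** (mean relative abundance > 1%, prevalence ≥ 80% of samples)
  finds taxa that are quantitatively capable of shaping the chemistry, but
  is blind to function — a salt-tolerant bystander can dominate without
  contributing.
* **Network hubness** (degree > 9 in the Spearman co-occurrence network with
  |ρ| > 0.6 and BH q < 0.05 edges) finds taxa embedded in the successional
  structure, but correlation cliques also form among passengers that merely
  share a growth window.
* **Flavor association** (|ρ| > 0.5, p < 0.05, q < 0.05 against at least
  five volatile compounds) ties a taxon to the product, but a correlate of a
  true producer inherits its associations.

The candidate core is the *strict intersection* of the three sets: a taxon
must be abundant, structurally embedded, and chemically implicated. The
intersection rule is deliberate — it is the only combination rule that
reproduces the worked example's nine-species candidate set from its three
printed lists (`moromi_candidate_lists()`), and each criterion vetoes a
distinct class of false positives.

Because all three criteria are correlational, the final step is
interventional: leave-one-out (omission) fermentations. Per indicator
(umami amino acids in g/L, 4-ethylguaiacol in µg/L) we run a one-way ANOVA
across all groups followed by Tukey's HSD against the intact-consortium
control at α = 0.05, and report the percent change
(control − omitted)/control × 100. A candidate is dropped only when it is
significant for *neither* indicator; requiring both would discard genuinely
specialised strains (an acidifier need not make phenols). Taxa without
omission data pass by default with a message — the koji mould is the
motivating case, since koji cannot be prepared without it. Welch t-tests
with BH correction are available (`method = "welch"`) for heteroscedastic
designs.

## Statistical primitives

**Spearman correlation.** ρ is the Pearson correlation of midranks (ties get
average ranks). The two-sided p-value is exact for n ≤ 9 — the proportion of
all n! permutations of one vector whose |ρ| reaches the observed value
(with a 10⁻¹² tolerance against floating-point ties) — and uses the t
approximation with n − 2 degrees of freedom for larger n. The cutoff at
n = 9 keeps the largest enumerated permutation matrix at 9! rows
(memoised per session, ~13 MB) while covering the per-timepoint analyses,
which have at most 9 observations; the per-sample network analyses
(n = 27 under the default design) take the t path. Constant vectors give an
undefined result that is excluded from networks with a warning rather than
an error, so a single absent taxon cannot abort a run.

**Multiple testing.** Benjamini–Hochberg q-values are computed per test
*family*: all taxon pairs form one family, all taxon × volatile pairs a
second, the taxon × metabolite-class tests a third. Mixing families would
let the thousands of taxon-pair tests dilute the smaller families.
`bh_fdr()` delegates to `stats::p.adjust(method = "BH")` and is verified in
the tests against a hand-evaluated step-up oracle.

**Compositionality.** Relative abundances are used as-is, matching standard
practice for these surveys; no CLR/SparCC correction is applied. The closure
operation does induce artefactual correlations (see the generator notes
below), which is one reason hubness alone is never trusted.

## Phase segmentation

Practitioners usually divide a fermentation into phases by eye from a PCA
plot. The package replaces that judgement with a reproducible procedure —
the single largest methodological choice in the package, so it is spelled
out:

1. Average replicates to a timepoint × taxon trajectory
   (`community_trajectory()`), z-standardise, and project onto the first two
   principal components.
2. Split the ordered timepoints into k contiguous segments (default k = 4,
   labelled immediate early / early / middle / late) minimising the total
   within-segment sum of squared deviations in PC space. The optimum is
   found *exactly* by dynamic programming over segment boundaries
   (O(T²k) with prefix sums); ties break toward the earliest boundary so
   results are deterministic.
3. Report each boundary as the midpoint between the last timepoint of one
   segment and the first of the next — with 5-day sampling, a boundary
   between days 5 and 10 is reported as day 7.5.

The DP is property-tested against brute-force enumeration of all contiguous
splits for up to 12 timepoints, and uniform rescaling of the input variables
cannot change the answer because the PCA is correlation-based.

## Early versus late indicators

Assigning quality indicators to the early or late fermentation side is
operationalised on **rates of change, not levels**. The reasoning: almost
every useful indicator accumulates monotonically (glutamate and
4-ethylguaiacol both only rise), so on raw levels they all load with the
same sign on the time axis and cannot be separated. What distinguishes an
early indicator is *when it moves*: glutamate accrues in the first two
weeks and flattens, 4-EG is flat until yeast activity begins and then
climbs. `assign_indicators()` therefore takes first differences of each
indicator's mean trajectory per unit day, z-standardises, and runs PCA over
the interval × indicator matrix with PC1 oriented so the earliest interval
scores non-negatively; a positive PC1 loading means "changes in the
early-active direction" → early, negative → late. The rule is
sign-sensitive by construction (a mirrored pair of trajectories gets
opposite sides): pH, which *falls* early, lands on the late side, which is
why pH is conventionally read through lactic acid instead. Indicators with
fewer than three observations, or constant over time, are excluded with a
warning — a flat trajectory has no defined side.

## Taxa-to-phase correspondence

`taxa_phase_correspondence()` links each core taxon to the phases it likely
drives. Metabolite classes are the seven volatile classes plus two derived
from the indicator series: amino acids (glutamate, umami amino acids, amino
nitrogen) and organic acids (lactic acid). Each class trajectory is the mean
of its members' per-timepoint z-scores; each taxon trajectory is its mean
relative abundance. Associations are Spearman correlations across
timepoints (exact p at n ≤ 9), BH-corrected within this family, and only
*positive* significant correlations count — a taxon that declines while a
class accumulates is not producing it. A significantly associated class
votes for the phase in which its mean absolute rate of change peaks
(intervals attributed to the phase of their left endpoint; earliest phase
wins ties).

## SynCom schedule grammar

Schedules are written `"W→L→P+T→Z+C"`: arrow groups map onto successive
inoculation days (default slots 0, 5, 10 and 25 — the yeasts are added on
day 25 when the pH has dropped enough for them), `+` joins simultaneous
strains. Default doses are 1.0 × 10⁸ CFU/g for bacteria and 1.0 × 10⁷ CFU/g
for yeasts. Parsing preserves the written within-slot order so every
shorthand round-trips byte-for-byte, but *identity* is set-based: the
canonical form sorts codes within a slot, which is what
`enumerate_schedules()` deduplicates on. The published seven-row design this
grammar encodes contains two rows that differ only in within-slot order —
as sets they are the same schedule, and both map onto the same member of
the 12-schedule constraint-valid space (single LAB starter W or L on day 0,
the remaining three LAB split non-emptily over days 5 and 10, yeasts fixed
on day 25). No fermentation-outcome simulator is implied: schedule
comparison (`compare_groups()`) consumes measured or simulated indicator
series and applies a two-way ANOVA (group × day) with per-day Tukey
contrasts against control.

## The synthetic generator and its planted truth

`simulate_fermentation()` is a first-class module, not a test fixture: it
generates datasets in which the right answer is *planted and recorded*, so
recovery can be scored. Its defaults describe the study design the package
targets: 9 sampling days over a 40-day run × 3 replicate batches, 55
bacterial + 28 fungal taxa, 128 volatiles split over the seven classes in
the proportions 16:6:10:21:26:47:9, and 9 planted core members.

* **Succession guilds.** Three guilds — early LAB + koji mould, late
  (salt-tolerant) LAB, late yeast — follow plateau signals built from
  logistic transitions (width ≈ 1 day) at the planted changepoints, which
  sit at days 7.5, 17.5 and 27.5: the midpoints between sampled days
  bracketing the narrative phase limits (0–5, 5–15, 15–25, 25–40 d), i.e.
  exactly what the segmentation's midpoint convention can recover.
* **Cliques.** Each guild is a planted correlation clique of 12 taxa (core
  members plus low-abundance fillers) sharing the guild latent signal with
  taxon-specific loadings in U(0.8, 1.2), guaranteeing within-clique degree
  11 > 9.
* **Producer links.** Each core taxon drives 6 volatiles (classes matched to
  guild chemistry: early → acids/aldehydes/ketones, late LAB →
  acids/esters/pyrazines, yeast → alcohols/phenols/esters) through the
  linear model concentration = baseline + effect × relative abundance, with
  baseline U(5, 30) µg/L and effect ≈ 400 µg/L per unit RA, so the
  association sign is unambiguous.
* **Noise.** Replicates share each taxon's latent trajectory and differ only
  by multiplicative log-normal noise (σ = 0.3 on the log scale by default —
  typical replicate scatter for amplicon surveys; strictly positive and
  heavy-tailed), applied *before* compositional closure. σ = 0 gives
  bit-identical replicates; every sample always closes to 1 within 10⁻⁹.
* **Decoys.** Intersection selection is kept non-trivial by taxa passing
  one or two criteria only: four dominant-only decoys holding a constant
  ~2–4% *share* of the community (dominance is defined on relative
  abundance, and a taxon flat in latent units would inherit a spurious
  trend from closure — pinning the share is what makes "flat" mean flat);
  clique fillers (hubs, often flavor-associated, never abundant); two
  flavor-only decoys and one four-link boundary decoy with oscillating,
  trend-free trajectories driving their own volatiles.
* **Indicators.** Glutamate rises and flattens after mid-fermentation;
  lactic acid rises in three waves (0–5, 5–10, 10–20 d); reducing sugars
  hump near 21 g/L around day 10 and then decline; pH falls from 6.2 to
  ~4.8; 4-EG stays near zero until the last changepoint and then climbs;
  total nitrogen is nearly flat on purpose — a decoy indicator whose
  early/late side is legitimately noise-dominated, which is why the truth
  record lists sides only for the seven informative indicators.
* **Omission.** `simulate_omission()` draws control and per-taxon omission
  groups with planted percent decreases (defaults anchored on effect sizes
  of 15–60% typical of leave-one-out fermentations) and Gaussian noise
  scaled to the control mean. Under the defaults every planted core member
  is functionally active, so full-pipeline recovery is scored against all
  nine.

What the generator does **not** emulate: sequencing depth and count noise
(data are closed intensities, not reads), taxonomic misassignment, absolute
biomass dynamics, chemical interconversion among volatiles, salt/temperature
kinetics, and any spatial heterogeneity. Passing the planted-recovery tests
therefore demonstrates that the pipeline's logic is sound under its own
assumptions — not that those assumptions hold for a particular real
dataset.

## Numerical choices and degenerate inputs

* Exact-permutation cutoff n ≤ 9; midranks everywhere; permutation p-values
  compare |ρ| with a 10⁻¹² slack.
* DP ties break toward the earliest boundary; class-activity ties toward the
  earliest phase; PC1 reflection pinned by the earliest observation.
* Constant taxa/indicators are excluded with warnings; an all-zero sample
  is a hard error in `normalize_relative()` (it has no composition); pH is
  validated to (0, 14); negative abundances and unmatched sample ids are
  hard errors naming the offender.
* Tables are TSV with a `_samples.tsv` metadata sidecar, written with 12
  significant digits, which round-trips decimal text exactly.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to make the
Monte-Carlo estimates stable while keeping a full run interactive on one
CPU: 25 seeds for planted-recovery rates (10 in the acceptance script), 50
seeds for null calibration in the tests (20 in the script), 100 seeds for
omission power (50 in the script), 200 random instances for the
segmentation brute-force equivalence, and 100 random pairs for the exact
Spearman oracle. The worked example is deterministic and instantaneous.

## Limitations

Correlation-guided screening misses rare-but-active taxa by construction;
the omission analysis conflates biomass loss with function loss (the
package reports percent changes and significance, and makes no causal
claim); and the segmentation assumes phases are contiguous in time, which
is the point of the method but would mask a community that revisits an
earlier state.
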