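---
title: "Methods: abundance-weighted isotopic niches and community decline in canopy ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance-weighted isotopic niches and community decline in canopy ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antniche)
```

## The analysis in one paragraph

`antniche` takes a plot-based canopy-fogging survey of an ant assemblage —
worker counts per plot and species, specimen-level bulk stable isotopes, and
per-plot pooled-leaf baselines — and produces (i) leaf-calibrated,
abundance-weighted univariate isotopic niche metrics per plot, (ii) per-plot
community metrics (density, richness, inverse-occupancy rarity) with
land-use-level species-pool estimates, dominance and rarefaction curves and a
nestedness partition, and (iii) fixed-effects land-use contrasts per
response with AICc simplification. A synthetic-data generator reproduces the
hierarchical design so every stage is testable, including recovery of known
simulated effects.

## Model and assumptions

**Calibration.** Δ¹³C and Δ¹⁵N are specimen values minus the plot's pooled
leaf values. This is an affine, per-plot shift: plot Ranges are invariant to
the baseline, locations move one-to-one with it (a property the test suite
asserts). The calibration assumes the pooled head-height leaves represent
the basal resource of each plot's food web; where understory leaves are
¹³C-depleted relative to the upper canopy (the "canopy effect"), Δ¹³C
contrasts between open and closed-canopy systems partially confound diet
with leaf-sampling height. The package makes the calibration explicit and
reversible (raw δ values stay in the dataset) but cannot remove that
confound.

**Weighting.** The Average is the relative-abundance-weighted mean of
species-per-plot means. Weights are renormalised over the functional-
community species that actually carry isotope data: unmeasured species
cannot contribute isotope values, and renormalisation preserves the
invariant that weights sum to 1 per plot (asserted at 1e-12). The
alternative — weighting over all functional species — would shrink every
plot mean toward zero by the unmeasured share and was rejected.

**Extremes.** "Abundance-weighted metrics" admits two readings for
Maximum/Minimum. The default takes extremes over the (unweighted) species
means: abundance decides *membership* (via the functional community) and the
Average, but a species' isotopic position is not rescaled by how common it
is. The literal alternative — extremes of the products $w_i x_i$ — is
dimensionally awkward for calibrated values that can be negative, but is
preserved behind `plot_isotope_metrics(..., extremes = "weighted")` so both
readings remain available.

**Statistics.** Gaussian identity models are ordinary least squares with the
land-use term tested by the classical F (a balanced one-factor design on 28
plots gives F on 3 and 24 df; on 32 plots, 3 and 28). Abundance uses a
negative binomial with log link (`MASS::glm.nb`), tested by the
likelihood-ratio χ² against the nested null with the dispersion re-estimated
in both models; the reported χ² is an LR statistic (a Wald test would be the
other convention; the choice is flagged here). The Δ¹⁵N Range uses a
Gaussian log link because it is positive and right-skewed — which is why
single-species plots (Range 0) must be excluded from that response, see
below. Model simplification minimises
$AICc = AIC + 2k(k+1)/(n-k-1)$ over the ladder interaction → additive →
land-use-only, ties resolved toward fewer parameters, candidates with
$n \le k+1$ excluded. No multiple-testing correction is applied by default,
matching standard single-response reporting; `p.adjust` can be applied to
the output table by users who want it.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` (functional community) | 0.90 | fraction | species cumulating to ≥ 90 % of plot abundance, most abundant first; the species crossing the threshold is included |
| `effective_area_m2` | 12 | m² per plot | the design deploys 24 trap-m² (3 subplots × 8 traps), but funnel traps intercept only part of the knockdown; 12 m² is the normalisation under which published densities for this design are reproduced (6819 workers over 8 plots → 71.0 /m²). Both normalisations are supported; the constant lives in plot metadata and the manifest |
| `min_species` | 1 | count | a single measured species still defines Average/Max/Min |
| `min_species_range` | 2 | count | a one-species plot has no meaningful Range, and a log-link Range model cannot accept 0; "insufficient data" exclusions are not defined more precisely anywhere, so both minima are explicit, configurable and logged per plot |
| `extremes` | `"unweighted"` | — | see above |
| `bias_corrected` (Chao2) | `TRUE` | — | remains defined at q₂ = 0; classic form available and matches `vegan::specpool()` exactly |

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 4 land uses × 2
clusters × 4 plots (32 plots), 3 subplots × 8 one-m² traps, a 14-species
pool with occupancy 13/10/4/4 along F ⊇ J ⊇ R ⊇ O, and isotope offsets
drawn per species (Δ¹³C ~ N(4, 1.5²) ‰, Δ¹⁵N ~ N(2.5, 1²) ‰ — about one
trophic level above leaves), with a monoculture δ¹³C shift (R −2 ‰,
O −1.5 ‰) and range compression (R, O: 0.5).

Counts are Poisson at trap level around log-normal per-trap species means
(μ = 0.1, σ = 1.5 on the log scale — strong dominance), a mean-1 gamma plot
multiplier shared across species (shape 1.2, so plot totals are
gamma–Poisson, i.e. negative binomial; the shape reproduces a plot-level
density CV near 0.9), land-use thinning factors (F 1, J 0.87, R 0.145,
O 0.21, set from the per-species thinning implied by published land-use
totals and richness), and a colony-presence Bernoulli per plot × species
with $p = 1 - e^{-0.3\lambda}$. The presence term matters: without it every
species occupies every plot, which flattens rarity, empties the Chao
uniques/duplicates counts and makes per-plot richness implausibly high.
With it, simulated rainforest plots average ≈ 4.8 species and ≈ 70
workers/m², and incidence has genuine q₁/q₂ structure.

Not emulated: spatial autocorrelation between plots, within-plot microhabitat
structure, morphospecies, observation error in identification, and any
dependence of isotope offsets on abundance. Passing tests on simulated data
therefore demonstrate the correctness of the computations and the
recoverability of effects under this model — not that real communities
satisfy the model. In particular, the compression parameter scales species
offsets around zero (so strong compression also pulls locations toward the
baseline); the simulation truth object carries everything needed to form
closed-form expectations either way.

Randomness is split into named per-stage substreams derived from one master
seed, so adding a stage does not perturb earlier draws, and identical
configurations are bitwise-reproducible.

## Numerical choices and degenerate inputs

- Functional-community ranking breaks count ties by species id (ascending)
  so output is deterministic.
- Threshold comparison is `>=`, so a prefix hitting exactly 90 % stops there;
  an all-zero plot yields an empty community.
- Plots with no measured species are excluded from isotope metrics (never
  from community metrics) and logged with a reason; empty land uses are
  omitted from summaries with a warning.
- CSV round trips print reals at 17 significant digits (doubles round-trip
  exactly); counts are integers end to end.
- Weighted SDs are population-style ($\sqrt{\sum w_i (x_i - \bar x)^2}$),
  undefined (NA) for single-species plots; across-plot summaries use the
  sample SD (n − 1).
- A numerically constant response short-circuits the F test to statistic 0,
  p = 1 rather than amplifying rounding noise.
- Chao2 uses the bias-corrected estimator and its matching variance; at
  q₁ = 0 the SE is 0. The classic variant reproduces `vegan::specpool`
  including its q₂ = 0 variance form (which differs from the bias-corrected
  variance by a $-A^2 q_1^4/(4\hat S)$ term — the two published conventions).
- Exact rarefaction uses `lchoose` differences to avoid overflow; the
  permutation variant is for plotting parity and converges to it.

## Known limitations

- **Small-sample LR calibration.** The package's own calibration experiment
  (in the test suite) simulates 1000 null communities (no land-use effect)
  and finds the Gaussian F test at its nominal level, but the negative
  binomial likelihood-ratio χ² rejecting at ≈ 0.088 instead of 0.05 at
  n = 32 with 3 df — and ≈ 0.05–0.08 even when the null is exactly negative
  binomial. This anticonservativeness is a property of the asymptotic test
  itself at this design size (theta estimated, small n), not of the
  implementation; both LR variants (per-model theta, and full-model theta as
  in `anova()` on a `glm.nb` fit) behave identically. Abundance p-values
  near 0.05 should therefore be read cautiously; a parametric bootstrap
  would be the rigorous alternative and is out of scope here.
- Published isotope means ± SDs and Chao pool values depend on the deposited
  raw data and are not desk-reproducible; they are covered instead by
  invariants, noise-free closed forms, and a replication path: the pipeline
  accepts user-supplied tables in the documented CSV schema via
  `run_pipeline(input_dir = ...)`.
- The 12 vs 24 m² density normalisation cannot be resolved from design
  constants alone; 12 m² reproduces published densities and is the default,
  and the choice is recorded in the manifest.

## A complete run

```{r example, eval = FALSE}
study <- generate_study(sim_config(seed = 42))
report <- run_pipeline(study$dataset, output_dir = tempfile("antniche_"))
report$landuse_summary
report$stats
figs <- make_figures_data(report)
```

Problem sizes used by the shipped checks: oracle equivalence runs 100
simulated 16-plot studies; parameter recovery 200 full 32-plot studies per
experiment; calibration 1000 null communities — all chosen so the whole
suite completes in a few minutes on one core.
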