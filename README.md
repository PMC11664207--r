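# antniche

Leaf-calibrated, abundance-weighted isotopic niche metrics and community
decline metrics for canopy ant assemblages sampled along a tropical land-use
gradient.

## The scientific problem

Rainforest conversion to cash-crop plantations restructures arboreal
arthropod communities. For an abundant, ecologically central ant genus this
shows up in two ways: the **trophic niche** of the assemblage shifts and
compresses, and the **community** itself declines in density, richness and
compositional distinctness. Quantifying both requires combining plot-based
canopy-fogging counts with bulk stable isotopes of carbon and nitrogen
measured on individual workers, calibrated against each plot's own primary
producers. `antniche` implements that full analysis for a design of four
land-use systems (rainforest `F`, jungle rubber `J`, rubber `R`, oil palm
`O`), two landscape clusters, and eight 50 x 50 m plots per system, each
fogged at 3 subplots x 8 one-square-metre traps.

It is aimed at community and trophic ecologists who have (or want to
simulate) three tables — plot metadata, a plot x species worker-count table,
and specimen-level isotope measurements plus per-plot pooled-leaf baselines —
and want reproducible plot-level metrics and land-use contrasts.

## The metrics and models

**Leaf calibration.** For every specimen, Δ¹³C = δ¹³C − δ¹³C_leaf(plot) and
Δ¹⁵N = δ¹⁵N − δ¹⁵N_leaf(plot), anchoring each plot's food web at its basal
resource. Δ¹⁵N indexes trophic position (≈ 2–3 ‰ per trophic level), Δ¹³C
basal resource use.

**Functional community.** Per plot, species are ranked by worker count and
the shortest most-abundant-first prefix reaching 90 % of the plot total is
retained; only those species carry isotope measurements (≤ 5 specimens per
species per plot).

**Abundance-weighted niche metrics.** Δ values are averaged per species per
plot, then per plot with relative-abundance weights *wᵢ* (renormalised over
measured species):

- Average = Σᵢ wᵢ xᵢ
- Maximum / Minimum = extremes over the species means
- Range = Maximum − Minimum

**Community metrics.** Density (workers per m² of effective trap area,
default 12 m² per plot), richness, and an inverse-occupancy rarity score:
each species weighs 1/(number of occupied plots) — 1 for a plot-endemic,
1/32 = 0.03125 for a ubiquitous species — and a plot's rarity is the sum of
weights of the species it holds. Species pools per land use are estimated
with bias-corrected incidence-based Chao2,
`S_est = S_obs + ((N−1)/N) · q₁(q₁−1)/(2(q₂+1))`, with rank-abundance
curves, sample-based rarefaction, and a Venn/nestedness partition of species
by land-use membership.

**Land-use contrasts.** Fixed-effects models per response — negative
binomial (log link) for abundance, Gaussian for richness, rarity and the
Δ metrics (log link for the Δ¹⁵N Range) — simplified over the AICc ladder
`land_use * cluster` → `land_use + cluster` → `land_use`, then tested
globally against the nested null (F test, or likelihood-ratio χ² for the
negative binomial).

A hierarchical synthetic-data generator (`generate_study()`) emulates the
whole design — nested occupancy along the disturbance gradient, log-normal
species abundances with colony-level patchiness, gamma–Poisson counts,
land-use isotope shifts and niche-range compression — so the entire pipeline
is testable without field data, including parameter recovery.

## Worked example

```r
library(antniche)

study  <- generate_study(sim_config(seed = 42))
study$dataset
#> <iso_dataset>
#>   plots:      32 (F=8, J=8, O=8, R=8)
#>   abundances: 84 plot-species records, 10 species, 6,767 workers
#>   specimens:  309 isotope measurements
#>   baselines:  32 plots with leaf baseline

report <- run_pipeline(study$dataset)
report
#> <antniche_report>
#>   32 plots (31 retained for isotope metrics)
#>   68 species-plot means, 11 statistical responses

subset(report$landuse_summary, metric == "maximum_D13C")
#>    land_use       metric      mean        sd n_plots
#> 2         F maximum_D13C 5.7655511 0.9340660       8
#> 10        J maximum_D13C 6.3051668 0.2704353       8
#> 18        R maximum_D13C 0.9999015 0.5941523       8
#> 26        O maximum_D13C 1.6613776 0.5368277       7
```

The maximum Δ¹³C per land use shows the expected pattern: ants in rainforest
and jungle rubber are strongly ¹³C-enriched relative to local leaves
(≈ +6 ‰), while the monoculture communities sit much closer to their leaf
baseline — the generator's built-in monoculture shift recovered from the
simulated specimens. The land-use contrasts:

```r
report$stats[1:4, c("response", "family", "test", "statistic", "df1", "df2", "p_value")]
#>       response            family test  statistic df1 df2      p_value
#> 1  total_count negative_binomial   LR  30.402276   3  NA 1.135694e-06
#> 2     richness          gaussian    F   8.202020   3  28 4.500388e-04
#> 3       rarity          gaussian    F   6.193256   3  28 2.307646e-03
#> 4 average_D13C          gaussian    F 130.939453   3  27 3.373405e-16

report$species_pool
#>   land_use n_sites s_obs q1 q2 chao_est  chao_se
#> 1        F       8    10  4  1  12.6250 3.704938
#> 2        J       8     8  4  1  10.6250 3.704938
#> 3        R       8     4  2  1   4.4375 1.160465
#> 4        O       8     3  0  0   3.0000 0.000000
```

Richness is tested on all 32 plots (F on 3 and 28 df); abundance declines
by an order of magnitude in the monocultures (LR χ²₃ = 30.4); and the
nestedness report confirms that every monoculture community is a subset of
the rainforest pool (`report$overlap$nestedness`). `make_figures_data(report)`
returns tidy tables for the standard figure set, and
`run_pipeline(..., output_dir = "out/")` writes every table as CSV/JSON plus
a manifest of all configurable decisions.

Real data in the documented four-table CSV format are analysed identically
via `run_pipeline(input_dir = "path/to/tables")`.

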