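# zosterosim

An individual-based, spatially and genetically explicit simulator of
introgressive hybridization between two East African white-eye species: the
endangered montane forest specialist *Zosterops silvanus* of the Taita
Hills and its widespread lowland congener *Z. flavilateralis*. The package
is for eco-evolutionary modellers and conservation scientists who want to
explore whether, and under which mating behaviour and landscape change
scenarios, gene flow from a congener can produce *evolutionary rescue* —
population recovery through rapid adaptation — in a habitat-limited
species.

## The model in brief

Space is a raster of 1-ha patches described by above-ground carbon
(AGC, Mg C ha⁻¹), which sets each patch's habitat class (montane forest at
AGC ≥ 90) and carrying capacity K_p. Each bird is a diploid individual
with four quantitative traits, each the mean of two alleles: AGC optimum
*o* and tolerance *τ* (patch habitable iff |a_p − o| ≤ τ), and dispersal
kernel parameters μ_d, σ_d. Chromosomes carry immutable
species-of-origin tags; the *population heterozygosity* H of a species is
the percentage of extraspecific chromosomes in its gene pool — the
admixture currency of the whole analysis.

Every simulated year each bird passes through three processes:

1. **Survival** — fixed annual probability s = 0.875 (mean lifespan
   1/(1−s) = 8 years); widows keep the pair territory.
2. **Reproduction** — lifelong faithful pairs produce 0–2 offspring;
   genomes recombine via independent assortment of whole chromosomes;
   hybrid offspring take the species label of the phenotypically closer
   parent (trait-scaled distance).
3. **Dispersal** — juveniles walk a greedy stochastic-movement rule,
   stepping to the 8-neighbour whose AGC is closest to their own optimum,
   until they find a suitable patch (free breeding territory or an
   unpaired resident; a conspecific mate is always accepted, a
   heterospecific one with the hybridization propensity *h*) or exceed a
   kernel-drawn maximum distance and die.

The landscape module loads plain-text AGC rasters, detects montane forest
fragments (8-connected components), applies five habitat-change scenarios
(control, edge depletion, fragment clearing, corridor planting, plantation
conversion), and generates synthetic Taita-like landscapes with known
ground truth. The metrics module tracks population size, global /
per-patch / per-fragment heterozygosity, trait means, density maps, and
the regression of fragment heterozygosity on log fragment area.

## Worked example

```r
library(zosterosim)

# a synthetic fragmented landscape with known fragments
ls <- generate_landscape(60, 60, fragment_areas = c(26, 9, 4, 1), seed = 7)
identify_fragments(ls)[, 1:4]
#> # A tibble: 4 × 4
#>   fragment area_ha centroid_row centroid_col
#>      <int>   <int>        <dbl>        <dbl>
#> 1        1      26         43.7         21.3
#> 2        2       9         32           29
#> 3        3       4         39.5          2.5
#> 4        4       1         15           26

# three replicates of 40 years at a 5% hybridization propensity
cfg <- sim_config(landscape = ls, h = 0.05, years = 40, replicates = 3,
                  seed = 1)
res <- run_simulation(cfg)
glance(res)
#> # A tibble: 1 × 8
#>   years replicates     h scenario mean_final_n mean_final_heterozygosity ...
#> 1    40          3  0.05 control          215.                      9.35
```

After 40 years the specialist's gene pool holds ≈9.4% extraspecific
chromosomes and the population mean sits at 215 adults; `tidy(res)` returns
the full per-replicate, per-year trajectory and `autoplot(res)` plots it.
Sweeps over propensities or habitat scenarios run via
`run_experiment(propensity_sweep(...))` and
`run_experiment(habitat_sweep(...))`.

The bundled reference fragment table reproduces the fragment-area effect:

```r
fit <- fragment_regression(taita_fragments, heterozygosity = "mean")
fit
#> <zos_fragment_fit> slope = -1.8 % per ln-ha, adj R^2 = 0.307 (n = 19)
```

Heterozygosity declines by about 1.8 percentage points per ln-hectare of
fragment area: small fragments, with their high edge-to-area ratio, are
where admixture concentrates.

A thin command-line front end is included at `inst/scripts/simulate.R`
(`--config run.yaml`, `--experiment hybridization|habitat`).

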