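---
title: "Methods: an individual-based model of hybridization-mediated evolutionary rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an individual-based model of hybridization-mediated evolutionary rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

zosterosim simulates two hybridizing white-eye species on a raster landscape
to ask whether introgressive gene flow from a widespread lowland generalist
(*Zosterops flavilateralis*) can rescue an endangered montane forest
specialist (*Z. silvanus*) whose habitat is fragmented. This vignette
documents the model, its parameters, the synthetic landscape generator, and
the numerical and design choices behind them.

## The model

**Landscape.** Space is a grid of 1-ha patches, each characterized by a
single habitat descriptor: above-ground carbon (AGC, Mg C ha^-1^). AGC
determines a habitat class through a step function (montane forest at
AGC ≥ 90; below that, configurable breakpoints for bushland/exotic,
woodland and cropland at 40, 10 and 0 by default) and, through the class, a
carrying capacity `K_p` in adult birds per patch (defaults 8/6/4/2 for
forest/bushland/woodland/cropland). Capacities are even because territory
slots are consumed in breeding-pair units of two. The per-class densities
are calibration knobs, not field estimates. A *fragment* is an 8-connected
(queen adjacency) component of montane-forest patches; a bird that can step
diagonally experiences diagonal forest as contiguous, so fragment
connectivity matches the movement neighbourhood.

**Genetics.** Each bird is diploid. Four quantitative traits — AGC optimum
`o`, AGC tolerance `τ` (a patch is habitable iff `|a_p − o| ≤ τ`), and the
location `μ_d` and scale `σ_d` of the dispersal kernel — are each encoded
by one gene whose expressed value is the arithmetic mean of the two
alleles. Genes sit on chromosomes; with the default of one gene per
chromosome the four traits assort independently at meiosis, while 2 or 4
genes per chromosome model genetic linkage. There is no intra-chromosome
crossover: recombination acts only through the independent assortment of
whole chromosomes, which is what makes linkage a pure consequence of gene
co-location. Every chromosome carries an immutable species-of-origin tag
copied from its founder lineage. The *population heterozygosity* `H` of a
species is the percentage of chromosomes in its gene pool whose tag belongs
to the other species — an admixture measure, not locus-level
heterozygosity. Tags persist through backcrossing indefinitely, which keeps
`H` well defined across generations; an empty gene pool has undefined `H`
(reported as missing, never 0).

**Founders.** *Z. silvanus* starts with `o = 180`, `τ = 90` (habitable band
90–270, montane forest) and *Z. flavilateralis* with `o = 50`, `τ = 47`
(band 3–97, everything else). Founder dispersal parameters default to
`μ_d = 30, σ_d = 10` (the specialist is a strong disperser) and
`μ_d = 15, σ_d = 5`; they are calibration values chosen so inter-fragment
distances on the default synthetic map are within reach. Founders are
homozygous, so without mutation the allele pool holds two values per trait
and expressed traits take three values each; all later variation comes from
recombination and hybridization.

**Annual cycle.** Each iteration is one year: survival, then reproduction,
then juvenile dispersal, then the census.

* *Survival* is an annual, fixed, density-independent Bernoulli draw with
  probability `s = 0.875` per species, derived from a mean life expectancy
  of roughly eight years under geometric lifetimes (`1/(1−s) = 8`). A
  surviving partner is widowed: it keeps the pair territory (two capacity
  slots, one reserved for a future mate) and becomes partner-less.
* *Reproduction*: breeding pairs are faithful for life and sedentary. Each
  pair draws a brood of 0, 1 or 2 offspring (uniform by default, mean 1 —
  clutch size, breeding attempts and juvenile mortality folded together).
  Offspring genomes fuse one meiotic gamete per parent; sex is random. A
  hybrid offspring is assigned to the species of the phenotypically closer
  parent: Euclidean distance over the four expressed traits, each scaled by
  the founder inter-species difference so that all traits contribute
  comparably; exact ties are resolved at random (an F1 of pure founders is
  exactly equidistant).
* *Dispersal*: juveniles leave their natal patch and move step by step to
  the 8-neighbour whose AGC is closest to their own AGC optimum (ties
  uniform at random; one uniform deviate per step so paths are fully
  seeded). This is a greedy adaptation of the stochastic movement
  simulator; deliberately, there is no matrix-avoidance penalty. Each
  juvenile first draws a maximum path length from a logistic kernel with
  its expressed `(μ_d, σ_d)`, truncated below at one patch length; diagonal
  steps cost √2. On every newly entered patch the bird checks settlement:
  it first tries to mate — an unpaired opposite-sex conspecific resident is
  always joined; failing that, an unpaired heterospecific resident is
  accepted with the hybridization propensity `h`, the single free
  behavioural parameter of the study — and only otherwise stakes out a
  territory if at least two capacity slots are free. A declined
  heterospecific option keeps the bird moving. Exceeding the drawn maximum
  distance is death. Territory settlers of the same cohort become joinable
  immediately, and a single without a reserved slot is joinable only while
  the patch has a free slot, which keeps adults within `K_p` at every
  census.

**Initialization.** Every patch whose AGC falls in a species' band receives
a uniform random number of founders between 0 and the remaining capacity
(species in random order per patch). Founders then go through one
settlement-style pairing pass inside their patch — conspecifics pair up,
remaining heterospecific combinations form with probability `h`. Without
this pass the population could never reproduce, because the annual cycle
creates new pairs only when dispersers join residents.

## The synthetic landscape generator

The generator emulates the essential structure of the Taita Hills AGC map:
a low-AGC agricultural matrix containing compact montane-forest fragments
(default: the 19 reference fragment areas, 180 ha down to 1 ha, on a
150×150 grid), each wrapped in an intermediate-AGC transition ring. It also
derives one scenario of each kind from the geometry it created: converting
the edge cells of the three largest fragments to woodland AGC
(edge depletion, 20 Mg C ha^-1^), clear-cutting the four smallest fragments
(fragment clearing, 20), planting a one-patch-wide corridor between the two
largest fragments (corridor planting, 100), and adding a new forest block
in the matrix (plantation conversion, 294 ha at 100).

Two deliberate symmetries in the default AGC levels (matrix 5, edge 60,
fragment 95) make the landscape *percolate* under the greedy movement rule.
Strict argmin movement on a discrete landscape confines each phenotype to
the cells nearest its own optimum, so habitat levels must be chosen the way
a continuous map behaves, where near-optimum cells form long connected
chains. First, all fragment cells share one AGC value just above the forest
threshold, so a whole fragment is a single tie-neighbourhood: its residents
(specialists with `o = 180` and hybrids alike) roam and can settle
anywhere in it. Second, matrix (5) and fragment (95) cells are exactly
equidistant from the generalist's optimum (50), so its random walk through
the matrix steps into fragment edges wherever the patchy transition ring
(60, coverage 0.25 by default) leaves a gap — the rings are attractive to
the generalist and hold it near fragments, while the gaps admit it into the
contact zone. These choices were made once, on the grounds above; a denser
forest core can be restored via `agc_levels` (e.g. `forest = 265`, the
mirror image of 95 around the specialist's optimum), at the cost of
excluding hybrid genotypes, whose tolerance bands end below 265, from the
fragment interior.

What the generator does *not* emulate: continuous AGC variation, elevation
and rainfall gradients, real fragment shapes, and the spatial
autocorrelation of the true map. Passing tests on these landscapes
therefore demonstrate the mechanics of the eco-evolutionary feedback —
contact-zone hybridization, introgression, habitat expansion — not
quantitative predictions for the Taita Hills.

## Emergent dynamics worth knowing about

With hybridization disabled the two gene pools are provably closed: `H ≡ 0`
and the specialist occupies only patches inside its founder band. With
`h > 0`, mixed pairs form in fragment edge cells, F1 birds (`o = 115`,
`τ = 68.5`) concentrate there, and backcrossing gradually assembles
genotypes that combine the generalist's low AGC optimum with the
specialist's broad tolerance. Individuals carrying such genotypes but
labelled *Z. silvanus* colonize the transition rings and the matrix — the
species expands beyond montane forest, its mean AGC optimum declines, and
its population exceeds the hybridization-free plateau: evolutionary rescue
through introgression, with hybrid vigour emerging from the broadened
habitat band rather than being imposed. At high propensities the same
mixing also floods the specialist's pool with the generalist's narrow
tolerance, so intermediate propensities do best in the long run. Because
the generalist's influx enters through fragment boundaries, small
fragments (high perimeter-to-area ratio) end up with higher admixture than
the interiors of large ones, giving the negative regression of fragment
heterozygosity on log fragment area.

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG, including the C++ dispersal core
  (`unif_rand`), so a run is reproducible from its seed; replicate `r` of a
  configuration with seed `s` uses seed `s + r`, and a synthetic landscape
  is generated once under `s` and shared by replicates.
* Movement consumes exactly one uniform deviate per step (even for a unique
  argmin), so step streams can be replayed and verified against independent
  path enumeration.
* AGC comparisons for ties are exact floating-point equality; the tie
  symmetries of the generator use exactly representable differences
  (|5−50| = |95−50| = 45).
* The distance cap is checked after each step with a 1e-9 slack; a bird
  whose step would exceed its drawn maximum dies before any settlement
  check on that patch.
* Mutation (disabled by default, matching the main study conditions) is a
  per-allele Bernoulli(10^-3^) Gaussian perturbation with per-trait
  standard deviation defaulting to 5% of the founder inter-species
  difference; tolerance and dispersal traits are floored at zero. Origin
  tags are untouched, so mutation-only runs keep `H = 0` while trait
  variation accumulates.
* Degenerate inputs: an all-nodata raster yields an empty habitable set; an
  empty population is an absorbing state whose summaries report zero adults
  and missing means; a fragment regression needs at least three fragments
  with defined heterozygosity and errors otherwise; an isolated cell
  without valid neighbours kills its dispersers.
* The log base of the fragment-area regression is natural log; the slope of
  the bundled reference table (−1.80 % per ln-ha, adjusted R² 0.31) pins
  this convention down, since a base-10 regression gives −4.14.

## Problem sizes

The packaged analyses use desk-scale study conditions chosen to show the
mechanisms with replication: 150×150 grids with the 19 reference fragment
areas, propensities {0, 1, 5, 10, 50, 100}%, 10 replicates × 100 years for
the propensity experiment (the 1% condition runs to year 300, the horizon
of the reference fragment table, for the fragment-level analysis), and 5
replicates (60 years, the 1% condition to year 300) in the acceptance
script's summary runs. Full-scale runs (50 replicates × 300 years on the
~96,200-patch Taita map) are supported by the same code paths given the
archived raster as `landscape` input.

## Known limitations

* Only two allele values per trait exist without mutation, so expressed
  traits take three values each; trait trajectories move through changing
  genotype frequencies rather than continuous shifts.
* The discrete-level landscape approximates continuous AGC variation by
  designed tie-sets; phenotypes whose optima fall between levels (possible
  under mutation) can be locally trapped by the greedy rule.
* Pairing is strictly heterosexual and lifelong with no divorce,
  re-pairing happens only through arriving dispersers, and there is no
  age structure in the vital rates (age is tracked for diagnostics only).
* One global hybridization propensity applies to both species; whether the
  acting disperser's species should carry its own propensity is untestable
  from the source material.
* The habitat scenarios are static; coupling to land-use change is out of
  scope.
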