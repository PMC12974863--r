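---
title: "Simulating and diagnosing bacterial ecoclines"
author: "ecocline package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing bacterial ecoclines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocline)
```

## The problem

Trees built from diverse samples of highly recombining bacteria such as
*Klebsiella pneumoniae* are "bushy": recombination erases most vertical
signal and strains radiate from a dense centre. Some species nevertheless
show a *backbone* — a single connected path of internal branches that
carries a large fraction of the tree's total internal branch length — with
the first principal component of the genotype matrix aligned along it.
One candidate explanation is a *bacterial ecocline*: diversifying
selection on an additive quantitative trait, balanced against the
homogenising effect of homologous recombination, spreads the population
continuously along a genetic gradient that is not geographic in origin.

This package provides (i) a forward-time, individual-based
(non-Wright–Fisher) simulator of recombining haploid populations under six
scenarios — neutral single population, linear stepping stone,
recombination-hotspot and mutation-rate heterogeneity, and diversifying
selection with uniform or Gamma-distributed per-site effects — and (ii)
the diagnostic stack used to tell these scenarios apart: binary
minor-allele SNP matrices, PCA strain and variant loadings, three
half-matching reproducibility tests, linkage-disequilibrium decay and
block structure, and a quantitative backbone score on neighbour-joining
trees.

## The simulation model

Each individual carries one haploid, linear chromosome represented
sparsely as a map from site to mutation record, relative to an empty
ancestral chromosome. Per generation, in order:

1. **Mutation.** Each genome gains Poisson(μ·L) mutations at uniform
   sites (μ = 10⁻⁶ per site per generation by default). A mutation is of
   type m1 or m2 with probability ½ each; both types are neutral in
   themselves and a new mutation replaces any resident record at its site
   (finite-sites convention, which keeps one record per site and maps
   directly onto the binary matrix downstream).
2. **HGT.** Every individual receives a fixed number of tract copies
   (rate-1.0 scheduler: one event per individual per generation by
   default). A donor is drawn uniformly from the rest of the population
   (from the recipient's deme in the stepping-stone model; 50/50 by label
   in the mutation-heterogeneity model), and the recipient's records in
   the half-open tract `[start, start+len)` are replaced by the donor's.
   Donor states are taken from a snapshot at the start of the HGT stage,
   so the operation is simultaneous and order-independent; tracts
   truncate at the chromosome end (hotspots sit well inside the
   chromosome, so truncation is rare).
3. **Migration** (stepping stone only). Each deme sends a fixed number of
   uniformly chosen individuals to each adjacent deme on the line;
   emigrant choices are made against pre-migration membership, so counts
   are conserved.
4. **Reproduction and regulation.** Each individual produces
   Poisson(λ) clonal offspring. In the neutral phase λ = 2 for everyone.
   During the selection phase of the selective scenarios, λ is the
   diversifying-selection fitness
   `2 + a·|s−μ̄|^k / (max|s−μ̄|^k + ε)` with trait score
   `s = Σ m1 effects − Σ m2 effects`, amplitude `a` (1.0, or 0.5 in the
   refined model), exponent `k` (5 or 10) and ε = 10⁻⁶; the mean μ̄ is
   recomputed from the current population every generation. Individuals
   at both tails of the trait distribution therefore out-reproduce
   intermediates. If the offspring pool exceeds the carrying capacity, a
   uniform random subset of exactly the capacity survives (per deme in
   the stepping-stone model); generations are non-overlapping. How a
   non-WF bacterial population is held at its census size is a modelling
   choice (the hard-capacity rule used here preserves the relative
   fitness structure the offspring law implies); survival scaling would
   be an alternative.

The generation loop runs in compiled code driven by R's RNG, so a run is
reproducible bit-for-bit from its `ScenarioSpec` seed. The per-operation
R functions (`mutatePopulation()`, `hgtEvent()`, `fitnessVector()`,
`reproduceAndRegulate()`, `migrateSteppingStone()`, ...) implement the
same rules and are what the unit tests exercise against analytic and
brute-force oracles.

Effect sizes: in the uniform model every site has effect 1, so the trait
is simply the m1 count minus the m2 count. In the Gamma model each of the
L sites receives a fixed magnitude drawn from Gamma(shape, scale) with
shape·scale = 1, so the mean effect stays 1 and the scale parameter
controls how concentrated the trait architecture is; whether a site ever
mutates or not, its coefficient is defined.

## Scale presets

The `"paper"` preset uses full study-scale parameters: 1 Mb chromosomes
(5 Mb in the refined Gamma model), populations of 10⁴ (2,000 for the
stepping stone), 10⁴ generations with selection from generation 5,001,
20 kb tracts, and Gamma scale 5·10⁶ with five 20 kb tracts per
generation in the refined model.

The `"desk"` preset is what the tests and worked examples run: N = 500,
L = 100 kb, 2,000 generations with selection from generation 1,001, and
tract lengths scaled by the genome-length ratio ({0.1, 2, 10} kb standing
in for {1, 20, 100} kb), preserving the tract/genome and HGT-event ratios
that the phenomenology depends on. Remaining desk choices, each made
once:

* **Stepping stone, 1 migrant per neighbour** (deme size 50): keeps the
  migrant counts in the low range (1–50 per generation for demes of
  100–1,000) where drift between demes builds a backbone.
* **Gamma scale 10⁴** (shape 10⁻⁴, mean 1): maintains on the order of
  ten large-effect segregating loci on the 100 kb chromosome. The
  sharper shape·L = 1 regime of the full-scale model is not attainable
  at desk scale: the per-site establishment supply N·μ·T is roughly a
  hundredfold smaller, so a single-locus architecture usually never
  acquires its mutation and the trait signal vanishes.
* **Mutation rate stays at 10⁻⁶ per site**, as at full scale. The
  per-genome mutation supply is therefore tenfold lower than at full
  scale, which pushes the selective scenarios towards the
  low-recombination end of the selection–recombination balance (see
  "What desk-scale runs do and do not show").

## The diagnostic stack

**Binary encoding.** At each polymorphic site the allele with the second
largest count (the minor allele) is coded 1; every other state, including
the third and fourth most frequent alleles at multi-allelic sites, is
coded 0. The ancestral (no-mutation) state is an allele like any other.
Count ties are resolved so that the smaller internal identifier
(ancestral < m1 < m2; for imported calls, the lexicographically smaller
allele) becomes the minor allele — deterministic and documented. Sites
below 2% minor-allele frequency are removed before PCA. Windowed LD
pruning (remove the later site of any pair with R² > 0.1 within 50 kb) is
implemented and exported, but simulated matrices are analysed unpruned,
matching how the full-scale study treated its simulations; imported
real-data matrices should be pruned.

**Non-redundant selection.** A greedy scan keeps a strain iff its Hamming
distance to every kept strain exceeds a threshold. The pipeline applies
it before the tree and half-matching diagnostics with a default threshold
of half the run's mean pairwise distance — at the full-scale simulation
parameters this reproduces the 2 kb threshold used there (equilibrium
diversity 2NμL = 4 kb). Without it, the dense clonal micro-structure of
a completely sampled population dominates every tree-shape statistic.
The greedy pass runs in input order; real-data users who want a canonical
set should sort first.

**PCA and loadings.** Columns are mean-centred (a variance-standardised
mode is available) and the strain covariance is eigen-decomposed by SVD.
Strain loadings are eigenvectors scaled by the square root of the
eigenvalues — the standard loading definition; scaling by the raw
eigenvalues is available behind `loadingScale = "eigenvalue"` for
replication against tools that report it that way. Per-variant loadings
are the product of the (raw binary, MAF-filtered, unpruned) matrix with
the strain loadings, one value per MAF site; squared loadings provide the
direction-independent per-site summary. Projection of a second strain
set onto existing loadings is a plain matrix product over the shared
sites; its scale is arbitrary, so it is only ever correlated.

**Half-matching.** Three reproducibility tests for PC1: (1) half-strain —
split the strains in two (by default on the sign of a preliminary
full-data PC1, standing in for a split along the tree backbone), define
loadings on one group, project the other, and correlate the projection
with the projected group's own PC1, in both directions; (2) half-genome —
independent PCAs on the two halves of the chromosome; (3)
partial-variants — assign each site the maximum squared PC1 loading
within a 50 kb vicinity (genome-ratio scaled), call the lower tertile
low-loading and the upper decile high-loading, ignore the middle, and
correlate the PC1s of independent PCAs on the two sets. The tertile and
decile cutoffs are defaults of this package (the source analyses show the
histogram split but print no numbers) and are configurable. Because
"significant correlation" needs an operational definition, every test
carries a permutation null: 200 strain-relabelling permutations,
α = 0.01.

**LD.** Pairwise LD is the frequency form
R² = (f_ij − f_i f_j)² / (f_i f_i′ f_j f_j′), algebraically the squared
Pearson correlation of the binary columns (asserted numerically to
10⁻¹⁰ in the tests). The decay curve averages R² in 10 bp distance bins
(scaled) up to a 30 kb (scaled) cap, with no MAF or equilibrium filtering
inside the computation. High-loading variants (squared PC1 loading above
a configurable cutoff, 300 in the source analyses) get a full-genome R²
matrix, clustered by complete-linkage agglomeration on 1 − R² and cut to
a requested block count; complete linkage keeps blocks tight, matching
the visually crisp blocks of published LD heatmaps. Whether to cut by
count or height is open; count is implemented (44 for the real data,
configurable).

**Trees.** Neighbour joining (via ape) on Hamming distances, with
negative branch estimates clamped to zero — the diagnostics need tree
*shape*, not substitution-model inference, which is why no
maximum-likelihood engine is wrapped. `backboneScore()` computes, by
dynamic programming over the unrooted tree, the maximum over simple
paths of the internal branch length on the path, divided by the total
internal branch length: 0 for a perfect star, 1 for a caterpillar. The
score is reported as a continuous fraction; the notion of "having a
backbone" is graded, so no threshold is imposed.

## What desk-scale runs do and do not show

The desk-scale test suite reproduces, with three fixed seeds per
condition: the higher backbone score and PC1–trait correlation of
intermediate-recombination selective runs over matched neutral runs; the
collapse of that backbone at high recombination; the stronger
leptokurtosis of PC1 loadings under Gamma effects than under uniform
effects; a stepping-stone backbone whose loading distribution carries
more intermediate values (lower kurtosis) than selection produces; and
the half-matching asymmetry of neutral runs (at most one of three tests
significant).

Two full-scale behaviours do **not** survive the desk rescaling, and the
corresponding checks are expected to fail honestly rather than being
relaxed:

* At N = 500 the selective runs sit in the low-recombination regime and
  split into two discrete trait clusters rather than a continuous cline.
  Within either half of the strain split there is then almost no
  trait-axis variance, so the half-strain test — which asks whether one
  half's PC1 is recoverable inside the other half — is structurally near
  zero even though half-genome and partial-variants both reproduce.
  Ecologically this is the ecospecies limit of the model, not the
  ecocline.
* With order-ten comparable large-effect loci (the only architecture
  that establishes reliably at desk scale), the top squared-loading peak
  always tags *one of* the leading trait-variance contributors, but not
  reliably the single largest one.

Desk simulations also idealise real data in ways that matter for
interpretation: complete sampling of the population, no missing calls,
no accessory genome, a single linear chromosome, and neutrality of both
mutation types outside the trait. Passing tests therefore validate the
mechanics and the qualitative contrasts, not any quantitative claim
about real species.

## Numerical notes

* The fitness band `[2, 2+a)` is analytically open at the top, but when
  `max|s−μ̄|^k` is large the ε in the denominator falls below double
  precision and the bound is attained exactly; tests and downstream code
  treat the band as closed.
* Minor-allele ties (frequency exactly 0.5, or rank ties at
  multi-allelic sites) are broken towards the smaller allele identifier.
* LD pruning processes sites left-to-right and removes the
  later-positioned member of an offending pair; with any step not larger
  than the window this is equivalent to the sliding-window formulation
  and leaves no retained within-window pair above the R² cap
  (post-checked in tests).
* Monomorphic columns are undefined for R² and flagged `NA`, never
  silently zero; strain subsetting does not re-encode a matrix, so
  `dropMonomorphicSites()` runs before any within-subset PCA.
* Extinction (zero offspring in a generation, or an empty deme) raises
  an error; runs are never silently restarted.

## Run sizes used by the tests

Unit tests run toy populations (tens of strains, ≤ 20 kb genomes,
hundreds of generations). The phenomenology suite runs fifteen
desk-preset pipelines (five conditions × seeds 101–103), about a minute
of compute in total; the acceptance script's sampling experiments use
10³–10⁴ draws each and finish in seconds.
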