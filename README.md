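# ecocline

Forward-time simulation and diagnosis of **bacterial ecoclines**:
continuous, genome-wide gradients of allele frequencies generated by
diversifying selection on an additive quantitative trait, balanced
against homologous recombination — the candidate explanation for the
"backboned" phylogenies seen in highly recombining species such as
*Klebsiella pneumoniae*.

The package is aimed at bacterial population geneticists who want to ask,
on simulated data with a known ground truth, which observable signatures
separate selection-driven clines from the alternatives (pure drift,
geographic stepping-stone structure, mutation- or recombination-rate
heterogeneity).

## What it implements

**Simulator** — an individual-based, non-Wright–Fisher model of clonal
haploid bacteria. Each genome is a sparse set of site mutations (two
neutral types, m1/m2, 1:1). Per generation: Poisson mutation
(10⁻⁶/site by default), HGT tract copying (every individual receives a
fixed-length tract from a random donor each generation), optional linear
stepping-stone migration, and Poisson reproduction with a hard carrying
capacity. During the selection phase, the trait score of an individual is

    s = Σ (m1 effects) − Σ (m2 effects)

and its offspring rate is the diversifying-selection fitness

    λ = 2 + a · |s − μ̄|^k / (max|s − μ̄|^k + ε),

so both tails of the trait distribution out-reproduce intermediates
(amplitude a = 1, exponent k = 5; the refined model uses a = 0.5,
k = 10). Effect magnitudes are either all 1 or drawn per site from a
mean-1 Gamma law whose scale parameter concentrates the architecture.
Six scenarios ship with `"paper"` (full) and `"desk"` (scaled-down)
presets.

**Diagnostics** — the analysis stack applied to the binary strain × SNP
minor-allele matrix: MAF filtering and windowed LD pruning;
non-redundant strain selection by pairwise SNP distance; PCA with strain
loadings (eigenvectors × √eigenvalues), per-variant loadings (binary
matrix × strain loadings) and cross-group projection; three
half-matching reproducibility tests for PC1 with permutation nulls;
LD decay curves, high-loading R² matrices and hierarchical block
clustering; neighbour-joining trees and a `backboneScore()` — the
largest fraction of total internal branch length carried by a single
path (star = 0, caterpillar = 1). VCF and TSV import/export included.

## Worked example

```r
library(ecocline)

spec <- scenarioSpec("selective_uniform", preset = "desk", seed = 42)
spec
#> ScenarioSpec: selective_uniform
#>   genome 100000 bp | N = 500 in 1 deme(s) | 2000 generations
#>   mu = 1e-06 /site/gen | HGT 1 x 2000 bp tract(s)/ind/gen
#>   selection from generation 1001 (amplitude 1, exponent 5)
#>   seed: 42

sim <- runScenario(spec)
sim
#> SimOutput: 500 individuals (selective_uniform scenario)
#>   mutations per genome: mean 233.5 (range 218-251)
#>   trait: mean 1.284, sd 39.107

rep <- runPipeline(spec)   # encode -> filter -> PCA -> half-match -> LD -> tree
neu <- runPipeline(scenarioSpec("neutral", preset = "desk", seed = 42))
compareRuns(list(rep, neu))
#>            scenario seed      pve1  backbone r_half_strain r_half_genome
#> 1 selective_uniform   42 0.2820385 0.4977208     0.1593472     0.8136234
#> 2           neutral   42 0.1122389 0.2971660     0.1761523     0.7170907
#>   r_partial_variants n_significant pc1_trait_r loading_kurtosis
#> 1          0.7614824             2   0.9923888       -0.1515625
#> 2          0.3620617             1   0.4800498        1.8515443
```

Reading the table: the selective run's PC1 explains 2.5× more variance
than the neutral run's, its strain PC1 scores track the true simulated
trait almost perfectly (|r| = 0.99 vs 0.48), and its tree carries half
of its internal branch length on a single path (backbone 0.50 vs 0.30).
Half-genome and partial-variants matching reproduce PC1 significantly in
the selective run (2 of 3 tests; at this scaled-down population size the
selective regime splits into two discrete clusters, so the half-strain
test has no within-half trait variance to recover — see the methods
vignette). A scenario can also be run from the shell:

```sh
Rscript inst/scripts/ecocline-pipeline.R --scenario selective_gamma \
    --preset desk --seed 7 --out run7
```

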