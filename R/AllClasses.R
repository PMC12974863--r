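#' @import methods
NULL

.SCENARIOS <- c("neutral", "stepping_stone", "hotspot", "mutation_het",
                "selective_uniform", "selective_gamma")

#' ScenarioSpec: configuration of one simulation scenario
#'
#' Holds the full parameterisation of a forward-time run: genome and
#' population sizes, mutation and HGT rates, the demographic model
#' (single population, linear stepping stone, or labelled-subpopulation
#' heterogeneity), the diversifying-selection phase and fitness function,
#' and the effect-size law for the quantitative trait. Use [scenarioSpec()]
#' to construct one with scenario-appropriate defaults.
#'
#' @slot scenario one of `"neutral"`, `"stepping_stone"`, `"hotspot"`,
#'   `"mutation_het"`, `"selective_uniform"`, `"selective_gamma"`.
#' @slot genomeLength chromosome length in bp (haploid, linear coordinates).
#' @slot popSize total carrying capacity (summed over demes).
#' @slot nDemes number of demes (1 except for the stepping-stone model).
#' @slot migrantsPerGen individuals sent to each adjacent deme per generation.
#' @slot mutationRate per-site, per-generation mutation rate.
#' @slot hgtEventsPerGen HGT tract copies received by every individual per
#'   generation (the rate-1.0 scheduler: each individual is a recipient).
#' @slot hgtTractLength tract length in bp (truncated at the chromosome end).
#' @slot hotspotPositions bp start coordinates of recombination hotspots.
#' @slot hotspotFraction fraction of HGT events forced to start at a hotspot.
#' @slot generations number of generations to run.
#' @slot selectionStart first generation at which diversifying selection acts
#'   (ignored for non-selective scenarios).
#' @slot fitnessAmplitude amplitude of the fitness function (1.0 or 0.5).
#' @slot fitnessExponent exponent of the deviation power law (5 or 10).
#' @slot fitnessEpsilon regulariser in the fitness denominator.
#' @slot gammaShape,gammaScale Gamma law for per-site effect magnitudes
#'   (`selective_gamma`); shape*scale = 1 keeps the mean effect at 1.
#' @slot baseLambda neutral-phase Poisson offspring mean (2.0).
#' @slot seed integer seed; fixes the run bit-for-bit.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    scenario = "character",
    genomeLength = "numeric",
    popSize = "numeric",
    nDemes = "numeric",
    migrantsPerGen = "numeric",
    mutationRate = "numeric",
    hgtEventsPerGen = "numeric",
    hgtTractLength = "numeric",
    hotspotPositions = "numeric",
    hotspotFraction = "numeric",
    generations = "numeric",
    selectionStart = "numeric",
    fitnessAmplitude = "numeric",
    fitnessExponent = "numeric",
    fitnessEpsilon = "numeric",
    gammaShape = "numeric",
    gammaScale = "numeric",
    baseLambda = "numeric",
    seed = "numeric"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character(0)
  if (!(object@scenario %in% .SCENARIOS))
    msg <- c(msg, paste("unknown scenario:", object@scenario))
  if (object@genomeLength < 1) msg <- c(msg, "genomeLength must be >= 1")
  if (object@popSize < 2) msg <- c(msg, "popSize must be >= 2")
  if (object@nDemes < 1) msg <- c(msg, "nDemes must be >= 1")
  if (object@popSize %% object@nDemes != 0)
    msg <- c(msg, "popSize must be divisible by nDemes")
  if (object@mutationRate < 0) msg <- c(msg, "mutationRate must be >= 0")
  if (object@hotspotFraction < 0 || object@hotspotFraction > 1)
    msg <- c(msg, "hotspotFraction must be in [0, 1]")
  if (object@hotspotFraction > 0 && length(object@hotspotPositions) == 0)
    msg <- c(msg, "hotspotFraction > 0 requires hotspotPositions")
  if (any(object@hotspotPositions < 0) ||
      any(object@hotspotPositions >= object@genomeLength))
    msg <- c(msg, "hotspotPositions must lie in [0, genomeLength)")
  if (object@scenario %in% c("selective_uniform", "selective_gamma") &&
      object@selectionStart > object@generations + 1)
    msg <- c(msg, "selectionStart must be <= generations + 1")
  if (object@scenario == "selective_gamma" &&
      (object@gammaShape <= 0 || object@gammaScale <= 0))
    msg <- c(msg, "gammaShape and gammaScale must be positive")
  if (length(msg)) msg else TRUE
})

#' SimOutput: result of one forward-time run
#'
#' @slot population list of genomes; each genome is a list with integer
#'   fields `pos` (sorted 0-based mutated sites), `type` (1 = m1, 2 = m2),
#'   `deme` and `label`.
#' @slot traitValues per-individual quantitative trait scores at the final
#'   generation (all-ones effects unless the scenario draws a Gamma table).
#' @slot effectTable per-site effect magnitudes (length 0 for uniform
#'   effects, meaning every coefficient is 1).
#' @slot generationLog per-generation summaries: population size, mean trait
#'   score, mean offspring rate, realised mean offspring count and the
#'   fraction of HGT recipients.
#' @slot spec the [ScenarioSpec-class] that produced the run.
#' @exportClass SimOutput
setClass("SimOutput",
  representation(
    population = "list",
    traitValues = "numeric",
    effectTable = "numeric",
    generationLog = "data.frame",
    spec = "ScenarioSpec"
  )
)

setValidity("SimOutput", function(object) {
  if (length(object@traitValues) != length(object@population))
    return("traitValues length must equal population size")
  TRUE
})

#' SNPMatrix: strains x polymorphic-sites binary minor-allele matrix
#'
#' Rows are strains, columns are polymorphic sites; entry 1 marks the
#' minor allele (the second most frequent state at that site), 0 all other
#' states including ranks 3-4 at multi-allelic sites.
#'
#' @slot values integer matrix in \{0, 1\}, strains x sites.
#' @slot positions 0-based bp coordinate per site, strictly increasing.
#' @slot strainIds character labels, one per row.
#' @slot minorFreqs frequency of the allele coded 1 at each site, as
#'   computed at encoding time (<= 0.5 by construction; strain subsetting
#'   does not re-encode).
#' @exportClass SNPMatrix
setClass("SNPMatrix",
  representation(
    values = "matrix",
    positions = "numeric",
    strainIds = "character",
    minorFreqs = "numeric"
  )
)

setValidity("SNPMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@values) != length(object@positions))
    msg <- c(msg, "positions length must equal number of columns")
  if (nrow(object@values) != length(object@strainIds))
    msg <- c(msg, "strainIds length must equal number of rows")
  if (length(object@minorFreqs) != length(object@positions))
    msg <- c(msg, "minorFreqs length must equal number of sites")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@values) && !all(object@values %in% c(0L, 1L)))
    msg <- c(msg, "values must be binary (0/1)")
  if (length(msg)) msg else TRUE
})

#' PCAResult: eigen-decomposition of a strain x strain covariance
#'
#' @slot eigenvalues top-k eigenvalues of the strain covariance.
#' @slot pve proportion of total variance explained by each retained
#'   component (computed from the full spectrum).
#' @slot strainLoadings strains x k scores: eigenvectors scaled by the
#'   square root of the eigenvalues (default) or by the eigenvalues.
#' @slot strainIds strain labels matching the input matrix rows.
#' @slot loadingScale `"sqrt"` or `"eigenvalue"`.
#' @slot standardize `"center"` or `"plink"` (unit-variance scaling).
#' @exportClass PCAResult
setClass("PCAResult",
  representation(
    eigenvalues = "numeric",
    pve = "numeric",
    strainLoadings = "matrix",
    strainIds = "character",
    loadingScale = "character",
    standardize = "character"
  )
)

#' HalfMatchReport: result of one PC1 reproducibility test
#'
#' @slot testName `"half_strain"`, `"half_genome"` or `"partial_variants"`.
#' @slot rForward,rReverse absolute Pearson correlations between the two
#'   PC1 estimates (`rReverse` is `NA` except for the half-strain test).
#' @slot pForward,pReverse permutation p-values for the correlations.
#' @slot nullQuantile95,nullQuantile99 quantiles of the permutation null.
#' @slot significant logical: forward test significant at `alpha`.
#' @slot alpha significance level used.
#' @slot groupAssignments per-strain or per-site labels defining the split.
#' @slot thresholds numeric cutoffs used (partial-variants categories).
#' @exportClass HalfMatchReport
setClass("HalfMatchReport",
  representation(
    testName = "character",
    rForward = "numeric",
    rReverse = "numeric",
    pForward = "numeric",
    pReverse = "numeric",
    nullQuantile95 = "numeric",
    nullQuantile99 = "numeric",
    significant = "logical",
    alpha = "numeric",
    groupAssignments = "ANY",
    thresholds = "numeric"
  )
)

#' LDSummary: pairwise R2 matrix with optional block labels
#'
#' @slot r2Matrix symmetric variant x variant R2 matrix (unit diagonal).
#' @slot positions bp coordinate of each variant.
#' @slot blocks integer block label per variant (0 length until clustered).
#' @slot cutoff squared-loading threshold that defined the variant set.
#' @exportClass LDSummary
setClass("LDSummary",
  representation(
    r2Matrix = "matrix",
    positions = "numeric",
    blocks = "integer",
    cutoff = "numeric"
  )
)

setValidity("LDSummary", function(object) {
  if (nrow(object@r2Matrix) != ncol(object@r2Matrix))
    return("r2Matrix must be square")
  TRUE
})
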