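#' @useDynLib ecocline, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif rgamma cor quantile sd
NULL

# A genome is a list(pos = integer (sorted, 0-based), type = integer (1 = m1,
# 2 = m2), deme = integer, label = integer). A population is a list of them.

.emptyGenome <- function(deme = 0L, label = 0L) {
  list(pos = integer(0), type = integer(0), deme = deme, label = label)
}

#' Construct a simulation scenario
#'
#' Builds a [ScenarioSpec-class] with defaults appropriate to the chosen
#' scenario and scale preset. The `"paper"` preset uses full study-scale
#' parameters (1 Mb genomes, populations up to 10,000, 10,000 generations,
#' selection switched on at generation 5,001; 5 Mb for the refined
#' Gamma-effects model). The `"desk"` preset scales the genome to 100 kb,
#' population to 500 and run length to 2,000 generations (selection from
#' 1,001), with HGT tract lengths scaled by the genome-length ratio so that
#' the tract/genome and event/genome ratios that drive the phenomenology
#' are preserved.
#'
#' @param scenario one of `"neutral"`, `"stepping_stone"`, `"hotspot"`,
#'   `"mutation_het"`, `"selective_uniform"`, `"selective_gamma"`.
#' @param preset `"desk"` (default) or `"paper"`.
#' @param seed integer seed for the run.
#' @param ... override any [ScenarioSpec-class] slot by name
#'   (e.g. `hgtTractLength = 10000`, `popSize = 2000`).
#' @return a validated [ScenarioSpec-class].
#' @examples
#' spec <- scenarioSpec("neutral", preset = "desk", seed = 1)
#' spec
#' @export
scenarioSpec <- function(scenario = .SCENARIOS, preset = c("desk", "paper"),
                         seed = 1L, ...) {
  scenario <- match.arg(scenario)
  preset <- match.arg(preset)
  paper <- preset == "paper"
  L <- if (paper) 1e6 else 1e5
  scl <- L / 1e6  # tract-length scaling relative to a 1 Mb genome
  p <- list(
    scenario = scenario,
    genomeLength = L,
    popSize = if (paper) 1e4 else 500,
    nDemes = 1, migrantsPerGen = 0,
    mutationRate = 1e-6,
    hgtEventsPerGen = 1,
    hgtTractLength = 10e3 * scl,
    hotspotPositions = numeric(0), hotspotFraction = 0,
    generations = if (paper) 1e4 else 2000,
    selectionStart = if (paper) 1e4 + 1 else 2001,  # off unless selective
    fitnessAmplitude = 1.0, fitnessExponent = 5, fitnessEpsilon = 1e-6,
    gammaShape = 1, gammaScale = 1,
    baseLambda = 2.0,
    seed = seed
  )
  if (scenario == "stepping_stone") {
    p$nDemes <- 10
    p$popSize <- if (paper) 2000 else 500
    p$migrantsPerGen <- if (paper) 10 else 1
    p$hgtTractLength <- 10e3 * scl
  } else if (scenario == "hotspot") {
    p$hgtTractLength <- 20e3 * scl
    p$hotspotPositions <- c(250e3, 500e3, 750e3) * scl
    p$hotspotFraction <- 0.8
  } else if (scenario == "mutation_het") {
    p$hgtTractLength <- 20e3 * scl
  } else if (scenario == "selective_uniform") {
    p$hgtTractLength <- 20e3 * scl
    p$selectionStart <- if (paper) 5001 else 1001
  } else if (scenario == "selective_gamma") {
    if (paper) {
      # refined model: 5 Mb genome, 5 x 20 kb tracts, Gamma scale 5e6
      p$genomeLength <- 5e6
      p$hgtEventsPerGen <- 5
      p$hgtTractLength <- 20e3
      p$gammaScale <- 5e6
      p$fitnessAmplitude <- 0.5
      p$fitnessExponent <- 10
      p$selectionStart <- 5001
    } else {
      p$hgtTractLength <- 2e3
      p$gammaScale <- 1e4
      p$selectionStart <- 1001
    }
    p$gammaShape <- 1 / p$gammaScale  # mean effect fixed at 1
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown ScenarioSpec fields: ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  selective <- scenario %in% c("selective_uniform", "selective_gamma")
  if (!selective && !"selectionStart" %in% names(ov))
    p$selectionStart <- p$generations + 1  # selection never engages
  do.call(new, c(list(Class = "ScenarioSpec"), p))
}

#' Add de novo mutations to a population
#'
#' Each genome gains a Poisson(`rate * genomeLength`) number of new
#' mutations at uniformly random sites; each new mutation is m1 or m2 with
#' probability 1/2, and a new mutation at an occupied site replaces the
#' resident record (finite-sites convention).
#'
#' @param pop list of genomes.
#' @param rate per-site, per-generation mutation rate (>= 0).
#' @param genomeLength chromosome length in bp.
#' @return the mutated population.
#' @export
mutatePopulation <- function(pop, rate, genomeLength) {
  if (rate < 0) stop("mutation rate must be non-negative")
  if (rate == 0 || length(pop) == 0) return(pop)
  counts <- rpois(length(pop), rate * genomeLength)
  for (i in which(counts > 0L)) {
    g <- pop[[i]]
    np <- as.integer(floor(runif(counts[i]) * genomeLength))
    nt <- ifelse(runif(counts[i]) < 0.5, 1L, 2L)
    pos <- c(g$pos, np)
    type <- c(g$type, nt)
    keep <- !duplicated(pos, fromLast = TRUE)  # later draws replace residents
    pos <- pos[keep]; type <- type[keep]
    o <- order(pos)
    g$pos <- pos[o]; g$type <- type[o]
    pop[[i]] <- g
  }
  pop
}

#' Copy an HGT tract from a donor genome into a recipient
#'
#' The recipient's mutations at positions in the half-open interval
#' `[start, min(start + tract, genomeLength))` are deleted and replaced by
#' the donor's mutations in the same interval; everything outside the tract
#' is untouched. Tracts running off the chromosome end are truncated.
#'
#' @param recipient,donor genomes (lists with `pos`/`type`).
#' @param start 0-based tract start in bp.
#' @param tract tract length in bp.
#' @param genomeLength chromosome length (defaults to `Inf`: no truncation).
#' @return the modified recipient genome.
#' @export
hgtEvent <- function(recipient, donor, start, tract, genomeLength = Inf) {
  if (start < 0 || start >= genomeLength) stop("tract start out of range")
  e <- min(start + tract, genomeLength)
  keepR <- recipient$pos < start | recipient$pos >= e
  takeD <- donor$pos >= start & donor$pos < e
  pos <- c(recipient$pos[keepR], donor$pos[takeD])
  type <- c(recipient$type[keepR], donor$type[takeD])
  o <- order(pos)
  recipient$pos <- pos[o]
  recipient$type <- type[o]
  recipient
}

#' Draw HGT tract start positions
#'
#' With probability `hotspotFraction` a start is a uniformly chosen hotspot
#' coordinate; otherwise it is uniform over `[0, genomeLength)`.
#'
#' @param spec a [ScenarioSpec-class] (its hotspot configuration and genome
#'   length are used).
#' @param n number of draws.
#' @return integer vector of 0-based start positions.
#' @export
sampleHgtStart <- function(spec, n = 1L) {
  frac <- spec@hotspotFraction
  hs <- spec@hotspotPositions
  if (frac > 0 && length(hs) == 0)
    stop("hotspotFraction > 0 but no hotspot positions configured")
  out <- as.numeric(floor(runif(n) * spec@genomeLength))
  if (frac > 0) {
    hot <- runif(n) < frac
    if (any(hot)) out[hot] <- hs[floor(runif(sum(hot)) * length(hs)) + 1]
  }
  out
}

#' Draw HGT donors under the mutation-heterogeneity rule
#'
#' The donor's label group is chosen first (p1 or p2 with probability 1/2
#' each), then a donor is drawn uniformly within that group. This is the
#' 50/50-by-label donor rule of the mutation-rate heterogeneity model.
#'
#' @param labels integer vector of individual labels (two groups).
#' @param n number of donor draws.
#' @return integer vector of donor indices into `labels`.
#' @export
sampleHgtDonors <- function(labels, n = 1L) {
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must contain exactly two groups")
  i1 <- which(labels == lv[1]); i2 <- which(labels == lv[2])
  pick1 <- runif(n) < 0.5
  out <- integer(n)
  out[pick1] <- i1[floor(runif(sum(pick1)) * length(i1)) + 1]
  out[!pick1] <- i2[floor(runif(sum(!pick1)) * length(i2)) + 1]
  out
}

#' Draw a per-site effect table from a Gamma law
#'
#' One Gamma(shape, scale) magnitude per site, covering every site on the
#' chromosome whether or not it is ever mutated. With shape * scale = 1 the
#' mean effect is 1, matching the uniform-effects model's overall selection
#' intensity.
#'
#' @param length genome length in bp (number of coefficients).
#' @param shape,scale positive Gamma parameters.
#' @return numeric vector of non-negative per-site effect magnitudes.
#' @export
drawEffectTable <- function(length, shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  rgamma(length, shape = shape, scale = scale)
}

#' Quantitative trait score of a genome
#'
#' The additive trait is the sum of per-site effect magnitudes over m1
#' mutations minus the sum over m2 mutations. With all-ones effects
#' (`coefficients = NULL`) this is simply the m1 count minus the m2 count.
#'
#' @param genome a genome (list with `pos`/`type`).
#' @param coefficients per-site effect magnitudes (length = genome length),
#'   or `NULL` for uniform effects of 1.
#' @return the trait score.
#' @export
traitScore <- function(genome, coefficients = NULL) {
  if (length(genome$pos) == 0) return(0)
  sgn <- ifelse(genome$type == 1L, 1, -1)
  if (is.null(coefficients)) sum(sgn)
  else sum(sgn * coefficients[genome$pos + 1L])
}

#' Diversifying-selection fitness from trait scores
#'
#' Fitness is a normalised power function of the deviation from the mean
#' score: with `d_i = |score_i - mean(score)|^exponent`,
#' `fitness_i = 2 + amplitude * d_i / (max(d) + epsilon)`. All values lie
#' in `[2, 2 + amplitude)`; when every score is equal, every fitness is
#' exactly 2.
#'
#' @param scores numeric vector of trait scores (non-empty).
#' @param amplitude fitness amplitude (1.0 for the base selective model,
#'   0.5 for the refined model).
#' @param exponent power-law exponent (5 or 10).
#' @param epsilon denominator regulariser.
#' @return numeric vector of per-individual fitness values.
#' @export
fitnessVector <- function(scores, amplitude = 1.0, exponent = 5,
                          epsilon = 1e-6) {
  if (length(scores) == 0) stop("scores must be non-empty")
  d <- abs(scores - mean(scores))^exponent
  2.0 + amplitude * d / (max(d) + epsilon)
}

#' Poisson reproduction with hard capacity regulation
#'
#' Each parent produces a Poisson(`lambdas[i]`) number of clonal offspring.
#' If the total exceeds `capacity`, a uniformly random subset of exactly
#' `capacity` offspring survives; otherwise all survive. Zero total
#' offspring is an extinction error.
#'
#' @param pop list of parent genomes.
#' @param lambdas per-parent offspring means (length = population size).
#' @param capacity carrying capacity (> 0).
#' @return list with `population` (the surviving offspring) and
#'   `offspringPerParent` (pre-regulation Poisson counts).
#' @export
reproduceAndRegulate <- function(pop, lambdas, capacity) {
  if (length(lambdas) != length(pop))
    stop("lambdas must have one entry per parent")
  if (capacity <= 0) stop("capacity must be positive")
  counts <- rpois(length(pop), lambdas)
  total <- sum(counts)
  if (total == 0)
    stop("population went extinct: zero offspring produced in this generation")
  offspring <- pop[rep(seq_along(pop), counts)]
  if (total > capacity)
    offspring <- offspring[sort(sample.int(total, capacity))]
  list(population = offspring, offspringPerParent = counts)
}

#' Linear stepping-stone migration
#'
#' Each deme sends `migrants` uniformly chosen individuals to each adjacent
#' deme on the line (end demes have one neighbour, interior demes two);
#' emigrants are chosen from the pre-migration membership so the exchange
#' is simultaneous and the total individual count is conserved.
#'
#' @param demes list of demes, each a list of genomes, ordered on a line.
#' @param migrants individuals sent to each neighbour per generation.
#' @return list of demes after the exchange.
#' @export
migrateSteppingStone <- function(demes, migrants) {
  nd <- length(demes)
  if (migrants == 0 || nd < 2) return(demes)
  moves <- vector("list", nd)  # per-deme: indices leaving, and destination
  for (d in seq_len(nd)) {
    nb <- c(if (d > 1) d - 1L, if (d < nd) d + 1L)
    need <- migrants * length(nb)
    if (need > length(demes[[d]]))
      stop("migrants exceed deme size in deme ", d)
    sel <- sample.int(length(demes[[d]]), need)
    moves[[d]] <- list(idx = sel, dest = rep(nb, each = migrants))
  }
  out <- vector("list", nd)
  for (d in seq_len(nd)) out[[d]] <- demes[[d]][-moves[[d]]$idx]
  for (d in seq_len(nd)) {
    mv <- moves[[d]]
    for (k in seq_along(mv$idx)) {
      dest <- mv$dest[k]
      out[[dest]] <- c(out[[dest]], demes[[d]][mv$idx[k]])
    }
  }
  out
}

#' Run one forward-time scenario
#'
#' Orchestrates, per generation: de novo mutation (disabled for p1-labelled
#' individuals in the mutation-heterogeneity model), HGT tract copying
#' (every individual receives `hgtEventsPerGen` tracts from donors drawn
#' from a start-of-stage snapshot, within its deme for the stepping-stone
#' model and 50/50 by label in the mutation-heterogeneity model), linear
#' stepping-stone migration, and Poisson reproduction with hard per-deme
#' capacity regulation. During the selection phase of the selective
#' scenarios, the Poisson offspring mean is the diversifying-selection
#' fitness (see [fitnessVector()]); otherwise it is `baseLambda`. The
#' generation loop runs in compiled code; an identical seed reproduces the
#' run bit-for-bit.
#'
#' @param spec a [ScenarioSpec-class].
#' @return a [SimOutput-class].
#' @examples
#' out <- runScenario(scenarioSpec("neutral", seed = 1, popSize = 50,
#'                                 genomeLength = 2e4, generations = 50,
#'                                 hgtTractLength = 500))
#' out
#' @export
runScenario <- function(spec) {
  stopifnot(is(spec, "ScenarioSpec"))
  validObject(spec)
  set.seed(spec@seed)
  coefficients <- numeric(0)
  if (spec@scenario == "selective_gamma")
    coefficients <- drawEffectTable(spec@genomeLength, spec@gammaShape,
                                    spec@gammaScale)
  selectionOn <- spec@scenario %in% c("selective_uniform", "selective_gamma")
  res <- sim_engine(
    genome_length = as.integer(spec@genomeLength),
    pop_size = as.integer(spec@popSize),
    n_demes = as.integer(spec@nDemes),
    migrants = as.integer(spec@migrantsPerGen),
    mutation_rate = spec@mutationRate,
    hgt_events = as.integer(spec@hgtEventsPerGen),
    tract_length = as.integer(spec@hgtTractLength),
    hotspots = as.integer(spec@hotspotPositions),
    hotspot_fraction = spec@hotspotFraction,
    generations = as.integer(spec@generations),
    selection_start = as.integer(spec@selectionStart),
    selection_on = selectionOn,
    amplitude = spec@fitnessAmplitude,
    exponent = spec@fitnessExponent,
    epsilon = spec@fitnessEpsilon,
    base_lambda = spec@baseLambda,
    coefficients = coefficients,
    mut_het = spec@scenario == "mutation_het"
  )
  pop <- Map(function(p, t, d, l) list(pos = p, type = t, deme = d, label = l),
             res$positions, res$types, as.list(res$deme), as.list(res$label))
  names(pop) <- NULL
  new("SimOutput", population = pop, traitValues = res$trait,
      effectTable = coefficients, generationLog = res$log, spec = spec)
}

# ---- accessors / show ----

#' @rdname accessors
#' @aliases traitValues,SimOutput-method
setMethod("traitValues", "SimOutput", function(x) x@traitValues)

#' @rdname accessors
#' @aliases generationLog,SimOutput-method
setMethod("generationLog", "SimOutput", function(x) x@generationLog)

#' @rdname accessors
#' @aliases scenario,ScenarioSpec-method
setMethod("scenario", "ScenarioSpec", function(x) x@scenario)

#' @rdname accessors
#' @aliases scenario,SimOutput-method
setMethod("scenario", "SimOutput", function(x) x@spec@scenario)

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec:", object@scenario, "\n")
  cat(sprintf("  genome %g bp | N = %g in %g deme(s) | %g generations\n",
              object@genomeLength, object@popSize, object@nDemes,
              object@generations))
  cat(sprintf("  mu = %g /site/gen | HGT %g x %g bp tract(s)/ind/gen\n",
              object@mutationRate, object@hgtEventsPerGen,
              object@hgtTractLength))
  if (object@scenario %in% c("selective_uniform", "selective_gamma"))
    cat(sprintf("  selection from generation %g (amplitude %g, exponent %g)\n",
                object@selectionStart, object@fitnessAmplitude,
                object@fitnessExponent))
  if (object@scenario == "selective_gamma")
    cat(sprintf("  Gamma effects: shape %g, scale %g\n",
                object@gammaShape, object@gammaScale))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "SimOutput", function(object) {
  nmut <- vapply(object@population, function(g) length(g$pos), 1L)
  cat(sprintf("SimOutput: %d individuals (%s scenario)\n",
              length(object@population), object@spec@scenario))
  cat(sprintf("  mutations per genome: mean %.1f (range %d-%d)\n",
              mean(nmut), min(nmut), max(nmut)))
  cat(sprintf("  trait: mean %.3f, sd %.3f\n",
              mean(object@traitValues), sd(object@traitValues)))
})
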