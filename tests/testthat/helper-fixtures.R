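# Fixtures built in code: toy genomes, random populations and matrices.

makeGenome <- function(pos = integer(0), type = integer(0),
                       deme = 0L, label = 0L) {
  o <- order(pos)
  list(pos = as.integer(pos[o]), type = as.integer(type[o]),
       deme = deme, label = label)
}

# random population with mutations sprinkled at uniform sites
randomPopulation <- function(n, genomeLength, meanMutations = 20) {
  lapply(seq_len(n), function(i) {
    k <- rpois(1, meanMutations)
    pos <- sample.int(genomeLength, min(k, genomeLength)) - 1L
    makeGenome(pos, sample(1:2, length(pos), replace = TRUE))
  })
}

# random binary SNPMatrix via a population encode (guarantees invariants)
randomSNPMatrix <- function(n, genomeLength, meanMutations = 20) {
  encodeBinary(randomPopulation(n, genomeLength, meanMutations))
}

# small deterministic scenario that runs in well under a second
tinySpec <- function(scenario = "neutral", seed = 1, ...) {
  scenarioSpec(scenario, preset = "desk", seed = seed, popSize = 60,
               genomeLength = 2e4, generations = 150,
               hgtTractLength = 500, ...)
}

# brute-force R2 from the frequency definition (independent of r2Pair)
bruteR2 <- function(x, y) {
  fi <- mean(x); fj <- mean(y); fij <- mean(x == 1 & y == 1)
  (fij - fi * fj)^2 / (fi * (1 - fi) * fj * (1 - fj))
}
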