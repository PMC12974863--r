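# End-to-end scenario pipelines: simulate -> encode -> filter -> PCA and
# loadings -> half-matching trio -> LD decay -> NJ tree and backbone score,
# collapsed into one machine-readable report per run.

#' Run a full scenario pipeline
#'
#' Simulates one scenario, encodes the binary matrix, applies the MAF
#' filter (2% by default; LD pruning is off by default because simulated
#' matrices are analysed unpruned), and runs the requested diagnostics.
#' Window and distance parameters for the diagnostics are scaled by the
#' genome-length ratio to a 1 Mb chromosome, so desk-scale runs use the
#' same relative geometry as full-scale ones. The report is deterministic
#' given the spec (the spec's seed drives every stochastic stage,
#' including the permutation nulls).
#'
#' @param spec a [ScenarioSpec-class].
#' @param outDir optional directory for the tabular artifacts and a JSON
#'   report.
#' @param diagnostics subset of `c("pca", "halfmatch", "ld", "tree")`.
#' @param maf minor-allele frequency cutoff.
#' @param prune apply windowed LD pruning before the PCA.
#' @param nonRedundant collapse clonal relatives before the diagnostics
#'   with the greedy pairwise-distance rule (see [nonredundantSelect()]).
#' @param minDist SNP-distance threshold for the non-redundant selection;
#'   the default is half the mean pairwise Hamming distance of the run,
#'   which reproduces the study's 2 kb threshold at its own simulation
#'   parameters (equilibrium diversity `2 N mu L = 4 kb`, threshold 2 kb).
#' @param nPerm permutation replicates in the half-matching nulls.
#' @param alpha significance level for the half-matching trio.
#' @return a list report: PVE of PC1, the half-matching `|r|` trio with
#'   significance calls, the backbone score, the PC1-trait correlation and
#'   the excess kurtosis of the PC1 variant loadings.
#' @export
runPipeline <- function(spec, outDir = NULL,
                        diagnostics = c("pca", "halfmatch", "ld", "tree"),
                        maf = 0.02, prune = FALSE, nonRedundant = TRUE,
                        minDist = NULL, nPerm = 200, alpha = 0.01) {
  diagnostics <- match.arg(diagnostics, several.ok = TRUE)
  scl <- spec@genomeLength / 1e6
  window <- 50e3 * scl
  sim <- runScenario(spec)
  mFull <- encodeBinary(sim)   # full population, written out as-is
  mAll <- mFull
  traits <- sim@traitValues
  if (nonRedundant) {
    if (is.null(minDist)) {
      D <- pairwiseDistance(mAll)
      minDist <- mean(D[upper.tri(D)]) / 2
    }
    kept <- match(nonredundantSelect(mAll, minDist), mAll@strainIds)
    traits <- traits[kept]
    # re-encode the subset so minor coding and frequencies are recomputed
    mAll <- encodeBinary(sim@population[kept],
                         strainIds = mAll@strainIds[kept])
  }
  m <- mafFilter(mAll, maf)
  if (prune) m <- ldPrune(m, window = window)
  report <- list(
    scenario = spec@scenario,
    seed = spec@seed,
    nStrains = nrow(m@values),
    nSitesPolymorphic = ncol(mAll@values),
    nSitesMaf = ncol(m@values)
  )
  pca <- NULL
  if (any(c("pca", "halfmatch") %in% diagnostics)) {
    pca <- runPCA(m, k = min(10, nrow(m@values) - 1, ncol(m@values)))
    vl <- variantLoadings(pca, m)
    report$pve1 <- pca@pve[1]
    report$pc1TraitAbsR <- abs(cor(pca@strainLoadings[, 1], traits))
    report$loadingKurtosis <- excessKurtosis(vl[, 1])
    report$topLoadingPosition <- m@positions[which.max(vl[, 1]^2)]
    if (length(sim@effectTable)) {
      # site with the largest realised effect among the analysed sites
      eff <- sim@effectTable[m@positions + 1]
      report$maxEffectPosition <- m@positions[which.max(eff)]
    }
  }
  if ("halfmatch" %in% diagnostics) {
    hs <- halfStrainTest(m, nPerm = nPerm, alpha = alpha)
    hg <- halfGenomeTest(m, split = spec@genomeLength / 2,
                         nPerm = nPerm, alpha = alpha)
    pv <- tryCatch(
      partialVariantsTest(m, squaredLoadings = variantLoadings(pca, m)[, 1]^2,
                          window = window, nPerm = nPerm, alpha = alpha),
      error = function(e) NULL)
    report$halfStrain <- list(r = hs@rForward, rReverse = hs@rReverse,
                              p = hs@pForward,
                              significant = hs@significant)
    report$halfGenome <- list(r = hg@rForward, p = hg@pForward,
                              significant = hg@significant)
    report$partialVariants <- if (is.null(pv)) {
      list(r = NA_real_, p = NA_real_, significant = FALSE,
           degenerate = TRUE)
    } else {
      list(r = pv@rForward, p = pv@pForward, significant = pv@significant,
           degenerate = FALSE)
    }
    report$nSignificant <- sum(report$halfStrain$significant,
                               report$halfGenome$significant,
                               report$partialVariants$significant)
  }
  if ("ld" %in% diagnostics) {
    decay <- ldDecay(m, maxDist = 30e3 * scl, binSize = max(1, 10 * scl))
    report$ldDecayMeanR2 <- if (nrow(decay)) {
      sum(decay$mean_r2 * decay$n_pairs) / sum(decay$n_pairs)
    } else NA_real_
  }
  if ("tree" %in% diagnostics) {
    tree <- njTree(pairwiseDistance(mAll))
    report$backboneScore <- backboneScore(tree)
  }
  if (!is.null(outDir)) {
    writeSimOutput(sim, mFull, outDir)
    if (!is.null(pca)) {
      scores <- data.frame(id = pca@strainIds, pca@strainLoadings)
      write.table(scores, file.path(outDir, "strain_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      lds <- data.frame(position = m@positions, loading = vl[, 1],
                        squared = vl[, 1]^2, abs = abs(vl[, 1]))
      write.table(lds, file.path(outDir, "variant_loadings.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("ld" %in% diagnostics)
      write.table(decay, file.path(outDir, "ld_decay.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if ("tree" %in% diagnostics)
      ape::write.tree(tree, file.path(outDir, "nj_tree.nwk"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Tabulate reports from several runs
#'
#' @param reports list of reports from [runPipeline()].
#' @return a data.frame with one row per run: scenario, seed, PVE of PC1,
#'   backbone score, the half-matching `|r|` trio and significance count,
#'   PC1-trait correlation and loading kurtosis.
#' @export
compareRuns <- function(reports) {
  if (length(reports) < 1) stop("need at least one report")
  grab <- function(r, field, sub = NULL) {
    v <- if (is.null(sub)) r[[field]] else r[[field]][[sub]]
    if (is.null(v)) NA else v
  }
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      scenario = r$scenario,
      seed = r$seed,
      pve1 = grab(r, "pve1"),
      backbone = grab(r, "backboneScore"),
      r_half_strain = grab(r, "halfStrain", "r"),
      r_half_genome = grab(r, "halfGenome", "r"),
      r_partial_variants = grab(r, "partialVariants", "r"),
      n_significant = grab(r, "nSignificant"),
      pc1_trait_r = grab(r, "pc1TraitAbsR"),
      loading_kurtosis = grab(r, "loadingKurtosis")
    )
  }))
}
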