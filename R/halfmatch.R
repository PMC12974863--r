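# Three reproducibility tests for PC1: half-strain matching (cross-group
# projection), half-genome matching (independent PCA on two chromosome
# fragments) and partial-variants matching (independent PCA on low- and
# high-loading variant sets). Significance is operationalised by a
# strain-label permutation null.

.absCor <- function(x, y) abs(stats::cor(as.numeric(x), as.numeric(y)))

# permutation null for |cor(x, y)| under random re-pairing of strains
.permTest <- function(x, y, nPerm, alpha) {
  obs <- .absCor(x, y)
  null <- vapply(seq_len(nPerm),
                 function(i) .absCor(x, sample(y)), numeric(1))
  p <- (1 + sum(null >= obs)) / (nPerm + 1)
  list(r = obs, p = p,
       q95 = as.numeric(quantile(null, 0.95)),
       q99 = as.numeric(quantile(null, 0.99)),
       significant = p <= alpha)
}

.subPCA <- function(m, prune = FALSE, window = 50e3, r2max = 0.1) {
  m <- dropMonomorphicSites(m)
  if (ncol(m@values) < 2)
    stop("degenerate group: fewer than 2 polymorphic sites")
  if (prune) m <- ldPrune(m, window = window, r2max = r2max)
  runPCA(m, k = 1)
}

#' Half-strain matching test
#'
#' Strains are split into two groups (by default on the sign of their PC1
#' score in a preliminary full-data PCA, standing in for a split along the
#' phylogenetic backbone; an explicit partition can be supplied). PCA is
#' run on group 1, per-variant loadings over all MAF sites are computed,
#' and group 2 is projected onto them; `rForward` is the absolute Pearson
#' correlation between group 2's projected PC1 and its own PC1. The
#' symmetric analysis (group 2 defines, group 1 is projected) gives
#' `rReverse`.
#'
#' @param m a MAF-filtered [SNPMatrix-class].
#' @param partition logical/integer per-strain labels defining the two
#'   groups, or `NULL` for the automatic PC1-sign split.
#' @param prune prune sites within each group before its PCA.
#' @param window pruning window (bp).
#' @param nPerm permutation replicates for the null.
#' @param alpha significance level.
#' @return a [HalfMatchReport-class].
#' @export
halfStrainTest <- function(m, partition = NULL, prune = FALSE,
                           window = 50e3, nPerm = 200, alpha = 0.01) {
  n <- nrow(m@values)
  if (is.null(partition)) {
    full <- runPCA(dropMonomorphicSites(m), k = 1)
    partition <- full@strainLoadings[, 1] >= 0
  }
  partition <- as.logical(partition)
  if (length(partition) != n) stop("partition must label every strain")
  if (sum(partition) < 3 || sum(!partition) < 3)
    stop("each group needs at least 3 strains")
  oneWay <- function(defIdx, projIdx) {
    mDef <- m[defIdx, ]
    mProj <- m[projIdx, ]
    pcaDef <- .subPCA(mDef, prune = prune, window = window)
    # loadings over ALL MAF sites of the defining group
    vl <- variantLoadings(pcaDef, mDef)
    proj <- projectStrains(mProj, vl)[, 1]
    own <- .subPCA(mProj, prune = prune, window = window)@strainLoadings[, 1]
    .permTest(proj, own, nPerm, alpha)
  }
  fwd <- oneWay(which(partition), which(!partition))
  rev <- oneWay(which(!partition), which(partition))
  new("HalfMatchReport", testName = "half_strain",
      rForward = fwd$r, rReverse = rev$r,
      pForward = fwd$p, pReverse = rev$p,
      nullQuantile95 = fwd$q95, nullQuantile99 = fwd$q99,
      significant = fwd$significant && rev$significant, alpha = alpha,
      groupAssignments = partition, thresholds = numeric(0))
}

#' Half-genome matching test
#'
#' The chromosome is split at `split` bp; independent PCAs are run on the
#' sites of each fragment (optionally pruned) and the absolute Pearson
#' correlation between the two PC1 strain-score vectors is reported.
#'
#' @param m a MAF-filtered [SNPMatrix-class].
#' @param split fragment boundary in bp (sites with position < `split` form
#'   fragment 1).
#' @inheritParams halfStrainTest
#' @return a [HalfMatchReport-class].
#' @export
halfGenomeTest <- function(m, split, prune = FALSE, window = 50e3,
                           nPerm = 200, alpha = 0.01) {
  frag1 <- m@positions < split
  if (sum(frag1) < 2 || sum(!frag1) < 2)
    stop("both fragments need at least 2 polymorphic sites")
  pc1 <- .subPCA(m[, frag1], prune = prune, window = window)
  pc2 <- .subPCA(m[, !frag1], prune = prune, window = window)
  res <- .permTest(pc1@strainLoadings[, 1], pc2@strainLoadings[, 1],
                   nPerm, alpha)
  new("HalfMatchReport", testName = "half_genome",
      rForward = res$r, rReverse = NA_real_,
      pForward = res$p, pReverse = NA_real_,
      nullQuantile95 = res$q95, nullQuantile99 = res$q99,
      significant = res$significant, alpha = alpha,
      groupAssignments = ifelse(frag1, 1L, 2L), thresholds = split)
}

#' Windowed maximum of squared loadings
#'
#' Assigns to every site the maximum squared PC1 loading found within
#' `window / 2` bp on either side (the 50 kb vicinity rule used to
#' categorise variants before partial-variants matching).
#'
#' @param squaredLoadings per-site squared PC1 loadings.
#' @param positions sorted site positions (bp).
#' @param window window size in bp.
#' @return numeric vector: per-site windowed maxima.
#' @export
windowMaxLoading <- function(squaredLoadings, positions, window = 50e3) {
  if (length(squaredLoadings) != length(positions))
    stop("squaredLoadings and positions must have equal length")
  if (is.unsorted(positions)) stop("positions must be sorted")
  h <- window / 2
  lo <- findInterval(positions - h, positions, left.open = TRUE) + 1L
  hi <- findInterval(positions + h, positions)
  vapply(seq_along(positions),
         function(i) max(squaredLoadings[lo[i]:hi[i]]), numeric(1))
}

#' Partial-variants matching test
#'
#' Sites are categorised from the windowed-maximum squared PC1 loading
#' distribution: the lower `lowQ` quantile forms the low-loading set, the
#' upper tail above the `highQ` quantile the high-loading set, and
#' intermediate sites are ignored. Independent PCAs on the two sets give
#' two PC1 estimates whose absolute correlation is reported.
#'
#' @param m a MAF-filtered [SNPMatrix-class].
#' @param squaredLoadings per-site squared PC1 loadings over the sites of
#'   `m`, or `NULL` to compute them from a full PCA of `m`.
#' @param lowQ quantile bounding the low-loading category (default: lower
#'   tertile).
#' @param highQ quantile opening the high-loading category (default: upper
#'   decile).
#' @param window vicinity size for [windowMaxLoading()] (bp).
#' @inheritParams halfStrainTest
#' @return a [HalfMatchReport-class].
#' @export
partialVariantsTest <- function(m, squaredLoadings = NULL, lowQ = 1 / 3,
                                highQ = 0.9, window = 50e3, prune = FALSE,
                                nPerm = 200, alpha = 0.01) {
  if (is.null(squaredLoadings)) {
    full <- runPCA(dropMonomorphicSites(m), k = 1)
    squaredLoadings <- variantLoadings(full, m)[, 1]^2
  }
  wml <- windowMaxLoading(squaredLoadings, m@positions, window)
  cutLow <- as.numeric(quantile(wml, lowQ))
  cutHigh <- as.numeric(quantile(wml, highQ))
  if (cutLow >= cutHigh)
    stop("loading distribution has no low/high separation; ",
         "categorisation is degenerate")
  lowSet <- wml <= cutLow
  highSet <- wml >= cutHigh
  if (sum(lowSet) < 2 || sum(highSet) < 2)
    stop("both extreme categories need at least 2 sites")
  pcLow <- .subPCA(m[, lowSet], prune = prune, window = window)
  pcHigh <- .subPCA(m[, highSet], prune = prune, window = window)
  res <- .permTest(pcHigh@strainLoadings[, 1], pcLow@strainLoadings[, 1],
                   nPerm, alpha)
  cat3 <- ifelse(highSet, "high", ifelse(lowSet, "low", "medium"))
  new("HalfMatchReport", testName = "partial_variants",
      rForward = res$r, rReverse = NA_real_,
      pForward = res$p, pReverse = NA_real_,
      nullQuantile95 = res$q95, nullQuantile99 = res$q99,
      significant = res$significant, alpha = alpha,
      groupAssignments = cat3, thresholds = c(low = cutLow, high = cutHigh))
}

setMethod("show", "HalfMatchReport", function(object) {
  cat(sprintf("HalfMatchReport (%s): |r| = %.3f (p = %.3f)%s\n",
              object@testName, object@rForward, object@pForward,
              if (!is.na(object@rReverse))
                sprintf("; reverse |r| = %.3f (p = %.3f)",
                        object@rReverse, object@pReverse) else ""))
  cat(sprintf("  permutation null 95%%/99%%: %.3f / %.3f | %s at alpha = %g\n",
              object@nullQuantile95, object@nullQuantile99,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})
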