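# Pairwise linkage disequilibrium: the frequency-based R2, distance-binned
# decay curves, the full R2 matrix among high-loading variants, and
# hierarchical block clustering of that matrix.

#' Pairwise R2 between two binary variant columns
#'
#' `R2 = (f_ij - f_i f_j)^2 / (f_i (1 - f_i) f_j (1 - f_j))`, where `f_i`
#' and `f_j` are the frequencies of allele 1 at the two sites and `f_ij`
#' the frequency of joint presence. Algebraically this equals the squared
#' Pearson correlation of the two columns and is invariant to swapping the
#' 0/1 coding of either column.
#'
#' @param x,y binary vectors over the same strains.
#' @return the R2 value, or `NA` (with a warning) if either column is
#'   monomorphic, for which LD is undefined.
#' @export
r2Pair <- function(x, y) {
  fi <- mean(x); fj <- mean(y)
  if (fi == 0 || fi == 1 || fj == 0 || fj == 1) {
    warning("monomorphic column: R2 undefined, not computed")
    return(NA_real_)
  }
  fij <- mean(x == 1 & y == 1)
  (fij - fi * fj)^2 / (fi * (1 - fi) * fj * (1 - fj))
}

# full R2 matrix among a set of columns via cross-products
.r2Matrix <- function(X) {
  n <- nrow(X)
  p <- colMeans(X)
  C <- crossprod(X) / n               # joint presence frequencies
  num <- (C - outer(p, p))^2
  den <- outer(p * (1 - p), p * (1 - p))
  R2 <- num / den
  R2[den == 0] <- NA_real_
  diag(R2)[!is.na(diag(R2))] <- 1
  R2
}

#' Distance-binned LD decay curve
#'
#' All site pairs separated by at most `maxDist` bp contribute their R2 to
#' the bin of their distance; the curve reports the mean R2 per `binSize`
#' bp distance bin (the study used a 30 kb maximum distance and a 10 bp
#' step). No MAF or equilibrium filtering is applied inside the
#' computation.
#'
#' @param m a [SNPMatrix-class].
#' @param maxDist maximum pair distance in bp.
#' @param binSize distance bin width in bp.
#' @return a data.frame with `bin_bp` (bin midpoint), `mean_r2` and
#'   `n_pairs`.
#' @export
ldDecay <- function(m, maxDist = 30e3, binSize = 10) {
  if (maxDist <= 0) stop("maxDist must be positive")
  pos <- m@positions
  S <- length(pos)
  sums <- numeric(0); cnts <- numeric(0)
  addPairs <- function(d, r2, sums, cnts) {
    ok <- !is.na(r2) & d > 0 & d <= maxDist
    if (!any(ok)) return(list(sums = sums, cnts = cnts))
    b <- ceiling(d[ok] / binSize)
    mx <- max(b)
    if (mx > length(sums)) {
      sums <- c(sums, numeric(mx - length(sums)))
      cnts <- c(cnts, numeric(mx - length(cnts)))
    }
    add <- rowsum(r2[ok], b)
    ub <- as.integer(rownames(add))
    sums[ub] <- sums[ub] + add[, 1]
    cnts[seq_len(mx)] <- cnts[seq_len(mx)] + tabulate(b, nbins = mx)
    list(sums = sums, cnts = cnts)
  }
  chunk <- 512L
  i0 <- 1L
  while (i0 <= S) {
    i1 <- min(i0 + chunk - 1L, S)
    jmax <- findInterval(pos[i1] + maxDist, pos)
    jr <- i0:jmax
    R2 <- .r2Matrix2(m@values[, i0:i1, drop = FALSE],
                     m@values[, jr, drop = FALSE])
    D <- outer(pos[i0:i1], pos[jr], function(a, b) b - a)
    upper <- outer(i0:i1, jr, "<")    # each unordered pair once
    acc <- addPairs(D[upper], R2[upper], sums, cnts)
    sums <- acc$sums; cnts <- acc$cnts
    i0 <- i1 + 1L
  }
  keep <- which(cnts > 0)
  data.frame(bin_bp = (keep - 0.5) * binSize,
             mean_r2 = sums[keep] / cnts[keep],
             n_pairs = cnts[keep])
}

# rectangular R2 between two column blocks
.r2Matrix2 <- function(X, Y) {
  n <- nrow(X)
  px <- colMeans(X); py <- colMeans(Y)
  C <- crossprod(X, Y) / n
  num <- (C - outer(px, py))^2
  den <- outer(px * (1 - px), py * (1 - py))
  R2 <- num / den
  R2[den == 0] <- NA_real_
  R2
}

#' LD matrix among high-loading variants
#'
#' Computes the full pairwise R2 matrix among the variants whose squared
#' PC1 loading exceeds `cutoff` (the study's default threshold is 300).
#' No distance cap is applied: high-loading blocks are compared across the
#' whole genome.
#'
#' @param m a [SNPMatrix-class].
#' @param squaredLoadings per-site squared PC1 loadings for the sites of
#'   `m`.
#' @param cutoff squared-loading threshold.
#' @return an [LDSummary-class] (blocks unassigned; see [clusterBlocks()]).
#' @export
highLoadingLD <- function(m, squaredLoadings, cutoff = 300) {
  if (length(squaredLoadings) != ncol(m@values))
    stop("squaredLoadings must have one value per site")
  idx <- which(squaredLoadings > cutoff)
  if (length(idx) < 2)
    stop("fewer than 2 variants exceed the squared-loading cutoff")
  R2 <- .r2Matrix(m@values[, idx, drop = FALSE])
  dimnames(R2) <- list(as.character(m@positions[idx]),
                       as.character(m@positions[idx]))
  new("LDSummary", r2Matrix = R2, positions = m@positions[idx],
      blocks = integer(0), cutoff = cutoff)
}

#' Hierarchical LD block clustering
#'
#' Agglomerative clustering (complete linkage) on the distance `1 - R2`,
#' with the tree cut into `nBlocks` groups. Complete linkage keeps blocks
#' tight, matching the visually crisp blocks of LD heatmaps. Labels are
#' ordered by descending within-block mean loading when loadings are
#' supplied, otherwise by descending block size.
#'
#' @param ld an [LDSummary-class] or a square R2 matrix.
#' @param nBlocks number of blocks to cut the dendrogram into.
#' @param loadings optional per-variant loadings used to order the block
#'   labels.
#' @return for an [LDSummary-class] input, the summary with `blocks`
#'   filled in; for a matrix input, the integer label vector.
#' @export
clusterBlocks <- function(ld, nBlocks, loadings = NULL) {
  R2 <- if (is(ld, "LDSummary")) ld@r2Matrix else ld
  nv <- nrow(R2)
  if (nBlocks > nv) stop("nBlocks exceeds the number of variants")
  if (nBlocks == 1) {
    labels <- rep(1L, nv)
  } else {
    R2f <- R2
    R2f[is.na(R2f)] <- 0
    hc <- hclust(as.dist(1 - R2f), method = "complete")
    raw <- cutree(hc, k = nBlocks)
    key <- if (!is.null(loadings)) {
      -vapply(seq_len(nBlocks), function(b) mean(loadings[raw == b]),
              numeric(1))
    } else {
      -tabulate(raw, nbins = nBlocks)
    }
    relabel <- integer(nBlocks)
    relabel[order(key)] <- seq_len(nBlocks)
    labels <- relabel[raw]
  }
  if (is(ld, "LDSummary")) {
    ld@blocks <- as.integer(labels)
    ld
  } else {
    as.integer(labels)
  }
}

setMethod("show", "LDSummary", function(object) {
  cat(sprintf("LDSummary: %d variants (squared-loading cutoff %g)\n",
              nrow(object@r2Matrix), object@cutoff))
  if (length(object@blocks))
    cat(sprintf("  %d blocks assigned\n", max(object@blocks)))
})
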