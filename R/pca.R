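# PCA on the binary matrix: strain loadings (eigenvectors scaled by the
# square root of the eigenvalues), per-variant loadings obtained by
# multiplying the binary MAF-filtered matrix with the strain loadings, and
# cross-group projection.

#' Principal component analysis of a SNP matrix
#'
#' Columns are mean-centred (optionally variance-standardised) and the
#' strain-by-strain covariance is eigen-decomposed via SVD. Strain loadings
#' are the strain-space eigenvectors scaled by the square root of the
#' eigenvalues (the standard loading definition); scaling by the raw
#' eigenvalues is available for exact-replication attempts. The proportion
#' of variance explained is computed from the full eigenvalue spectrum.
#'
#' @param m a [SNPMatrix-class] (typically MAF-filtered, and LD-pruned for
#'   real data).
#' @param k number of components to retain (default: up to 20).
#' @param standardize `"center"` (default) or `"plink"`
#'   (divide each centred column by `sqrt(p(1-p))`).
#' @param loadingScale `"sqrt"` (default) or `"eigenvalue"`.
#' @return a [PCAResult-class].
#' @export
runPCA <- function(m, k = 20, standardize = c("center", "plink"),
                   loadingScale = c("sqrt", "eigenvalue")) {
  standardize <- match.arg(standardize)
  loadingScale <- match.arg(loadingScale)
  X <- m@values
  n <- nrow(X); S <- ncol(X)
  if (n < 2 || S < 1) stop("PCA needs >= 2 strains and >= 1 site")
  kmax <- min(n - 1, S)
  if (k > kmax) {
    if (k != 20) stop("k exceeds min(strains - 1, sites)")
    k <- kmax
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (standardize == "plink") {
    sdc <- sqrt(ctr * (1 - ctr))
    sdc[sdc == 0] <- 1
    Xc <- sweep(Xc, 2, sdc, "/")
  }
  if (all(abs(Xc) < .Machine$double.eps * 10))
    stop("matrix is constant: no variation to decompose")
  sv <- svd(Xc, nu = kmax, nv = 0)
  eig <- sv$d^2 / (n - 1)
  if (eig[1] <= 0) stop("matrix is constant: no variation to decompose")
  pveAll <- eig / sum(eig)
  scl <- if (loadingScale == "sqrt") sqrt(eig[seq_len(k)]) else eig[seq_len(k)]
  L <- sv$u[, seq_len(k), drop = FALSE] %*% diag(scl, nrow = k)
  colnames(L) <- paste0("PC", seq_len(k))
  rownames(L) <- m@strainIds
  new("PCAResult", eigenvalues = eig[seq_len(k)], pve = pveAll[seq_len(k)],
      strainLoadings = L, strainIds = m@strainIds,
      loadingScale = loadingScale, standardize = standardize)
}

#' Per-variant loadings from strain loadings
#'
#' The loading of a site on a component is the product of the binary site
#' column with the strain-loading column, i.e. the matrix product of the
#' transposed MAF-filtered binary matrix and the strain loadings. The MAF
#' matrix may (and for the study's design should) contain sites that were
#' pruned away before the PCA itself; one loading row is produced per MAF
#' site.
#'
#' @param res a [PCAResult-class].
#' @param mafMatrix the MAF-filtered (not pruned) [SNPMatrix-class] over
#'   the same strains, in the same strain order.
#' @return a sites x k matrix of loadings; row names are site positions.
#'   Square or take absolute values for the direction-independent
#'   per-variant summaries.
#' @export
variantLoadings <- function(res, mafMatrix) {
  if (!identical(res@strainIds, mafMatrix@strainIds))
    stop("mafMatrix strains must match the PCA strains (same order)")
  L <- crossprod(mafMatrix@values, res@strainLoadings)
  rownames(L) <- as.character(mafMatrix@positions)
  colnames(L) <- colnames(res@strainLoadings)
  L
}

#' Project strains onto existing variant loadings
#'
#' Maps a second group of strains onto the component space defined by a
#' first group: each projected score is the product of the strain's binary
#' row with the loading vector, restricted to the sites shared between the
#' matrix and the loading table (inner join on position). The scale of the
#' projection is unconstrained; it is intended for correlation.
#'
#' @param m2 a [SNPMatrix-class] for the strains to project.
#' @param loadings a sites x k loading matrix from [variantLoadings()]
#'   (row names are positions).
#' @return a strains x k matrix of projected scores.
#' @export
projectStrains <- function(m2, loadings) {
  lpos <- as.numeric(rownames(loadings))
  idx <- match(lpos, m2@positions)
  ok <- !is.na(idx)
  if (!any(ok)) {
    out <- matrix(0, nrow(m2@values), ncol(loadings))
  } else {
    out <- m2@values[, idx[ok], drop = FALSE] %*%
      loadings[ok, , drop = FALSE]
  }
  rownames(out) <- m2@strainIds
  colnames(out) <- colnames(loadings)
  out
}

#' Excess kurtosis
#'
#' Moment estimator `m4 / m2^2 - 3`, used to summarise how leptokurtic a
#' loading distribution is (many near-zero values with long thin tails).
#'
#' @param x numeric vector.
#' @return the excess kurtosis.
#' @export
excessKurtosis <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(NA_real_)
  mean(xc^4) / m2^2 - 3
}

# ---- accessors / show ----

#' @rdname accessors
#' @aliases eigenvalues,PCAResult-method
setMethod("eigenvalues", "PCAResult", function(x) x@eigenvalues)

#' @rdname accessors
#' @aliases pve,PCAResult-method
setMethod("pve", "PCAResult", function(x) x@pve)

#' @rdname accessors
#' @aliases strainLoadings,PCAResult-method
setMethod("strainLoadings", "PCAResult", function(x) x@strainLoadings)

#' @rdname accessors
#' @aliases strainIds,PCAResult-method
setMethod("strainIds", "PCAResult", function(x) x@strainIds)

setMethod("show", "PCAResult", function(object) {
  k <- length(object@eigenvalues)
  cat(sprintf("PCAResult: %d strains, %d components (%s loading scale)\n",
              nrow(object@strainLoadings), k, object@loadingScale))
  cat(sprintf("  PVE: %s%s\n",
              paste(sprintf("%.1f%%", 100 * utils::head(object@pve, 5)),
                    collapse = ", "),
              if (k > 5) ", ..." else ""))
})
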