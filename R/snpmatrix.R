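# Binary minor-allele matrix construction and the filtering rules applied
# before PCA: MAF filtering, windowed LD pruning, non-redundant strain
# selection and pairwise Hamming distances.

#' @importFrom stats hclust cutree as.dist
NULL

.newSNPMatrix <- function(values, positions, strainIds, minorFreqs) {
  storage.mode(values) <- "integer"
  dimnames(values) <- NULL
  new("SNPMatrix", values = values, positions = as.numeric(positions),
      strainIds = as.character(strainIds), minorFreqs = as.numeric(minorFreqs))
}

# minor-allele choice given per-site counts for states 0 (ancestral), 1 (m1),
# 2 (m2): the state with the second-largest count is coded 1; when counts tie
# the smaller state id becomes minor (so the major is the largest tied id).
# Returns the minor state id, or NA for monomorphic sites.
.minorState <- function(c0, c1, c2) {
  maxc <- pmax(c0, c1, c2)
  major <- ifelse(c2 == maxc, 2L, ifelse(c1 == maxc, 1L, 0L))
  s0 <- ifelse(major == 0L, -1L, c0)
  s1 <- ifelse(major == 1L, -1L, c1)
  s2 <- ifelse(major == 2L, -1L, c2)
  second <- pmax(s0, s1, s2)
  minor <- ifelse(s0 == second, 0L, ifelse(s1 == second, 1L, 2L))
  ifelse(second <= 0L, NA_integer_, minor)
}

.encodePopulation <- function(pop, strainIds = NULL) {
  n <- length(pop)
  if (n < 2) stop("encoding requires at least 2 strains")
  if (is.null(strainIds)) strainIds <- paste0("strain", seq_len(n))
  nmut <- vapply(pop, function(g) length(g$pos), 1L)
  posAll <- unlist(lapply(pop, `[[`, "pos"), use.names = FALSE)
  typeAll <- unlist(lapply(pop, `[[`, "type"), use.names = FALSE)
  strain <- rep(seq_len(n), nmut)
  if (length(posAll) == 0)
    return(.newSNPMatrix(matrix(0L, n, 0), numeric(0), strainIds, numeric(0)))
  upos <- sort(unique(posAll))
  j <- match(posAll, upos)
  c1 <- tabulate(j[typeAll == 1L], nbins = length(upos))
  c2 <- tabulate(j[typeAll == 2L], nbins = length(upos))
  c0 <- n - c1 - c2
  minor <- .minorState(c0, c1, c2)
  keep <- !is.na(minor)
  if (!any(keep))
    return(.newSNPMatrix(matrix(0L, n, 0), numeric(0), strainIds, numeric(0)))
  col <- cumsum(keep)                 # site index -> column in kept matrix
  S <- sum(keep)
  X <- matrix(0L, n, S)
  minorK <- minor[keep]
  # sites where the ancestral (no-mutation) state is minor: column starts at 1
  ancMinor <- which(minorK == 0L)
  if (length(ancMinor)) X[, ancMinor] <- 1L
  ek <- keep[j]                       # entries at kept sites
  ecol <- col[j[ek]]; estrain <- strain[ek]; etype <- typeAll[ek]
  hit <- etype == minorK[ecol]
  X[cbind(estrain[hit], ecol[hit])] <- 1L
  # any mutation at an anc-minor site means that strain is not ancestral there
  ancAt <- minorK[ecol] == 0L
  if (any(ancAt)) X[cbind(estrain[ancAt], ecol[ancAt])] <- 0L
  cnts <- cbind(c0, c1, c2)[keep, , drop = FALSE]
  freq <- cnts[cbind(seq_len(S), minorK + 1L)] / n
  .newSNPMatrix(X, upos[keep], strainIds, freq)
}

.encodeCalls <- function(calls, positions = NULL, strainIds = NULL) {
  n <- nrow(calls)
  if (n < 2) stop("encoding requires at least 2 strains")
  if (is.null(positions)) {
    positions <- suppressWarnings(as.numeric(colnames(calls)))
    if (any(is.na(positions))) positions <- seq_len(ncol(calls)) - 1
  }
  if (is.null(strainIds))
    strainIds <- if (!is.null(rownames(calls))) rownames(calls)
                 else paste0("strain", seq_len(n))
  cols <- vector("list", ncol(calls))
  freqs <- numeric(ncol(calls))
  keep <- logical(ncol(calls))
  for (s in seq_len(ncol(calls))) {
    v <- as.character(calls[, s])
    tab <- table(v[!is.na(v)])
    if (length(tab) < 2) next
    st <- names(tab)[order(-as.integer(tab), names(tab))]
    cnt <- as.integer(tab)[order(-as.integer(tab), names(tab))]
    # major: largest tied id among top counts; minor: smallest id at rank-2
    topTie <- which(cnt == cnt[1])
    major <- st[topTie[length(topTie)]]
    rest <- setdiff(st, major)
    restCnt <- cnt[match(rest, st)]
    minor <- rest[which(restCnt == max(restCnt))[1]]
    cols[[s]] <- as.integer(!is.na(v) & v == minor)
    freqs[s] <- sum(v == minor, na.rm = TRUE) / n
    keep[s] <- TRUE
  }
  o <- order(positions[keep])
  X <- do.call(cbind, cols[keep])[, o, drop = FALSE]
  .newSNPMatrix(X, sort(positions[keep]), strainIds, freqs[keep][o])
}

#' @rdname encodeBinary
#' @aliases encodeBinary,SimOutput-method
setMethod("encodeBinary", "SimOutput", function(x, ...) {
  .encodePopulation(x@population, ...)
})

#' @rdname encodeBinary
#' @aliases encodeBinary,list-method
setMethod("encodeBinary", "list", function(x, strainIds = NULL, ...) {
  .encodePopulation(x, strainIds = strainIds)
})

#' @rdname encodeBinary
#' @aliases encodeBinary,matrix-method
setMethod("encodeBinary", "matrix",
  function(x, positions = NULL, strainIds = NULL, ...) {
    .encodeCalls(x, positions = positions, strainIds = strainIds)
  })

#' Filter sites by minor-allele frequency
#'
#' Retains sites whose encoded minor-allele frequency is at least
#' `threshold` (the study default removes sites below 2%).
#'
#' @param m a [SNPMatrix-class].
#' @param threshold frequency cutoff in `[0, 0.5]`.
#' @return the filtered [SNPMatrix-class].
#' @export
mafFilter <- function(m, threshold = 0.02) {
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must be in [0, 0.5]")
  m[, m@minorFreqs >= threshold]
}

#' Drop sites that are constant over the current strains
#'
#' Strain subsetting can leave columns monomorphic; this removes them
#' (needed before PCA on a strain subset).
#'
#' @param m a [SNPMatrix-class].
#' @return the reduced [SNPMatrix-class].
#' @export
dropMonomorphicSites <- function(m) {
  cm <- colMeans(m@values)
  m[, cm > 0 & cm < 1]
}

#' Windowed LD pruning
#'
#' Greedy left-to-right scan: a site is removed if its squared correlation
#' with any retained site less than `window` bp to its left exceeds
#' `r2max`. With `step <= window` the sliding-window formulation (the study
#' used a 50 kb window shifted by 10 bp) covers every within-window pair,
#' so the greedy scan is equivalent; the later-positioned member of each
#' offending pair is the one removed.
#'
#' @param m a [SNPMatrix-class].
#' @param window window size in bp.
#' @param step window shift in bp (kept for interface parity; any value
#'   `<= window` yields the same comprehensive coverage).
#' @param r2max maximum allowed within-window R2.
#' @return the pruned [SNPMatrix-class]; no retained pair within `window`
#'   bp has R2 exceeding `r2max`.
#' @export
ldPrune <- function(m, window = 50e3, step = 10, r2max = 0.1) {
  if (window <= 0) stop("window must be positive")
  S <- ncol(m@values)
  if (S < 2) return(m)
  X <- m@values
  pos <- m@positions
  keep <- logical(S)
  keptIdx <- integer(0)
  for (jj in seq_len(S)) {
    inWin <- keptIdx[pos[keptIdx] > pos[jj] - window]
    ok <- TRUE
    if (length(inWin)) {
      r <- suppressWarnings(stats::cor(X[, inWin, drop = FALSE], X[, jj]))
      r[is.na(r)] <- 0
      ok <- all(r * r <= r2max)
    }
    if (ok) {
      keep[jj] <- TRUE
      keptIdx <- c(keptIdx, jj)
    }
  }
  m[, keep]
}

#' Pairwise Hamming distances between strains
#'
#' Raw count of differing sites for every strain pair (symmetric, zero
#' diagonal).
#'
#' @param m a [SNPMatrix-class].
#' @return an integer strains x strains matrix.
#' @export
pairwiseDistance <- function(m) {
  X <- m@values
  S1 <- tcrossprod(X)
  rs <- rowSums(X)
  D <- outer(rs, rs, "+") - 2 * S1
  storage.mode(D) <- "integer"
  dimnames(D) <- list(m@strainIds, m@strainIds)
  D
}

#' Greedy non-redundant strain selection
#'
#' Scans strains in input order and keeps a strain iff its Hamming distance
#' to every already-kept strain exceeds `minDist`; all pairwise distances
#' in the kept set therefore exceed `minDist`. The study used this rule
#' with a 20 kb SNP-distance threshold to collapse clonal relatives.
#'
#' @param m a [SNPMatrix-class].
#' @param minDist minimum pairwise SNP distance (>= 0).
#' @return character vector of kept strain ids.
#' @export
nonredundantSelect <- function(m, minDist) {
  if (minDist < 0) stop("minDist must be non-negative")
  D <- pairwiseDistance(m)
  kept <- integer(0)
  for (i in seq_len(nrow(D))) {
    if (length(kept) == 0 || all(D[i, kept] > minDist))
      kept <- c(kept, i)
  }
  m@strainIds[kept]
}

# ---- accessors, subsetting, show ----

#' @rdname accessors
#' @aliases snpValues,SNPMatrix-method
setMethod("snpValues", "SNPMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@strainIds, as.character(x@positions))
  v
})

#' @rdname accessors
#' @aliases positions,SNPMatrix-method
setMethod("positions", "SNPMatrix", function(x) x@positions)

#' @rdname accessors
#' @aliases strainIds,SNPMatrix-method
setMethod("strainIds", "SNPMatrix", function(x) x@strainIds)

#' @rdname accessors
#' @aliases minorFreqs,SNPMatrix-method
setMethod("minorFreqs", "SNPMatrix", function(x) x@minorFreqs)

setMethod("dim", "SNPMatrix", function(x) dim(x@values))

#' Subset a SNPMatrix by strains (rows) and/or sites (columns)
#'
#' Subsetting does not re-encode: the 0/1 coding and the stored
#' `minorFreqs` refer to the original encoding. Use
#' [dropMonomorphicSites()] after strain subsetting when polymorphism
#' within the subset is required.
#'
#' @param x a [SNPMatrix-class].
#' @param i,j strain and site indices.
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @return a [SNPMatrix-class].
#' @export
setMethod("[", "SNPMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  .newSNPMatrix(x@values[i, j, drop = FALSE], x@positions[j],
                x@strainIds[i], x@minorFreqs[j])
})

setMethod("show", "SNPMatrix", function(object) {
  cat(sprintf("SNPMatrix: %d strains x %d polymorphic sites\n",
              nrow(object@values), ncol(object@values)))
  if (ncol(object@values)) {
    cat(sprintf("  positions %g-%g | minor-allele freq %.3f-%.3f\n",
                min(object@positions), max(object@positions),
                min(object@minorFreqs), max(object@minorFreqs)))
  }
})
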