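# Binary encoding, filtering and distance rules against enumeration oracles.

test_that("encodeBinary codes the second most frequent allele as minor", {
  # (anc, anc, m1): the rarer mutant state is minor
  pop <- list(makeGenome(), makeGenome(), makeGenome(10, 1L))
  m <- encodeBinary(pop)
  expect_identical(as.vector(snpValues(m)), c(0L, 0L, 1L))
  expect_identical(positions(m), 10)
  expect_equal(minorFreqs(m), 1 / 3)

  # (anc, m1, m1, m2): m1 major, anc/m2 tie for minor -> the smaller
  # internal id (ancestral) is coded 1, rank-3 state coded 0
  pop <- list(makeGenome(), makeGenome(10, 1L), makeGenome(10, 1L),
              makeGenome(10, 2L))
  m <- encodeBinary(pop)
  expect_identical(as.vector(snpValues(m)), c(1L, 0L, 0L, 0L))

  # triallelic with distinct counts: rank-2 coded 1, rank-3 coded 0
  pop <- c(replicate(3, makeGenome(10, 1L), simplify = FALSE),
           replicate(2, makeGenome(10, 2L), simplify = FALSE),
           list(makeGenome()))
  m <- encodeBinary(pop)
  expect_identical(as.vector(snpValues(m)),
                   c(0L, 0L, 0L, 1L, 1L, 0L))  # m2 (count 2) is minor

  # monomorphic sites are dropped
  pop <- replicate(4, makeGenome(5, 1L), simplify = FALSE)
  expect_identical(ncol(snpValues(encodeBinary(pop))), 0L)
  expect_error(encodeBinary(list(makeGenome())), "2 strains")
})

test_that("minor tie at 0.5 goes to the smaller allele id", {
  # anc vs m1 at 2:2 -> ancestral state coded 1
  pop <- list(makeGenome(), makeGenome(), makeGenome(10, 1L),
              makeGenome(10, 1L))
  m <- encodeBinary(pop)
  expect_identical(as.vector(snpValues(m)), c(1L, 1L, 0L, 0L))
  # m1 vs m2 at 2:2 -> m1 coded 1
  pop <- list(makeGenome(10, 1L), makeGenome(10, 1L),
              makeGenome(10, 2L), makeGenome(10, 2L))
  m <- encodeBinary(pop)
  expect_identical(as.vector(snpValues(m)), c(1L, 1L, 0L, 0L))
})

test_that("encoded column means never exceed one half", {
  set.seed(100)
  for (i in 1:5) {
    m <- randomSNPMatrix(30, 200, 25)
    expect_true(all(colMeans(snpValues(m)) <= 0.5 + 1e-12))
    expect_true(all(minorFreqs(m) > 0 & minorFreqs(m) <= 0.5))
    expect_true(all(diff(positions(m)) > 0))
  }
})

test_that("mafFilter matches a brute-force frequency scan", {
  set.seed(101)
  m <- randomSNPMatrix(50, 200, 30)
  expect_identical(dim(mafFilter(m, 0)), dim(m))
  f <- mafFilter(m, 0.1)
  expect_identical(ncol(snpValues(f)), sum(colMeans(snpValues(m)) >= 0.1))
  # a singleton among 100 strains falls below a 2% threshold
  pop <- c(list(makeGenome(10, 1L)),
           replicate(99, makeGenome(), simplify = FALSE))
  pop[[2]] <- makeGenome(20, 1L); pop[[3]] <- makeGenome(20, 1L)
  pop[[4]] <- makeGenome(20, 1L)
  m2 <- mafFilter(encodeBinary(pop), 0.02)
  expect_identical(positions(m2), 20)
  expect_error(mafFilter(m, 0.7), "0, 0.5")
})

test_that("ldPrune removes linked later sites and is idempotent", {
  # two identical columns 1 kb apart: exactly the earlier one survives
  pop <- c(replicate(5, makeGenome(c(100, 1100), c(1L, 1L)),
                     simplify = FALSE),
           replicate(5, makeGenome(), simplify = FALSE))
  m <- encodeBinary(pop)
  pr <- ldPrune(m, window = 50e3, r2max = 0.1)
  expect_identical(positions(pr), 100)
  # pairwise-independent columns are untouched
  set.seed(102)
  m2 <- randomSNPMatrix(200, 50, 10)
  m2 <- mafFilter(m2, 0.1)
  R2 <- suppressWarnings(cor(snpValues(m2)))^2
  if (all(R2[upper.tri(R2)] < 0.1)) {
    expect_identical(dim(ldPrune(m2, r2max = 0.1)), dim(m2))
  }
  # planted-blocks toy: post-condition checked exhaustively
  set.seed(103)
  base <- replicate(4, sample(0:1, 40, replace = TRUE))
  calls <- base[, rep(1:4, each = 5)]
  flip <- matrix(runif(length(calls)) < 0.05, nrow(calls))
  calls[flip] <- 1 - calls[flip]
  mm <- encodeBinary(matrix(as.character(calls), nrow(calls)),
                     positions = seq(0, by = 1000, length.out = 20))
  pr <- ldPrune(mm, window = 50e3, r2max = 0.1)
  X <- snpValues(pr); pos <- positions(pr)
  if (ncol(X) > 1) {
    for (i in seq_len(ncol(X) - 1)) {
      for (j in (i + 1):ncol(X)) {
        if (pos[j] - pos[i] < 50e3)
          expect_lte(suppressWarnings(cor(X[, i], X[, j]))^2, 0.1)
      }
    }
  }
  # idempotent, and output is a subset of input columns
  expect_identical(positions(ldPrune(pr, window = 50e3, r2max = 0.1)),
                   positions(pr))
  expect_true(all(positions(pr) %in% positions(mm)))
})

test_that("pairwiseDistance equals the double-loop Hamming count", {
  set.seed(104)
  m <- randomSNPMatrix(10, 100, 20)
  D <- pairwiseDistance(m)
  X <- snpValues(m)
  for (i in 1:10) for (j in 1:10)
    expect_identical(D[i, j], as.integer(sum(X[i, ] != X[j, ])))
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  # complementary rows are at maximal distance
  cm <- matrix(c("a", "b", "b", "a"), 2, 2)
  m2 <- encodeBinary(cm, positions = c(1, 2))
  expect_identical(pairwiseDistance(m2)[1, 2], 2L)
})

test_that("nonredundantSelect is a greedy scan over kept distances", {
  # identical strains collapse to one
  pop <- replicate(5, makeGenome(c(1, 7), c(1L, 2L)), simplify = FALSE)
  pop <- c(pop, replicate(5, makeGenome(), simplify = FALSE))
  m <- encodeBinary(pop)
  expect_identical(length(nonredundantSelect(m, 1)), 2L)
  # all pairwise distances above threshold: all kept
  set.seed(105)
  m2 <- randomSNPMatrix(8, 400, 60)
  D <- pairwiseDistance(m2)
  thr <- min(D[upper.tri(D)]) - 1
  expect_identical(nonredundantSelect(m2, thr), strainIds(m2))
  # greedy oracle by explicit loop
  greedyOracle <- function(D, minDist) {
    kept <- integer(0)
    for (i in seq_len(nrow(D)))
      if (!length(kept) || all(D[i, kept] > minDist)) kept <- c(kept, i)
    kept
  }
  med <- median(D[upper.tri(D)])
  expect_identical(nonredundantSelect(m2, med),
                   strainIds(m2)[greedyOracle(D, med)])
  # appending duplicate strains does not change the kept set
  m3 <- m2[c(1:8, 1, 3), ]
  expect_identical(nonredundantSelect(m3, med), nonredundantSelect(m2, med))
})

test_that("TSV and VCF import round-trip the coding rules", {
  set.seed(106)
  m <- randomSNPMatrix(12, 300, 15)
  tf <- tempfile(fileext = ".tsv")
  exportSNPMatrix(m, tf)
  m2 <- importSNPMatrix(tf)
  expect_identical(snpValues(m2), snpValues(m))
  expect_equal(positions(m2), positions(m))
  # hand-written haploid VCF: site 100 has alt freq 2/5 (minor = ALT),
  # site 200 is triallelic (counts ref 1, alt1 3, alt2 1)
  vf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste0("s", 1:5, collapse = "\t")),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0\t0\t0\t1\t1",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT\t0\t1\t1\t1\t2"
  ), vf)
  mv <- importVCF(vf)
  expect_equal(positions(mv), c(100, 200))
  expect_identical(snpValues(mv)[, 1], c(s1 = 0L, s2 = 0L, s3 = 0L,
                                         s4 = 1L, s5 = 1L))
  # at 200: major is allele 1 (count 3); ref and allele 2 tie at 1;
  # the smaller identifier ("0") is coded minor
  expect_identical(snpValues(mv)[, 2], c(s1 = 1L, s2 = 0L, s3 = 0L,
                                         s4 = 0L, s5 = 0L))
})
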