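# Plain-text exchange formats: TSV matrices with a position header, trait
# and effect tables, and VCF import for externally called haploid variants.

#' @importFrom utils write.table read.table
NULL

#' Export a SNPMatrix as TSV
#'
#' Writes a strains x sites table with a `strain` column and one column
#' per site named by its bp position.
#'
#' @param m a [SNPMatrix-class].
#' @param file output path.
#' @export
exportSNPMatrix <- function(m, file) {
  df <- data.frame(strain = m@strainIds, m@values, check.names = FALSE)
  colnames(df) <- c("strain", as.character(m@positions))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Import a SNPMatrix from TSV
#'
#' Reads the format written by [exportSNPMatrix()]: a `strain` column and
#' binary site columns named by position. Already-binary input is taken
#' at face value; the stored minor-allele frequencies are the column
#' means.
#'
#' @param file input path.
#' @return a [SNPMatrix-class].
#' @export
importSNPMatrix <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  pos <- as.numeric(colnames(df)[-1])
  o <- order(pos)
  .newSNPMatrix(X[, o, drop = FALSE], pos[o], ids, colMeans(X)[o])
}

#' Import haploid variant calls from VCF
#'
#' Reads a VCF (via \pkg{vcfR}), takes the haploid GT field per sample and
#' applies the minor-allele coding rule to every record: the second most
#' frequent allele at each site is coded 1 and every other allele 0
#' (including ranks 3-4 at multi-allelic sites); monomorphic records are
#' dropped. Missing genotypes are treated as non-minor (0).
#'
#' @param file VCF path (plain text or gzipped).
#' @return a [SNPMatrix-class].
#' @export
importVCF <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("importVCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt == "."] <- NA
  calls <- t(gt)                      # strains x sites, allele indices
  pos <- as.numeric(vcfR::getPOS(v))
  .encodeCalls(calls, positions = pos, strainIds = rownames(calls))
}

#' Write the tabular artifacts of a simulation run
#'
#' Writes the binary matrix (TSV with position header), the per-individual
#' trait table (id, deme, score), the per-site effect table (Gamma-effects
#' scenarios only) and the generation log into `dir`.
#'
#' @param sim a [SimOutput-class].
#' @param m the encoded [SNPMatrix-class] for the run.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimOutput <- function(sim, m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exportSNPMatrix(m, file.path(dir, "snp_matrix.tsv"))
  traits <- data.frame(
    id = m@strainIds,
    deme = vapply(sim@population, function(g) as.integer(g$deme), 1L),
    score = sim@traitValues
  )
  write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(sim@effectTable)) {
    eff <- data.frame(position = seq_along(sim@effectTable) - 1,
                      coefficient = sim@effectTable)
    write.table(eff, file.path(dir, "effects.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sim@generationLog, file.path(dir, "generation_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
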