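#' Accessors for ecocline classes
#'
#' Small accessor generics for the package's S4 containers: `snpValues()`
#' returns the binary strains x sites matrix, `positions()` the per-site bp
#' coordinates, `strainIds()` the row labels, `minorFreqs()` the encoded
#' minor-allele frequencies, `eigenvalues()`, `pve()` and `strainLoadings()`
#' the PCA components, and `traitValues()`, `generationLog()` and
#' `scenario()` the simulation outputs.
#'
#' @param x an ecocline S4 object.
#' @return the slot contents (matrix or vector), see each method.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("snpValues", function(x) standardGeneric("snpValues"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname accessors
#' @export
setGeneric("minorFreqs", function(x) standardGeneric("minorFreqs"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("pve", function(x) standardGeneric("pve"))

#' @rdname accessors
#' @export
setGeneric("strainLoadings", function(x) standardGeneric("strainLoadings"))

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname accessors
#' @export
setGeneric("generationLog", function(x) standardGeneric("generationLog"))

#' @rdname accessors
#' @export
setGeneric("scenario", function(x) standardGeneric("scenario"))

#' Encode a population or call matrix as a binary minor-allele SNP matrix
#'
#' @param x a [SimOutput-class], a list of simulated genomes, or a character
#'   matrix of allele calls (strains x sites).
#' @param ... passed to methods (`positions`, `strainIds` for matrices).
#' @return a [SNPMatrix-class].
#' @seealso [mafFilter()], [ldPrune()]
#' @export
setGeneric("encodeBinary", function(x, ...) standardGeneric("encodeBinary"))
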