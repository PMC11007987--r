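#' @name accessors
#' @title Accessors for pairGWAS data classes
#' @description Slot access for [GenotypeMatrix-class], [TraitTable-class]
#'   and [BinarizationResult-class] objects goes through these functions.
#' @param x a pairGWAS data object.
NULL

#' @rdname accessors
#' @export
setGeneric("isolateIds", function(x) standardGeneric("isolateIds"))

#' @rdname accessors
#' @export
setGeneric("orthogroupIds", function(x) standardGeneric("orthogroupIds"))

#' @rdname accessors
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname accessors
#' @export
setGeneric("genePresence", function(x) standardGeneric("genePresence"))

#' @rdname accessors
#' @export
setGeneric("geneLists", function(x) standardGeneric("geneLists"))

#' @rdname accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))

#' @rdname accessors
#' @export
setGeneric("traitKinds", function(x) standardGeneric("traitKinds"))

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname accessors
setMethod("isolateIds", "GenotypeMatrix", function(x) rownames(x@counts))

#' @rdname accessors
setMethod("isolateIds", "TraitTable", function(x) rownames(x@values))

#' @rdname accessors
setMethod("orthogroupIds", "GenotypeMatrix", function(x) colnames(x@counts))

#' @rdname accessors
setMethod("geneCounts", "GenotypeMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("genePresence", "GenotypeMatrix", function(x) {
  p <- x@counts >= 1L
  storage.mode(p) <- "integer"
  p
})

#' @rdname accessors
setMethod("geneLists", "GenotypeMatrix", function(x) {
  if (!length(x@geneLists)) return(NULL)
  gl <- x@geneLists
  dim(gl) <- dim(x@counts)
  dimnames(gl) <- dimnames(x@counts)
  gl
})

#' @rdname accessors
setMethod("traitIds", "TraitTable", function(x) colnames(x@values))

#' @rdname accessors
setMethod("traitKinds", "TraitTable", function(x) {
  structure(x@kinds, names = colnames(x@values))
})

#' @rdname accessors
setMethod("traitValues", "TraitTable", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("binaryLabels", function(x) standardGeneric("binaryLabels"))

#' @rdname accessors
setMethod("binaryLabels", "BinarizationResult", function(x) x@labels)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d isolates x %d orthogroups\n",
              nrow(object@counts), ncol(object@counts)))
  cat(sprintf("  gene lists: %s\n",
              if (length(object@geneLists)) "present" else "absent"))
  pres <- mean(object@counts >= 1)
  cat(sprintf("  mean presence: %.3f\n", pres))
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d isolates x %d traits (%d binary, %d numeric)\n",
              nrow(object@values), ncol(object@values),
              sum(object@kinds == "binary"), sum(object@kinds == "numeric")))
  cat(sprintf("  missing values: %d\n", sum(is.na(object@values))))
})

setMethod("show", "BinarizationResult", function(object) {
  cat(sprintf("BinarizationResult '%s' (%s)\n", object@traitId, object@method))
  cat(sprintf("  component means: %s / %s; positives: %d; excluded: %d\n",
              fmt6(object@means[1]), fmt6(object@means[2]),
              sum(object@labels == 1L, na.rm = TRUE), object@nExcluded))
})
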