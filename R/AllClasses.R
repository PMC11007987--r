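#' GenotypeMatrix: orthogroup copy numbers per isolate
#'
#' Holds a non-negative integer matrix of gene counts (isolates in rows,
#' orthogroups in columns) and, for gene-list style inputs, the per-cell gene
#' identifiers. The association machinery works on the binarized view
#' (present = count >= 1); raw counts surface only in coverage matrices.
#'
#' @slot counts integer matrix, isolates x orthogroups, no negative entries.
#' @slot geneLists either an empty list, or a list-matrix of character
#'   vectors with the same dimensions as `counts`; each cell's length equals
#'   the corresponding count.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
  representation(counts = "matrix", geneLists = "list"))

setValidity("GenotypeMatrix", function(object) {
  cts <- object@counts
  msgs <- character(0)
  if (!is.numeric(cts)) msgs <- c(msgs, "counts must be numeric")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msgs <- c(msgs, "counts must have isolate rownames and orthogroup colnames")
  else {
    if (anyDuplicated(rownames(cts)))
      msgs <- c(msgs, "duplicate isolate identifiers")
    if (anyDuplicated(colnames(cts)))
      msgs <- c(msgs, "duplicate orthogroup identifiers")
  }
  if (any(cts < 0) || any(cts != round(cts)))
    msgs <- c(msgs, "counts must be non-negative integers")
  gl <- object@geneLists
  if (length(gl)) {
    if (length(gl) != length(cts))
      msgs <- c(msgs, "geneLists must match counts dimensions")
    else {
      len <- vapply(gl, length, integer(1))
      if (!all(len == as.vector(cts)))
        msgs <- c(msgs, "each gene list length must equal its count")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param counts numeric matrix (isolates x orthogroups) with row and column
#'   names; coerced to integer.
#' @param geneLists optional list of character vectors in column-major cell
#'   order (as produced by gene-list tables), or NULL.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 1, 1), nrow = 3,
#'             dimnames = list(c("i1", "i2", "i3"), c("og1", "og2")))
#' g <- GenotypeMatrix(m)
#' genePresence(g)
#' @export
GenotypeMatrix <- function(counts, geneLists = NULL) {
  storage.mode(counts) <- "integer"
  new("GenotypeMatrix", counts = counts,
      geneLists = if (is.null(geneLists)) list() else geneLists)
}

#' TraitTable: per-isolate phenotypes, binary or numeric
#'
#' @slot values numeric matrix, isolates x traits; NA marks missing. Binary
#'   traits hold 0/1.
#' @slot kinds character vector, one of "binary"/"numeric" per trait.
#'
#' @aliases TraitTable-class
#' @export
setClass("TraitTable",
  representation(values = "matrix", kinds = "character"))

setValidity("TraitTable", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have isolate rownames and trait colnames")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate isolate ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate trait ids")
  }
  if (length(object@kinds) != ncol(v))
    msgs <- c(msgs, "one kind per trait required")
  else if (!all(object@kinds %in% c("binary", "numeric")))
    msgs <- c(msgs, "kinds must be 'binary' or 'numeric'")
  else {
    for (j in seq_len(ncol(v))) {
      x <- v[, j][!is.na(v[, j])]
      if (length(x) < 1) {
        msgs <- c(msgs, sprintf("trait '%s' has no observed values",
                                colnames(v)[j]))
      } else if (object@kinds[j] == "binary" && !all(x %in% c(0, 1))) {
        msgs <- c(msgs, sprintf("binary trait '%s' has values outside {0,1}",
                                colnames(v)[j]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TraitTable
#'
#' Trait kinds are auto-detected when not given: a column whose non-missing
#' values are a subset of \{0, 1\} is binary, everything else numeric.
#'
#' @param values numeric matrix, isolates x traits, with dimnames.
#' @param kinds optional character vector "binary"/"numeric" per trait.
#' @return A [TraitTable-class] object.
#' @export
TraitTable <- function(values, kinds = NULL) {
  storage.mode(values) <- "double"
  if (is.null(kinds)) {
    kinds <- apply(values, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) && all(x %in% c(0, 1))) "binary" else "numeric"
    })
  }
  new("TraitTable", values = values, kinds = unname(kinds))
}

#' BinarizationResult: outcome of converting a numeric trait to binary
#'
#' @slot traitId trait identifier.
#' @slot method one of "kmeans", "gmm", "gmm_kmeans_fallback".
#' @slot labels integer 0/1 per isolate, NA for isolates that were missing in
#'   the input or abstained (posterior below the cutoff); named by isolate.
#' @slot means the two component means, ascending; label 1 always maps to
#'   the larger-mean component.
#' @slot posterior per-isolate posterior probability of the assigned
#'   component (GMM only; empty for k-means).
#' @slot nExcluded number of observed isolates abstained by the posterior
#'   cutoff.
#'
#' @aliases BinarizationResult-class
#' @export
setClass("BinarizationResult",
  representation(traitId = "character", method = "character",
                 labels = "integer", means = "numeric",
                 posterior = "numeric", nExcluded = "integer"))

setValidity("BinarizationResult", function(object) {
  msgs <- character(0)
  if (!object@method %in% c("kmeans", "gmm", "gmm_kmeans_fallback"))
    msgs <- c(msgs, "unknown method")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && !all(lab %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0/1/NA")
  if (length(object@means) != 2 || is.unsorted(object@means))
    msgs <- c(msgs, "means must be two values, ascending")
  if (length(msgs)) msgs else TRUE
})
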