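missingTokens <- c("", "na", "nan")

isMissingToken <- function(x) is.na(x) | tolower(trimws(x)) %in% missingTokens

sniffDelimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

checkRectangular <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("ragged table '%s': row %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], nf[1]), call. = FALSE)
}

readTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(sep)) sep <- sniffDelimiter(path)
  checkRectangular(path, sep)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL,
                   comment.char = "", quote = "\"")
  if (anyDuplicated(df[[1]]))
    stop(sprintf("duplicate identifiers in first column of '%s': %s", path,
                 paste(head(unique(df[[1]][duplicated(df[[1]])]), 3),
                       collapse = ", ")), call. = FALSE)
  if (anyDuplicated(colnames(df)[-1]))
    stop(sprintf("duplicate identifiers in header of '%s'", path),
         call. = FALSE)
  df
}

#' Read a genotype (orthogroup presence) table
#'
#' Accepts both table styles produced by pan-genome pipelines: gene-count
#' tables (cells hold per-genome copy numbers, Roary style) and gene-list
#' tables (cells hold delimiter-separated gene identifiers, Roary /
#' OrthoFinder style). The delimiter (comma vs tab) is sniffed from the
#' header; gene lists may be separated by "," or ";". By convention these
#' tables have orthogroups as rows and isolates as columns and are
#' transposed on read; pass `isolateIdsHint` (e.g. the trait table's isolate
#' ids) to let the reader detect the orientation from the header instead.
#'
#' @param path path to a CSV/TSV file.
#' @param format "auto" detects gene-list style from non-numeric cells.
#' @param delimiter field delimiter; NULL = sniff from header.
#' @param isolateIdsHint optional character vector of known isolate ids used
#'   for orientation detection.
#' @return A [GenotypeMatrix-class]; all-zero orthogroups are kept but
#'   reported with a warning.
#' @export
readGenotype <- function(path, format = c("auto", "gene_count", "gene_list"),
                         delimiter = NULL, isolateIdsHint = NULL) {
  format <- match.arg(format)
  df <- readTable(path, delimiter)
  rowIds <- df[[1]]
  colIds <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])

  # orientation: default is the pan-genome convention (orthogroups as rows)
  orthogroupsAsRows <- TRUE
  if (!is.null(isolateIdsHint)) {
    orthogroupsAsRows <- mean(colIds %in% isolateIdsHint) >=
      mean(rowIds %in% isolateIdsHint)
  }
  if (orthogroupsAsRows) {
    cells <- t(cells)
    tmp <- rowIds; rowIds <- colIds; colIds <- tmp
  }
  dimnames(cells) <- list(rowIds, colIds)

  if (format == "auto") {
    suppressWarnings(num <- as.numeric(cells))
    blank <- isMissingToken(cells)
    format <- if (any(is.na(num) & !blank)) "gene_list" else "gene_count"
  }
  if (format == "gene_count") {
    blank <- isMissingToken(cells)
    cells[blank] <- "0"
    counts <- matrix(as.numeric(cells), nrow(cells), ncol(cells),
                     dimnames = dimnames(cells))
    if (anyNA(counts)) {
      bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell in gene-count table at isolate '%s', orthogroup '%s'",
                   rowIds[bad[1]], colIds[bad[2]]), call. = FALSE)
    }
    g <- GenotypeMatrix(counts)
  } else {
    lists <- lapply(as.vector(cells), function(x) {
      if (isMissingToken(x)) return(character(0))
      ids <- trimws(strsplit(x, "[,;]")[[1]])
      ids[nzchar(ids)]
    })
    counts <- matrix(vapply(lists, length, integer(1)), nrow(cells),
                     ncol(cells), dimnames = dimnames(cells))
    g <- GenotypeMatrix(counts, geneLists = lists)
  }
  empty <- colSums(geneCounts(g)) == 0
  if (any(empty))
    warning(sprintf("%d orthogroup(s) absent from every isolate (e.g. %s)",
                    sum(empty), colnames(geneCounts(g))[which(empty)[1]]))
  validObject(g)
  g
}

#' Read a trait (phenotype) table
#'
#' Isolates as rows, traits as columns. Blank, "NA", "NaN" and "nan" cells
#' (case-insensitive) mark missing values. A column whose non-missing values
#' are all 0/1 is a binary trait; anything else is numeric. Traits with
#' fewer than two distinct observed values carry no contrast and are dropped
#' with a warning.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter field delimiter; NULL = sniff from header.
#' @return A [TraitTable-class].
#' @export
readTraits <- function(path, delimiter = NULL) {
  df <- readTable(path, delimiter)
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- ids
  miss <- isMissingToken(cells)
  suppressWarnings(vals <- matrix(as.numeric(cells), nrow(cells), ncol(cells),
                                  dimnames = dimnames(cells)))
  bad <- is.na(vals) & !miss
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at isolate '%s', trait '%s'",
                 cells[w[1], w[2]], rownames(cells)[w[1]],
                 colnames(cells)[w[2]]), call. = FALSE)
  }
  vals[miss] <- NA_real_
  keep <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j][!is.na(vals[, j])]
    length(unique(x)) >= 2
  }, logical(1))
  if (!all(keep))
    warning(sprintf("excluded %d trait(s) with < 2 distinct observed values: %s",
                    sum(!keep),
                    paste(head(colnames(vals)[!keep], 5), collapse = ", ")))
  if (!any(keep)) stop("no usable traits remain", call. = FALSE)
  TraitTable(vals[, keep, drop = FALSE])
}

#' Read an entity metadata table
#'
#' @param path TSV with the entity identifier in the first column.
#' @param kind one of "isolate", "trait", "orthogroup" (recorded as an
#'   attribute; any extra columns are carried along).
#' @return data.frame keyed by the first column.
#' @export
readMetadata <- function(path, kind = c("isolate", "trait", "orthogroup")) {
  kind <- match.arg(kind)
  df <- readTable(path, "\t")
  colnames(df)[1] <- "id"
  attr(df, "entityKind") <- kind
  df
}

#' Restrict genotype, traits and tree to their shared isolates
#'
#' All inputs are reduced to the intersection of isolate identifiers and put
#' into one canonical (lexicographic) ordering, so downstream results are
#' invariant to input row/column permutations. The tree is pruned to the
#' shared leaves. The operation is idempotent.
#'
#' @param genotype a [GenotypeMatrix-class].
#' @param traits a [TraitTable-class].
#' @param tree optional rooted `ape::phylo` over (a superset of) the
#'   isolates; NULL to infer one later.
#' @return list(genotype, traits, tree).
#' @export
alignInputs <- function(genotype, traits, tree = NULL) {
  shared <- intersect(isolateIds(genotype), isolateIds(traits))
  if (!is.null(tree)) shared <- intersect(shared, tree$tip.label)
  if (length(shared) == 0) {
    stop(sprintf("no shared isolates (genotype e.g. %s; traits e.g. %s%s)",
                 paste(head(isolateIds(genotype), 3), collapse = ","),
                 paste(head(isolateIds(traits), 3), collapse = ","),
                 if (is.null(tree)) "" else
                   sprintf("; tree e.g. %s",
                           paste(head(tree$tip.label, 3), collapse = ","))),
         call. = FALSE)
  }
  if (length(shared) < 4)
    stop(sprintf("only %d shared isolate(s) (%s); at least 4 required",
                 length(shared), paste(shared, collapse = ",")), call. = FALSE)
  shared <- sort(shared)
  cts <- geneCounts(genotype)[shared, sort(orthogroupIds(genotype)),
                              drop = FALSE]
  gl <- geneLists(genotype)
  g2 <- if (is.null(gl)) GenotypeMatrix(cts) else
    GenotypeMatrix(cts, as.list(gl[shared, colnames(cts)]))
  vals <- traitValues(traits)[shared, sort(traitIds(traits)), drop = FALSE]
  kinds <- traitKinds(traits)[colnames(vals)]
  t2 <- new("TraitTable", values = vals, kinds = unname(kinds))
  tr2 <- if (is.null(tree)) NULL else pruneTree(tree, shared)
  list(genotype = g2, traits = t2, tree = tr2)
}

#' Write a genotype table
#'
#' Writes the conventional orientation (orthogroups as rows, isolates as
#' columns). Gene-list format requires gene lists on the object.
#'
#' @param genotype a [GenotypeMatrix-class].
#' @param path output file.
#' @param format table style to emit.
#' @param delimiter field delimiter.
#' @export
writeGenotype <- function(genotype, path,
                          format = c("gene_count", "gene_list"),
                          delimiter = "\t") {
  format <- match.arg(format)
  cts <- t(geneCounts(genotype))
  if (format == "gene_list") {
    gl <- geneLists(genotype)
    if (is.null(gl)) stop("no gene lists on this GenotypeMatrix",
                          call. = FALSE)
    glT <- t(gl)
    cells <- matrix(vapply(glT, paste, character(1), collapse = ", "),
                    nrow(glT), ncol(glT), dimnames = dimnames(glT))
  } else {
    cells <- cts
  }
  df <- data.frame(Gene = rownames(cts), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trait table
#'
#' @param traits a [TraitTable-class].
#' @param path output file.
#' @param delimiter field delimiter.
#' @export
writeTraits <- function(traits, path, delimiter = "\t") {
  v <- traitValues(traits)
  df <- data.frame(isolate = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
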