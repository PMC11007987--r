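#' Maximum non-intersecting contrasting pairs on a tree
#'
#' A contrasting pair is two leaves that differ in both gene and trait
#' state; the statistic is the largest number of such pairs whose connecting
#' paths are mutually edge-disjoint, together with the maximum ("best") and
#' minimum ("worst") number of supporting pairs (gene+trait+ vs
#' gene-trait-) attainable among maximal pairings. Computed in one
#' iterative postorder pass per labeling; leaves with a missing trait state
#' are pruned first. `pBest`/`pWorst` are upper binomial tail probabilities
#' P[X >= best] and P[X >= worst] for X ~ Binomial(maxPairs, 1/2) — the
#' chance of at least that much co-variation among phylogenetically
#' independent contrasts under no association.
#'
#' @param tree rooted binary `ape::phylo`.
#' @param gene 0/1 vector over leaves (named by tip or in tip order).
#' @param trait 0/1 vector over leaves; NA = excluded.
#' @return list(maxPairs, bestSupporting, worstSupporting, pBest, pWorst).
#' @export
maxContrastingPairs <- function(tree, gene, trait) {
  gene <- alignLeafVector(gene, tree$tip.label)
  trait <- alignLeafVector(trait, tree$tip.label)
  names(gene) <- names(trait) <- tree$tip.label
  keep <- which(!is.na(trait))
  if (length(keep) < 2)
    return(list(maxPairs = 0L, bestSupporting = 0L, worstSupporting = 0L,
                pBest = 1, pWorst = 1))
  if (length(keep) < length(tree$tip.label))
    tree <- pruneTree(tree, tree$tip.label[keep])
  idx <- treeIndex(tree)
  labels <- integer(nrow(idx$children))
  labels[idx$leafNodes + 1L] <-
    2L * as.integer(gene[idx$tipLabels]) + as.integer(trait[idx$tipLabels])
  s <- pair_summary_cpp(idx$children, idx$postorder, labels)
  pairPvalues(s[1], s[2], s[3])
}

pairPvalues <- function(maxPairs, best, worst) {
  if (maxPairs == 0) {
    pB <- 1; pW <- 1
  } else {
    pB <- pbinom(best - 1, maxPairs, 0.5, lower.tail = FALSE)
    pW <- pbinom(worst - 1, maxPairs, 0.5, lower.tail = FALSE)
  }
  list(maxPairs = as.integer(maxPairs), bestSupporting = as.integer(best),
       worstSupporting = as.integer(worst), pBest = pFloor(pB),
       pWorst = pFloor(pW))
}

# Internal: summaries for many gene columns against one complete (no NA)
# trait vector on a pre-indexed tree. genes: nLeaves x nGenes 0/1 matrix in
# idx tip order.
pairSummaryMulti <- function(idx, genes, trait, reps = 1L) {
  storage.mode(genes) <- "integer"
  pair_summary_multi_cpp(idx$children, idx$postorder, idx$leafNodes,
                         genes, as.integer(trait), as.integer(reps))
}

#' Label-switching permutation test
#'
#' Holds the tree and gene labels fixed, permutes the trait labels over the
#' leaves uniformly at random, and recomputes the best-supporting-pair
#' count. The returned empirical p-value is
#' (1 + #\{null >= observed\}) / (1 + nPermut); ties count against
#' significance. If no contrasting pair exists on the observed data the
#' test returns 1 without permuting. The permutation null depends only on
#' the tree, the gene's presence pattern and the number of trait-positive
#' leaves, so nulls are cached under the gene's canonical pattern key and
#' reused across traits and duplicated orthogroups; the RNG stream is
#' derived from (seed, pattern key, positives, nPermut), making results
#' independent of processing order.
#'
#' @param tree rooted binary `ape::phylo`.
#' @param gene 0/1 vector over leaves.
#' @param trait 0/1 vector over leaves; NA = excluded (those leaves are
#'   pruned and trait labels are permuted among the remaining leaves only).
#' @param nPermut number of permutations (>= 100).
#' @param seed master seed.
#' @param cache optional [newPermCache()] store.
#' @return Empirical p-value in [1/(nPermut+1), 1].
#' @export
permutationTest <- function(tree, gene, trait, nPermut = 1000L, seed = 1L,
                            cache = NULL) {
  if (nPermut < 100) stop("nPermut must be >= 100", call. = FALSE)
  gene <- alignLeafVector(gene, tree$tip.label)
  trait <- alignLeafVector(trait, tree$tip.label)
  names(gene) <- names(trait) <- tree$tip.label
  keep <- which(!is.na(trait))
  if (length(keep) < 2) return(1)
  if (length(keep) < length(tree$tip.label))
    tree <- pruneTree(tree, tree$tip.label[keep])
  idx <- treeIndex(tree)
  gene <- unname(gene[idx$tipLabels])
  trait <- unname(trait[idx$tipLabels])
  labels <- integer(nrow(idx$children))
  labels[idx$leafNodes + 1L] <- 2L * as.integer(gene) + as.integer(trait)
  s <- pair_summary_cpp(idx$children, idx$postorder, labels)
  if (s[1] == 0L) return(1)
  null <- permNull(idx, tree, gene, sum(trait == 1), nPermut, seed, cache)
  (1 + sum(null >= s[2])) / (1 + nPermut)
}

permNull <- function(idx, tree, gene, nPos, nPermut, seed, cache = NULL) {
  key <- paste(canonicalGeneKey(tree, gene), nPos, nPermut, "v1", sep = "|")
  if (!is.null(cache)) {
    hit <- cacheGet(cache, key)
    if (!is.null(hit)) return(hit)
  }
  permSeed <- stableHash(seed, key)
  null <- perm_null_cpp(idx$children, idx$postorder, idx$leafNodes,
                        as.integer(gene), as.integer(nPos),
                        as.integer(nPermut), as.numeric(permSeed))
  if (!is.null(cache)) cacheSet(cache, key, null)
  null
}

#' Permutation-null cache
#'
#' A single-file key-value store for permutation null distributions, keyed
#' by (canonical gene pattern, trait-positive count, nPermut, seed-policy).
#' Values are deterministic given the master seed, so last-writer-wins is
#' safe. `newPermCache(path)` loads the file when it exists;
#' [savePermCache()] persists the store.
#'
#' @param path optional file path backing the cache; NULL = in-memory only.
#' @return An environment-backed cache object.
#' @export
newPermCache <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  assign(".format", "pairGWAS-permcache-1", envir = env)
  attr(env, "path") <- path
  if (!is.null(path) && file.exists(path)) {
    stored <- readRDS(path)
    if (!identical(stored$.format, "pairGWAS-permcache-1"))
      stop("unrecognized cache format", call. = FALSE)
    for (k in names(stored)) assign(k, stored[[k]], envir = env)
  }
  env
}

#' @rdname newPermCache
#' @param cache a cache from [newPermCache()].
#' @export
savePermCache <- function(cache) {
  path <- attr(cache, "path")
  if (is.null(path)) return(invisible(NULL))
  saveRDS(as.list(cache, all.names = TRUE), path)
  invisible(path)
}

cacheGet <- function(cache, key) {
  if (exists(key, envir = cache, inherits = FALSE))
    get(key, envir = cache) else NULL
}

cacheSet <- function(cache, key, value) assign(key, value, envir = cache)

#' Exhaustive contrasting-pairs reference (internal)
#'
#' Independent oracle used for validation: enumerates every set of
#' edge-disjoint contrasting leaf pairings by branch-and-bound over explicit
#' path edge bitmasks. Tractable to ~12 leaves.
#'
#' @param tree rooted binary `ape::phylo`.
#' @param gene,trait 0/1 vectors in tip order.
#' @return list(maxPairs, bestSupporting, worstSupporting).
#' @keywords internal
bruteForcePairSummary <- function(tree, gene, trait) {
  idx <- treeIndex(tree)
  lab <- as.integer(2L * gene + trait)
  s <- brute_force_pairs_cpp(idx$children, idx$postorder, idx$leafNodes, lab)
  list(maxPairs = s[1], bestSupporting = s[2], worstSupporting = s[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
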