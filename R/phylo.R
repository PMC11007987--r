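#' Parse a newick tree
#'
#' Reads a rooted tree from a newick string or file, strips square-bracket
#' comments, and normalizes to a binary tree: polytomies are resolved by a
#' left-fold over children in input order with zero-length edges (with a
#' warning, since contrasting-pair counts can depend on the resolution).
#' Branch lengths are carried but never used — only the branching pattern
#' matters to the pairwise-comparisons statistic.
#'
#' @param x newick string, or path to a newick file.
#' @return An `ape::phylo`, rooted and binary.
#' @export
parseNewick <- function(x) {
  text <- if (length(x) == 1 && !grepl("(", x, fixed = TRUE) &&
              file.exists(x)) paste(readLines(x), collapse = "") else x
  text <- gsub("\\[[^]]*\\]", "", text)
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes)
    stop(sprintf("unbalanced parentheses in newick: %d '(' vs %d ')'",
                 opens, closes), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop(sprintf("newick parse failed: %s",
                                                    conditionMessage(e)),
                                            call. = FALSE))
  if (is.null(tree)) stop("newick parse failed", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate leaf label '%s' in newick",
                 tree$tip.label[duplicated(tree$tip.label)][1]),
         call. = FALSE)
  normalizeTree(tree)
}

normalizeTree <- function(tree) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    warning("polytomies resolved to binary with zero-length edges; pair counts can depend on the resolution")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

#' Serialize a tree to newick
#'
#' @param tree an `ape::phylo`.
#' @return newick string (with trailing semicolon).
#' @export
serializeNewick <- function(tree) ape::write.tree(tree)

#' Infer a rooted tree from the genotype matrix
#'
#' Fallback when no phylogeny is supplied: UPGMA-style average-linkage
#' agglomeration on Hamming distances between binarized genotype rows.
#' Isolates are pre-sorted lexicographically so the result is deterministic
#' and invariant to input row order; identical genotype rows (distance 0)
#' join first.
#'
#' @param genotype a [GenotypeMatrix-class] with >= 4 isolates.
#' @return A rooted binary `ape::phylo`.
#' @export
inferTree <- function(genotype) {
  p <- genePresence(genotype)
  if (nrow(p) < 4) stop("tree inference requires >= 4 isolates",
                        call. = FALSE)
  p <- p[sort(rownames(p)), , drop = FALSE]
  d <- dist(p, method = "manhattan")  # Hamming count on 0/1 rows
  hc <- hclust(d, method = "average")
  normalizeTree(ape::as.phylo(hc))
}

#' Prune a tree to a set of leaves
#'
#' Removes all other leaves and collapses the resulting unary internal
#' nodes; the result is again binary.
#'
#' @param tree an `ape::phylo`.
#' @param keep character vector of leaf labels to retain (>= 2, all present
#'   in the tree).
#' @return Pruned `ape::phylo`.
#' @export
pruneTree <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop(sprintf("leaves not in tree: %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  if (length(keep) < 2) stop("need >= 2 leaves to keep", call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Convert an ape phylo into flat arrays for the C++ kernels: 0-based
# children matrix (-1 for leaves), an iterative (stack-based, never
# call-recursive) postorder over all nodes, and the node index of each leaf
# in tip.label order. Works on arbitrarily unbalanced trees.
treeIndex <- function(tree) {
  nTip <- length(tree$tip.label)
  nNodes <- nTip + tree$Nnode
  ch <- matrix(-1L, nNodes, 2)
  filled <- integer(nNodes)
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1]
    filled[p] <- filled[p] + 1L
    if (filled[p] > 2L)
      stop("tree is not binary after normalization", call. = FALSE)
    ch[p, filled[p]] <- e[k, 2] - 1L
  }
  if (any(filled > 0 & filled != 2L))
    stop("tree has unary internal nodes", call. = FALSE)
  root <- nTip + 1L
  # iterative postorder: reverse of (node, right-before-left preorder)
  stack <- integer(nNodes)
  out <- integer(nNodes)
  top <- 1L; stack[1] <- root - 1L
  nOut <- 0L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    nOut <- nOut + 1L; out[nOut] <- v
    if (ch[v + 1L, 1] >= 0L) {
      top <- top + 1L; stack[top] <- ch[v + 1L, 1]
      top <- top + 1L; stack[top] <- ch[v + 1L, 2]
    }
  }
  list(children = ch, postorder = rev(out), leafNodes = 0:(nTip - 1L),
       nTip = nTip, tipLabels = tree$tip.label)
}

#' Canonical key of a gene's presence pattern on a tree
#'
#' Two presence/absence vectors that induce isomorphic labeled topologies
#' (up to child-order swaps) share the same key, so their permutation nulls
#' can be computed once and cached. The key is built bottom-up: each node
#' combines the order-sorted keys of its children through two independent
#' modular rolling hashes (kept exact in double precision), which keeps the
#' computation linear and depth-independent even on very unbalanced trees.
#' The complement of a pattern gets a distinct key.
#'
#' @param tree an `ape::phylo` (binary).
#' @param gene 0/1 vector, named by tip label or aligned with
#'   `tree$tip.label`.
#' @return A string key; also encodes the leaf count and presence count.
#' @export
canonicalGeneKey <- function(tree, gene) {
  idx <- treeIndex(tree)
  g <- alignLeafVector(gene, idx$tipLabels)
  p1 <- 67108859; m1 <- 40503   # < 2^26 so products stay exact doubles
  p2 <- 67108837; m2 <- 30011
  h1 <- numeric(nrow(idx$children)); h2 <- numeric(nrow(idx$children))
  for (v in idx$postorder) {
    a <- idx$children[v + 1L, 1]
    if (a < 0L) {
      h1[v + 1L] <- g[v + 1L] + 2
      h2[v + 1L] <- g[v + 1L] + 5
    } else {
      b <- idx$children[v + 1L, 2]
      x1 <- sort(c(h1[a + 1L], h1[b + 1L]))
      x2 <- sort(c(h2[a + 1L], h2[b + 1L]))
      h1[v + 1L] <- ((x1[1] * m1 + x1[2]) %% p1 + 7) %% p1
      h2[v + 1L] <- ((x2[1] * m2 + x2[2]) %% p2 + 11) %% p2
    }
  }
  root <- idx$nTip + 1L
  sprintf("n%d.k%d.%.0f.%.0f", idx$nTip, sum(g), h1[root], h2[root])
}

# Align a leaf-indexed vector (possibly named) with the tree's tip labels.
alignLeafVector <- function(x, tipLabels) {
  if (!is.null(names(x))) {
    missing <- setdiff(tipLabels, names(x))
    if (length(missing))
      stop(sprintf("no value for leaf '%s'", missing[1]), call. = FALSE)
    x <- x[tipLabels]
  } else if (length(x) != length(tipLabels)) {
    stop("leaf vector length does not match the tree", call. = FALSE)
  }
  unname(x)
}

# Build a caterpillar (fully unbalanced) tree over the given labels without
# parsing a deep newick string; used for depth-independence checks and
# available to simulations.
caterpillarTree <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2)
  nNodes <- 2L * n - 1L
  edge <- matrix(0L, nNodes - 1L, 2)
  # internal nodes n+1 .. 2n-1; internal node n+i has children: leaf i and
  # internal n+i+1 (or leaf n at the bottom)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    k <- k + 1L
    edge[k, ] <- c(n + i, i)
    k <- k + 1L
    edge[k, ] <- c(n + i, if (i < n - 1L) n + i + 1L else n)
  }
  tree <- list(edge = edge, tip.label = labels, Nnode = n - 1L)
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}
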