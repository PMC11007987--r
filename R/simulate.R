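#' Random unstructured genotype/trait dataset
#'
#' i.i.d. Bernoulli(1/2) gene presence and a Bernoulli(1/2) binary trait,
#' used for runtime-scaling studies where no phylogenetic signal is wanted.
#'
#' @param nGenes,nGenomes dataset dimensions (>= 2).
#' @param seed RNG seed; the global RNG state is untouched.
#' @return list(genotype = [GenotypeMatrix-class], trait = named 0/1
#'   vector).
#' @export
randomDataset <- function(nGenes, nGenomes, seed = 1L) {
  stopifnot(nGenes >= 2, nGenomes >= 2)
  withSeed(seed, {
    iso <- sprintf("iso%04d", seq_len(nGenomes))
    og <- sprintf("og%04d", seq_len(nGenes))
    counts <- matrix(rbinom(nGenomes * nGenes, 1, 0.5), nGenomes, nGenes,
                     dimnames = list(iso, og))
    trait <- setNames(rbinom(nGenomes, 1, 0.5), iso)
    list(genotype = GenotypeMatrix(counts), trait = trait)
  })
}

# Random rooted bifurcating topology by uniform pairwise joining
# (coalescent-style): repeatedly merge two uniformly chosen lineages.
randomJoinTree <- function(labels) {
  n <- length(labels)
  nNodes <- 2L * n - 1L
  edge <- matrix(0L, nNodes - 1L, 2L)
  active <- seq_len(n)
  nextNode <- nNodes       # internal ids 2n-1 .. n+1, root ends at n+1
  k <- 0L
  while (length(active) > 1L) {
    pick <- sample.int(length(active), 2L)
    k <- k + 1L; edge[k, ] <- c(nextNode, active[pick[1]])
    k <- k + 1L; edge[k, ] <- c(nextNode, active[pick[2]])
    active <- c(active[-pick], nextNode)
    nextNode <- nextNode - 1L
  }
  # internal ids were assigned 2n-1 downwards, so the root (last created)
  # is n+1, matching the ape convention
  tree <- list(edge = edge, tip.label = labels, Nnode = n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# Evolve 0/1 characters down a tree: Bernoulli(1/2) root state, each branch
# flips the state with probability flipProb.
evolveGenes <- function(tree, nGenes, flipProb) {
  nTip <- length(tree$tip.label)
  nNodes <- nTip + tree$Nnode
  e <- ape::reorder.phylo(tree, "cladewise")$edge  # parents before children
  state <- matrix(0L, nNodes, nGenes)
  state[nTip + 1L, ] <- rbinom(nGenes, 1, 0.5)
  flips <- matrix(rbinom(nrow(e) * nGenes, 1, flipProb), nrow(e), nGenes)
  for (k in seq_len(nrow(e)))
    state[e[k, 2], ] <- bitwXor(state[e[k, 1], ], flips[k, ])
  state[seq_len(nTip), , drop = FALSE]
}

#' Simulate a tree-evolved pan-genome
#'
#' Draws a random bifurcating topology over the genomes, then evolves each
#' gene's presence/absence down the tree with a symmetric per-branch flip
#' probability — producing genotype columns that carry phylogenetic signal
#' (sister leaves agree more often than distant ones). Genes fixed across
#' all genomes are re-evolved until polymorphic; the designated causal gene
#' is additionally re-evolved until its presence frequency lies in
#' [20%, 80%].
#'
#' @param nGenomes number of genomes (>= 4).
#' @param nGenes total genes, causal included (default 101: one causal gene
#'   plus 100 background genes).
#' @param flipProb per-branch gain/loss probability (default 0.1).
#' @param seed RNG seed.
#' @param causalIndex column index of the causal gene.
#' @return list(tree, genotype, causal = causal orthogroup id).
#' @export
evolvePangenome <- function(nGenomes, nGenes = 101L, flipProb = 0.1,
                            seed = 1L, causalIndex = 1L) {
  stopifnot(nGenomes >= 4, nGenes >= 2)
  withSeed(seed, {
    iso <- sprintf("iso%04d", seq_len(nGenomes))
    og <- sprintf("og%04d", seq_len(nGenes))
    tree <- randomJoinTree(iso)
    m <- evolveGenes(tree, nGenes, flipProb)
    for (round in 1:1000) {
      freq <- colMeans(m)
      bad <- freq == 0 | freq == 1
      bad[causalIndex] <- freq[causalIndex] < 0.2 | freq[causalIndex] > 0.8
      if (!any(bad)) break
      m[, bad] <- evolveGenes(tree, sum(bad), flipProb)
    }
    dimnames(m) <- list(iso, og)
    list(tree = tree, genotype = GenotypeMatrix(m), causal = og[causalIndex])
  })
}

#' Simulate a numeric phenotype driven by one causal gene
#'
#' Genomes lacking the causal gene draw from N(0, 1); carriers draw from
#' N(effectSize, 1), so `effectSize` is the group separation in standard
#' deviations.
#'
#' @param genotype a [GenotypeMatrix-class].
#' @param causalGene orthogroup id of the causal gene (must be polymorphic).
#' @param effectSize mean shift for carriers, in sigma units.
#' @param seed RNG seed.
#' @return named numeric vector over isolates.
#' @export
simulatePhenotype <- function(genotype, causalGene, effectSize, seed = 1L) {
  pres <- genePresence(genotype)[, causalGene]
  if (length(unique(pres)) < 2)
    stop("causal gene must be polymorphic", call. = FALSE)
  withSeed(seed, setNames(rnorm(length(pres), mean = effectSize * pres),
                          names(pres)))
}

#' Causal-gene rank recovery benchmark
#'
#' The power study behind the automatic binarization: per replicate,
#' simulate a tree-evolved pan-genome and a Gaussian phenotype with the
#' given effect size, binarize (GMM with 0.85 cutoff and k-means fallback
#' by default), run the association, and record the 1-based rank of the
#' causal gene when orthogroups are sorted by ascending Fisher p (ties by
#' empirical permutation p where computed, then by orthogroup id). A trait
#' whose binarization is skipped scores rank nGenes + 1.
#'
#' @param nGenomes genomes per replicate (benchmark preset:
#'   25/50/75/100/150/200).
#' @param effectSize separation in sigma units (preset: 0.5/1/1.5/2/3).
#' @param nReplicates number of replicates (default 20).
#' @param seed master seed; replicate r uses a stream derived from
#'   (seed, r).
#' @param nGenes genes per replicate (default 101, one causal).
#' @param flipProb per-branch gain/loss probability.
#' @param config association/binarization settings ([pipelineConfig()]);
#'   the config seed is overridden per replicate.
#' @return integer vector of per-replicate ranks, with attributes
#'   `meanRank` and `band` (empirical 5th-95th percentile).
#' @export
rankRecovery <- function(nGenomes, effectSize, nReplicates = 20L, seed = 1L,
                         nGenes = 101L, flipProb = 0.1,
                         config = pipelineConfig()) {
  ranks <- integer(nReplicates)
  for (r in seq_len(nReplicates)) {
    repSeed <- stableHash(seed, "rank-recovery", r)
    sim <- evolvePangenome(nGenomes, nGenes = nGenes, flipProb = flipProb,
                           seed = repSeed)
    pheno <- simulatePhenotype(sim$genotype, sim$causal, effectSize,
                               seed = stableHash(repSeed, "pheno"))
    ranks[r] <- causalRank(sim, pheno, config, repSeed)
  }
  structure(ranks, meanRank = mean(ranks),
            band = unname(quantile(ranks, c(0.05, 0.95), type = 7)))
}

causalRank <- function(sim, pheno, config, repSeed) {
  nGenes <- ncol(geneCounts(sim$genotype))
  bin <- tryCatch({
    if (config$binarization == "gmm")
      binarizeGmm(pheno, posteriorCutoff = config$gmmCutoff,
                  onFailure = config$gmmOnFailure, traitId = "pheno")
    else binarizeKmeans(pheno, traitId = "pheno")
  }, error = function(e) NULL)
  if (is.null(bin)) return(nGenes + 1L)
  lab <- binaryLabels(bin)
  if (length(unique(lab[!is.na(lab)])) < 2) return(nGenes + 1L)
  res <- analyzeTrait(lab, sim$genotype, sim$tree,
                      config = modifyList(config, list(seed = repSeed)),
                      traitId = "pheno")
  ct <- res$fisher
  pe <- rep(1, nrow(ct))
  if (nrow(res$records))
    pe[match(res$records$orthogroup, ct$orthogroup)] <-
      res$records$p_empirical
  ord <- order(ct$p_fisher, pe, ct$orthogroup)
  which(ct$orthogroup[ord] == sim$causal)
}
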