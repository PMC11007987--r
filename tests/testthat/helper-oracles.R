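# Independent reference implementations and fixture builders used across the
# suite. Nothing here shares code with the package internals it checks.

# All rooted binary tree shapes with n leaves (Wedderburn-Etherington
# enumeration), as newick strings with leaves labeled t1..tn left to right.
allTreeShapes <- local({
  memo <- list("1" = "L")
  shapes <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- character(0)
    for (k in 1:(n %/% 2)) {
      left <- shapes(k); right <- shapes(n - k)
      for (i in seq_along(left)) {
        js <- if (2 * k == n) i:length(right) else seq_along(right)
        for (j in js) out <- c(out, sprintf("(%s,%s)", left[i], right[j]))
      }
    }
    memo[[key]] <<- out
    out
  }
  function(n) {
    vapply(shapes(n), function(s) {
      leaves <- sprintf("t%d", seq_len(n))
      for (lab in leaves) s <- sub("L", lab, s, fixed = TRUE)
      paste0(s, ";")
    }, character(1), USE.NAMES = FALSE)
  }
})

# Exhaustive permutation-test value: P(best_supporting >= observed) under a
# uniformly random permutation of the trait labels. Uses the brute-force
# pairing oracle for the statistic and enumerates distinct arrangements of
# the trait multiset (each equally likely under uniform permutation).
exhaustivePermP <- function(tree, gene, trait) {
  n <- length(trait)
  obs <- pairGWAS:::bruteForcePairSummary(tree, gene, trait)$bestSupporting
  pos <- sum(trait)
  hits <- 0; total <- 0
  for (comb in asplit(utils::combn(n, pos), 2)) {
    tr <- integer(n); tr[comb] <- 1L
    st <- pairGWAS:::bruteForcePairSummary(tree, gene, tr)$bestSupporting
    total <- total + 1
    if (st >= obs) hits <- hits + 1
  }
  hits / total
}

# Benjamini-Hochberg step-up q-values straight from the definition.
bhQvalues <- function(p, m = length(p)) {
  o <- order(p)
  q <- numeric(length(p))
  qo <- pmin(1, m * p[o] / seq_along(o))
  qo <- rev(cummin(rev(qo)))
  q[o] <- qo
  q
}

# Exhaustive best 2-partition of a numeric vector by total within-cluster
# squared distance, over ALL 2^(n-1)-1 splits (not just contiguous ones).
bestTwoPartition <- function(x) {
  n <- length(x)
  best <- Inf; bestAssign <- NULL
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(a) || all(a)) next
    sse <- sum((x[a] - mean(x[a]))^2) + sum((x[!a] - mean(x[!a]))^2)
    if (sse < best - 1e-12) { best <- sse; bestAssign <- a }
  }
  # orient: TRUE = larger-mean side
  if (mean(x[bestAssign]) < mean(x[!bestAssign])) bestAssign <- !bestAssign
  as.integer(bestAssign)
}

# Small aligned fixture: tree-evolved genotypes plus one causal numeric
# trait, one null numeric trait and one binary trait.
makeFixture <- function(nGenomes = 20, nGenes = 30, seed = 421) {
  sim <- evolvePangenome(nGenomes, nGenes = nGenes, seed = seed)
  ph <- simulatePhenotype(sim$genotype, sim$causal, 3, seed = seed + 1)
  iso <- isolateIds(sim$genotype)
  set.seed(seed + 2)
  vals <- cbind(causal_metab = ph,
                null_metab = setNames(rnorm(nGenomes), iso),
                marker = setNames(rbinom(nGenomes, 1, 0.5), iso))
  list(sim = sim, traits = TraitTable(vals))
}

writeFixtureFiles <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gPath <- file.path(dir, "genotype.tsv")
  tPath <- file.path(dir, "traits.tsv")
  nPath <- file.path(dir, "tree.nwk")
  writeGenotype(fix$sim$genotype, gPath)
  writeTraits(fix$traits, tPath)
  writeLines(serializeNewick(fix$sim$tree), nPath)
  list(genotype = gPath, traits = tPath, tree = nPath)
}
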