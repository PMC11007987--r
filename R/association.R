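#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Probability-mass definition: the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (with the standard 1 + 1e-7 relative slack against
#' floating-point ties). A zero margin leaves a single admissible table and
#' returns p = 1. Vectorized over table entries.
#'
#' @param tp,fp,fn,tn cell counts: gene+trait+, gene+trait-, gene-trait+,
#'   gene-trait-.
#' @return p-values in (0, 1].
#' @export
fisherExact <- function(tp, fp, fn, tn) {
  n <- length(tp)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- tp[i]; m1 <- tp[i] + fp[i]; c1 <- tp[i] + fn[i]
    tot <- tp[i] + fp[i] + fn[i] + tn[i]
    lo <- max(0, c1 + m1 - tot); hi <- min(c1, m1)
    if (lo == hi) { out[i] <- 1; next }
    k <- lo:hi
    pr <- dhyper(k, m1, tot - m1, c1)
    out[i] <- min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
  }
  pFloor(out)
}

#' Descriptive association statistics for a 2x2 table
#'
#' @inheritParams fisherExact
#' @return data.frame with odds_ratio ((tp*tn)/(fp*fn); 0/0 = NA, x/0 =
#'   Inf), sensitivity (tp/(tp+fn)) and specificity (tn/(tn+fp)); undefined
#'   margins give NA.
#' @export
descriptiveStats <- function(tp, fp, fn, tn) {
  num <- tp * tn; den <- fp * fn
  or <- ifelse(num == 0 & den == 0, NA_real_,
        ifelse(den == 0, Inf, num / den))
  sens <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  spec <- ifelse(tn + fp == 0, NA_real_, tn / (tn + fp))
  data.frame(odds_ratio = or, sensitivity = sens, specificity = spec)
}

#' Multiple-testing correction
#'
#' @param p p-values in (0, 1].
#' @param method "native" (no correction), "bonferroni", or "fdr_bh"
#'   (Benjamini-Hochberg step-up).
#' @param m pool size; defaults to `length(p)`. Under global-scope
#'   correction the caller pools p-values across traits before calling.
#' @return q-values, same length as p.
#' @export
correctPvalues <- function(p, method = c("native", "bonferroni", "fdr_bh"),
                           m = length(p)) {
  method <- match.arg(method)
  switch(method,
         native = p,
         bonferroni = pmin(1, p * m),
         fdr_bh = p.adjust(p, method = "BH", n = m))
}

#' Parse a "method:alpha" multiple-testing configuration string
#'
#' @param x e.g. "fdr_bh:0.1", "bonferroni:0.999", "native:0.05".
#' @return list(method, alpha).
#' @export
parseMultipleTesting <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop(sprintf("multiple-testing spec '%s' must be 'method:alpha'", x),
         call. = FALSE)
  method <- parts[1]
  if (!method %in% c("native", "bonferroni", "fdr_bh"))
    stop(sprintf("unknown multiple-testing method '%s'", method),
         call. = FALSE)
  alpha <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(alpha) || alpha <= 0 || alpha > 1)
    stop(sprintf("alpha '%s' must be in (0, 1]", parts[2]), call. = FALSE)
  list(method = method, alpha = alpha)
}

#' Pipeline configuration
#'
#' @param multipleTesting "method:alpha" string gating which orthogroups
#'   survive the Fisher stage (default "fdr_bh:0.1").
#' @param traitWise correct within each trait (TRUE) or pool Fisher
#'   p-values across all traits and orthogroups (FALSE).
#' @param nPermut permutations for the label-switching test.
#' @param maxGenes per-trait cap on reported orthogroups (Fisher-ranked).
#' @param nCpus worker processes for per-trait analysis; results are
#'   identical for any value.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it by stable hashing.
#' @param binarization,gmmCutoff,gmmOnFailure numeric-trait binarization
#'   settings.
#' @param permuteAll run the permutation test for every orthogroup instead
#'   of only Fisher-significant ones.
#' @param cachePath optional permutation-cache file.
#' @return list of validated settings.
#' @export
pipelineConfig <- function(multipleTesting = "fdr_bh:0.1", traitWise = TRUE,
                           nPermut = 1000L, maxGenes = 50L, nCpus = 1L,
                           seed = 1L, binarization = c("gmm", "kmeans"),
                           gmmCutoff = 0.85,
                           gmmOnFailure = c("kmeans", "skip"),
                           permuteAll = FALSE, cachePath = NULL) {
  mt <- parseMultipleTesting(multipleTesting)
  stopifnot(nPermut >= 100, maxGenes >= 1, nCpus >= 1)
  list(multipleTesting = multipleTesting, method = mt$method,
       alpha = mt$alpha, traitWise = isTRUE(traitWise),
       nPermut = as.integer(nPermut), maxGenes = as.integer(maxGenes),
       nCpus = as.integer(nCpus), seed = as.integer(seed),
       binarization = match.arg(binarization), gmmCutoff = gmmCutoff,
       gmmOnFailure = match.arg(gmmOnFailure),
       permuteAll = isTRUE(permuteAll), cachePath = cachePath)
}

# Contingency tables of every orthogroup against one binary trait vector
# (NA entries dropped). presence: isolates x orthogroups 0/1.
contingencyTables <- function(presence, trait) {
  obs <- !is.na(trait)
  p <- presence[obs, , drop = FALSE]
  tr <- trait[obs]
  tp <- colSums(p[tr == 1, , drop = FALSE])
  fp <- colSums(p[tr == 0, , drop = FALSE])
  data.frame(orthogroup = colnames(presence), tp = tp, fp = fp,
             fn = sum(tr == 1) - tp, tn = sum(tr == 0) - fp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analyze one binary(-ized) trait against all orthogroups
#'
#' Builds a contingency table and a two-sided Fisher p per orthogroup,
#' applies the configured multiple-testing correction (trait-wise by
#' default; pass `qvalues` for globally pooled correction), and runs the
#' contrasting-pairs statistic plus the label-switching permutation test
#' for the orthogroups whose q-value passes the gate. Records are sorted by
#' ascending Fisher p (ties by orthogroup id) and truncated to
#' `config$maxGenes`.
#'
#' @param trait named 0/1 vector over isolates; NA = missing/abstained.
#' @param genotype aligned [GenotypeMatrix-class].
#' @param tree aligned rooted binary `ape::phylo`.
#' @param config a [pipelineConfig()].
#' @param traitId identifier for reports and seed derivation.
#' @param qvalues optional pre-computed q-values (global scope), aligned
#'   with orthogroup order.
#' @param cache optional permutation cache.
#' @return list(traitId, records, significant, nObserved, fisher) where
#'   `fisher` holds the full per-orthogroup Fisher results (used for
#'   ranking) and `records` only the gate-surviving orthogroups with pair
#'   statistics.
#' @export
analyzeTrait <- function(trait, genotype, tree, config = pipelineConfig(),
                         traitId = "trait", qvalues = NULL, cache = NULL) {
  presence <- genePresence(genotype)
  trait <- trait[rownames(presence)]
  ct <- contingencyTables(presence, trait)
  ct$p_fisher <- fisherExact(ct$tp, ct$fp, ct$fn, ct$tn)
  ct$q_fisher <- if (is.null(qvalues))
    correctPvalues(ct$p_fisher, config$method) else qvalues
  ct <- cbind(ct, descriptiveStats(ct$tp, ct$fp, ct$fn, ct$tn))
  pass <- which(ct$q_fisher <= config$alpha | config$permuteAll)
  rec <- ct[pass, , drop = FALSE]
  if (nrow(rec)) {
    rec <- rec[order(rec$p_fisher, rec$orthogroup), , drop = FALSE]
    rec <- head(rec, config$maxGenes)
    stats <- lapply(rec$orthogroup, function(og) {
      g <- presence[, og]
      ps <- maxContrastingPairs(tree, g, trait)
      pe <- permutationTest(tree, g, trait, nPermut = config$nPermut,
                            seed = config$seed, cache = cache)
      c(max_pairs = ps$maxPairs, best_supporting = ps$bestSupporting,
        worst_supporting = ps$worstSupporting, p_best = ps$pBest,
        p_worst = ps$pWorst, p_empirical = pe)
    })
    rec <- cbind(rec, do.call(rbind, stats))
  } else {
    rec <- cbind(rec, max_pairs = integer(0), best_supporting = integer(0),
                 worst_supporting = integer(0), p_best = numeric(0),
                 p_worst = numeric(0), p_empirical = numeric(0))
  }
  rownames(rec) <- NULL
  sig <- any(ct$q_fisher <= config$alpha)
  list(traitId = traitId, records = rec, significant = sig,
       nObserved = sum(!is.na(trait)), fisher = ct)
}
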