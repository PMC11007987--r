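sanitizeId <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full association pipeline
#'
#' read -> align -> binarize numeric traits -> per-trait association
#' (Fisher gate, contrasting pairs, permutation test) -> multiple-testing
#' correction (trait-wise or globally pooled) -> result tables and report
#' bundles. Traits are independent work units; with `config$nCpus > 1` they
#' are processed by forked workers, and because every stochastic stage
#' derives its stream from the master seed and stable identifiers the
#' outputs are identical for any worker count and any schedule.
#'
#' @param genotype [GenotypeMatrix-class] or path to a genotype table.
#' @param traits [TraitTable-class] or path to a trait table.
#' @param tree `ape::phylo`, newick path/string, or NULL to infer a UPGMA
#'   tree from the genotype matrix.
#' @param outDir output directory; NULL skips all file output.
#' @param config a [pipelineConfig()].
#' @param isolateMetadata,traitMetadata,orthogroupMetadata optional
#'   metadata data.frames keyed by `id` (see [readMetadata()]).
#' @param linkGeneUrl,linkOrthogroupUrl URL templates for report bundles.
#' @return invisibly, list(results, binarization, aligned, config).
#' @export
runPipeline <- function(genotype, traits, tree = NULL, outDir = NULL,
                        config = pipelineConfig(), isolateMetadata = NULL,
                        traitMetadata = NULL, orthogroupMetadata = NULL,
                        linkGeneUrl = NULL, linkOrthogroupUrl = NULL) {
  t0 <- Sys.time()
  logLines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    message(line)
  }
  if (is.character(traits)) traits <- readTraits(traits)
  if (is.character(genotype))
    genotype <- readGenotype(genotype, isolateIdsHint = isolateIds(traits))
  if (is.character(tree)) tree <- parseNewick(tree)
  al <- alignInputs(genotype, traits, tree)
  if (is.null(al$tree)) {
    note("no tree supplied; inferring UPGMA tree from genotypes")
    al$tree <- inferTree(al$genotype)
  }
  note("aligned: %d isolates, %d orthogroups, %d traits",
       length(isolateIds(al$genotype)), length(orthogroupIds(al$genotype)),
       length(traitIds(al$traits)))

  bin <- binarizeTraits(al$traits, method = config$binarization,
                        posteriorCutoff = config$gmmCutoff,
                        onFailure = config$gmmOnFailure)
  ids <- colnames(bin$labels)

  qByTrait <- setNames(vector("list", length(ids)), ids)
  if (!config$traitWise) {
    presence <- genePresence(al$genotype)
    pmat <- vapply(ids, function(id) {
      ct <- contingencyTables(presence, bin$labels[, id])
      fisherExact(ct$tp, ct$fp, ct$fn, ct$tn)
    }, numeric(length(orthogroupIds(al$genotype))))
    qAll <- correctPvalues(as.vector(pmat), config$method)
    qmat <- matrix(qAll, nrow(pmat), ncol(pmat), dimnames = dimnames(pmat))
    for (id in ids) qByTrait[[id]] <- qmat[, id]
  }

  cache <- if (!is.null(config$cachePath)) newPermCache(config$cachePath)
           else newPermCache()
  analyzeOne <- function(id) {
    tStart <- Sys.time()
    localCache <- newPermCache()
    for (k in ls(cache, all.names = FALSE))
      cacheSet(localCache, k, cacheGet(cache, k))
    res <- analyzeTrait(bin$labels[, id], al$genotype, al$tree,
                        config = config, traitId = id,
                        qvalues = qByTrait[[id]], cache = localCache)
    res$seconds <- as.numeric(difftime(Sys.time(), tStart, units = "secs"))
    res$cacheEntries <- as.list(localCache, all.names = FALSE)
    res
  }
  results <- if (config$nCpus > 1) {
    parallel::mclapply(ids, analyzeOne, mc.cores = config$nCpus,
                       mc.preschedule = TRUE)
  } else {
    lapply(ids, analyzeOne)
  }
  names(results) <- ids
  for (res in results) {
    for (k in names(res$cacheEntries)) cacheSet(cache, k, res$cacheEntries[[k]])
  }
  savePermCache(cache)
  for (id in ids)
    note("trait %s: %d candidates, significant=%s, %.2fs", id,
         nrow(results[[id]]$records), results[[id]]$significant,
         results[[id]]$seconds)

  if (!is.null(outDir)) {
    writeResults(results, outDir, genotype = al$genotype, tree = al$tree,
                 traits = al$traits, binarization = bin, config = config,
                 isolateMetadata = isolateMetadata,
                 orthogroupMetadata = orthogroupMetadata,
                 linkGeneUrl = linkGeneUrl,
                 linkOrthogroupUrl = linkOrthogroupUrl)
    note("results written to %s (%.1fs total)", outDir,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  invisible(list(results = results, binarization = bin, aligned = al,
                 config = config))
}

#' Write all result tables for a finished run
#'
#' Emits `summary.tsv` (one row per trait with at least one orthogroup
#' surviving the Fisher q gate — traits without one are omitted),
#' `binarization.tsv`, the overview files, `config.tsv`, and one directory
#' per surviving trait under `traits/` holding `result.tsv` (records
#' sorted by ascending Fisher p) plus the [traitBundle()] files. Reruns on
#' identical inputs produce byte-identical tables.
#'
#' @param results named list of [analyzeTrait()] results.
#' @param outDir output directory.
#' @param genotype,tree,traits aligned inputs.
#' @param binarization result of [binarizeTraits()].
#' @param config the [pipelineConfig()] used.
#' @param isolateMetadata,orthogroupMetadata optional metadata frames.
#' @param linkGeneUrl,linkOrthogroupUrl URL templates.
#' @return invisibly, `outDir`.
#' @export
writeResults <- function(results, outDir, genotype, tree, traits,
                         binarization = NULL, config = pipelineConfig(),
                         isolateMetadata = NULL, orthogroupMetadata = NULL,
                         linkGeneUrl = NULL, linkOrthogroupUrl = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgDf <- data.frame(key = names(config),
                      value = vapply(config, function(x)
                        if (is.null(x)) "" else as.character(x), ""),
                      stringsAsFactors = FALSE)
  writeTsv(cfgDf, file.path(outDir, "config.tsv"))
  if (!is.null(binarization))
    writeTsv(binarization$log, file.path(outDir, "binarization.tsv"))

  sig <- Filter(function(r) r$significant && nrow(r$records) > 0, results)
  summary <- do.call(rbind, lapply(sig, function(r) {
    data.frame(trait = r$traitId, n_candidates = nrow(r$records),
               n_observed = r$nObserved,
               best_orthogroup = r$records$orthogroup[1],
               best_p_fisher = min(r$records$p_fisher),
               best_q_fisher = min(r$records$q_fisher),
               best_p_empirical = min(r$records$p_empirical),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(trait = character(0), n_candidates = integer(0),
                          n_observed = integer(0),
                          best_orthogroup = character(0),
                          best_p_fisher = numeric(0),
                          best_q_fisher = numeric(0),
                          best_p_empirical = numeric(0))
  writeTsv(summary[order(summary$best_p_fisher, summary$trait), ,
                   drop = FALSE],
           file.path(outDir, "summary.tsv"))

  vals <- traitValues(traits)
  kinds <- traitKinds(traits)
  labels <- if (is.null(binarization)) NULL else binarization$labels
  for (r in sig) {
    dir <- file.path(outDir, "traits", sanitizeId(r$traitId))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(r$records, file.path(dir, "result.tsv"))
    lab <- if (!is.null(labels) && r$traitId %in% colnames(labels))
      labels[, r$traitId] else vals[, r$traitId]
    raw <- if (kinds[[r$traitId]] == "numeric") vals[, r$traitId] else NULL
    traitBundle(r, genotype, tree, dir, trait = lab, rawValues = raw,
                isolateMetadata = isolateMetadata,
                orthogroupMetadata = orthogroupMetadata,
                linkGeneUrl = linkGeneUrl,
                linkOrthogroupUrl = linkOrthogroupUrl)
  }
  if (length(sig) >= 1) {
    sigIds <- vapply(sig, `[[`, "", "traitId")
    tsub <- new("TraitTable",
                values = vals[, sigIds, drop = FALSE],
                kinds = unname(kinds[sigIds]))
    D <- if (length(sigIds) >= 2)
      traitDistances(tsub, binarized = labels) else
      matrix(0, 1, 1, dimnames = list(sigIds, sigIds))
    overviewFigure(D, sig, outDir)
  }
  invisible(outDir)
}
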