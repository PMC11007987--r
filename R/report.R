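jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

#' Symmetrized distances between traits
#'
#' Distance matrix over (significant) traits for the overview dendrogram.
#' Numeric-numeric pairs use 1 - |Pearson r| over co-observed isolates;
#' binary-binary pairs use 1 - max(J(a,b), J(a, not-b)) with Jaccard index
#' J; mixed pairs compare the numeric trait's binarized view with the
#' binary trait. Each metric is symmetrized so strongly anti-correlated
#' traits are as close as strongly correlated ones. Pairs with fewer than 3
#' co-observed isolates, and zero-variance traits, get distance 1.
#'
#' @param traits a [TraitTable-class] (already restricted to the traits to
#'   plot).
#' @param binarized optional isolate x trait 0/1 matrix of binarized views
#'   (from [binarizeTraits()]), required for mixed pairs.
#' @return symmetric matrix with zero diagonal.
#' @export
traitDistances <- function(traits, binarized = NULL) {
  v <- traitValues(traits)
  kinds <- traitKinds(traits)
  ids <- colnames(v)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  zeroVar <- vapply(seq_len(n), function(j) {
    x <- v[, j][!is.na(v[, j])]
    length(unique(x)) < 2
  }, logical(1))
  if (any(zeroVar))
    warning(sprintf("zero-variance trait(s) placed at distance 1: %s",
                    paste(ids[zeroVar], collapse = ", ")))
  colOf <- function(j) {
    if (kinds[[ids[j]]] == "numeric" && !is.null(binarized) &&
        ids[j] %in% colnames(binarized)) binarized[, ids[j]] else v[, j]
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 1
      if (!zeroVar[i] && !zeroVar[j]) {
        bothNum <- kinds[[ids[i]]] == "numeric" && kinds[[ids[j]]] == "numeric"
        if (bothNum) {
          ok <- complete.cases(v[, i], v[, j])
          if (sum(ok) >= 3) {
            r <- suppressWarnings(cor(v[ok, i], v[ok, j]))
            d <- if (is.na(r)) 1 else 1 - abs(r)
          }
        } else {
          a <- colOf(i); b <- colOf(j)
          ok <- complete.cases(a, b)
          if (sum(ok) >= 3) {
            a <- a[ok] == 1; b <- b[ok] == 1
            d <- 1 - max(jaccard(a, b), jaccard(a, !b))
          }
        }
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Trait overview: dendrogram order and -log10 p-value panels
#'
#' Clusters the significant traits by average linkage on
#' [traitDistances()] and writes, per trait: -log10 of the best (smallest)
#' Fisher q-value, of the best empirical permutation p, and of their
#' product, aligned with the dendrogram leaf order. With a single trait no
#' dendrogram is computed. Output files: `overview_order.tsv`,
#' `overview_pvalues.tsv` and `overview.png` (bars in leaf order next to
#' the dendrogram).
#'
#' @param dist matrix from [traitDistances()].
#' @param results list of per-trait results from [analyzeTrait()].
#' @param outDir output directory (created if needed).
#' @param plot write the PNG (TRUE); the TSVs are always written.
#' @return invisibly, the leaf-ordered data.frame of panel values.
#' @export
overviewFigure <- function(dist, results, outDir, plot = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(rownames(dist))
  dist <- dist[ids, ids, drop = FALSE]
  byId <- setNames(results, vapply(results, `[[`, "", "traitId"))
  panel <- do.call(rbind, lapply(ids, function(id) {
    rec <- byId[[id]]$records
    q <- if (nrow(rec)) min(rec$q_fisher) else 1
    pe <- if (nrow(rec)) min(rec$p_empirical) else 1
    data.frame(trait = id, neglog_q_fisher = -log10(pFloor(q)),
               neglog_p_empirical = -log10(pFloor(pe)),
               neglog_product = -log10(pFloor(q * pe)),
               stringsAsFactors = FALSE)
  }))
  if (length(ids) >= 2) {
    hc <- hclust(as.dist(dist), method = "average")
    ord <- hc$order
  } else {
    hc <- NULL
    ord <- seq_along(ids)
  }
  panel <- panel[ord, , drop = FALSE]
  writeTsv(data.frame(position = seq_along(ids), trait = panel$trait),
           file.path(outDir, "overview_order.tsv"))
  writeTsv(panel, file.path(outDir, "overview_pvalues.tsv"))
  if (plot) {
    grDevices::png(file.path(outDir, "overview.png"), width = 900,
                   height = max(300, 18 * length(ids) + 120), res = 96)
    on.exit(grDevices::dev.off())
    if (!is.null(hc)) {
      graphics::layout(matrix(1:2, 1, 2), widths = c(1, 2))
      graphics::par(mar = c(4, 1, 2, 0))
      graphics::plot(ape::as.phylo(hc), cex = 0.7)
    } else {
      graphics::par(mar = c(4, 8, 2, 1))
    }
    graphics::par(mar = c(4, 8, 2, 1))
    m <- t(as.matrix(panel[, c("neglog_q_fisher", "neglog_p_empirical",
                               "neglog_product")]))
    graphics::barplot(m, beside = TRUE, horiz = TRUE,
                      names.arg = panel$trait, las = 1, cex.names = 0.6,
                      col = c("#1b9e77", "#d95f02", "#7570b3"),
                      xlab = "-log10(p)")
    graphics::legend("topright", legend = c("f (Fisher q)",
                                            "e (empirical p)", "* (product)"),
                     fill = c("#1b9e77", "#d95f02", "#7570b3"), cex = 0.7)
  }
  invisible(panel)
}

#' Per-trait data bundle
#'
#' Writes the static files a result viewer needs for one trait into
#' `outDir`: `tree.nwk` (the isolate tree), `stats.tsv` (candidate
#' records, pie counts g+t+/g+t-/g-t+/g-t-, joined orthogroup metadata),
#' `coverage.tsv` (isolates x candidate orthogroups gene counts, trait
#' class per isolate, joined isolate metadata), `genes.tsv` (gene
#' identifier lists, when available), `values.tsv` (for numeric traits:
#' raw value plus trait class, with abstained isolates labeled `excluded`),
#' and `app_config.json` carrying hyperlink URL templates verbatim.
#'
#' @param result one trait's result from [analyzeTrait()].
#' @param genotype aligned [GenotypeMatrix-class].
#' @param tree aligned `ape::phylo`.
#' @param outDir output directory for this trait.
#' @param trait named binary labels used in the association (NA =
#'   missing/abstained).
#' @param rawValues optional named numeric vector of the original
#'   (pre-binarization) trait values.
#' @param isolateMetadata,orthogroupMetadata optional data.frames keyed by
#'   `id`.
#' @param linkGeneUrl,linkOrthogroupUrl URL templates with an `{id}`
#'   placeholder, copied verbatim into the config block.
#' @return invisibly, the output directory.
#' @export
traitBundle <- function(result, genotype, tree, outDir, trait,
                        rawValues = NULL, isolateMetadata = NULL,
                        orthogroupMetadata = NULL,
                        linkGeneUrl = NULL, linkOrthogroupUrl = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(serializeNewick(tree), file.path(outDir, "tree.nwk"))
  rec <- result$records
  trait <- trait[isolateIds(genotype)]
  obs <- !is.na(trait)
  counts <- geneCounts(genotype)
  pres <- genePresence(genotype)
  cand <- rec$orthogroup
  pie <- t(vapply(cand, function(og) {
    g <- pres[obs, og] == 1
    tt <- trait[obs] == 1
    c(gp_tp = sum(g & tt), gp_tn = sum(g & !tt),
      gn_tp = sum(!g & tt), gn_tn = sum(!g & !tt))
  }, integer(4)))
  if (!length(cand))
    pie <- matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("gp_tp", "gp_tn", "gn_tp",
                                          "gn_tn")))
  stats <- cbind(rec, pie)
  if (!is.null(orthogroupMetadata)) {
    m <- match(stats$orthogroup, orthogroupMetadata$id)
    if (anyNA(m) && length(cand))
      warning("some orthogroups have no metadata entry")
    stats <- cbind(stats,
                   orthogroupMetadata[m, setdiff(colnames(orthogroupMetadata),
                                                 "id"), drop = FALSE])
  }
  writeTsv(stats, file.path(outDir, "stats.tsv"))
  covClass <- ifelse(is.na(trait), "excluded", as.character(trait))
  cov <- data.frame(isolate = isolateIds(genotype), trait_class = covClass,
                    counts[, cand, drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(isolateMetadata)) {
    m <- match(cov$isolate, isolateMetadata$id)
    if (anyNA(m)) warning("some isolates have no metadata entry")
    cov <- cbind(cov, isolateMetadata[m, setdiff(colnames(isolateMetadata),
                                                 "id"), drop = FALSE])
  }
  writeTsv(cov, file.path(outDir, "coverage.tsv"))
  gl <- geneLists(genotype)
  if (!is.null(gl) && length(cand)) {
    cells <- matrix(vapply(gl[, cand, drop = FALSE], paste, character(1),
                           collapse = ";"),
                    nrow(counts), length(cand),
                    dimnames = list(NULL, cand))
    writeTsv(data.frame(isolate = isolateIds(genotype), cells,
                        check.names = FALSE, stringsAsFactors = FALSE),
             file.path(outDir, "genes.tsv"))
  }
  if (!is.null(rawValues)) {
    rawValues <- rawValues[isolateIds(genotype)]
    writeTsv(data.frame(isolate = isolateIds(genotype), value = rawValues,
                        trait_class = covClass, stringsAsFactors = FALSE),
             file.path(outDir, "values.tsv"))
  }
  cfg <- list(trait = result$traitId,
              link_gene_url = linkGeneUrl,
              link_orthogroup_url = linkOrthogroupUrl)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(outDir, "app_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
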