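test_that("Fisher p matches closed forms on canonical tables", {
  expect_equal(fisherExact(5, 5, 5, 5), 1)
  # perfectly associated 10/10 table: both extreme tables, each 1/C(20,10)
  expect_equal(fisherExact(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # transpose symmetry
  set.seed(40)
  for (i in 1:25) {
    tb <- rmultinom(1, sample(10:60, 1), c(0.3, 0.2, 0.3, 0.2))
    expect_equal(fisherExact(tb[1], tb[2], tb[3], tb[4]),
                 fisherExact(tb[1], tb[3], tb[2], tb[4]))
  }
  # zero margin leaves a single admissible table
  expect_equal(fisherExact(0, 0, 7, 13), 1)
  expect_equal(fisherExact(4, 6, 0, 0), 1)
})

test_that("Fisher p agrees with the reference implementation", {
  set.seed(41)
  for (i in 1:60) {
    tb <- rmultinom(1, sample(8:80, 1), runif(4, 0.05, 0.5))
    mine <- fisherExact(tb[1], tb[2], tb[3], tb[4])
    ref <- fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(mine, min(1, ref), tolerance = 1e-10)
  }
})

test_that("descriptive statistics follow their definitions", {
  d <- descriptiveStats(10, 0, 0, 10)
  expect_equal(d$odds_ratio, Inf)
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  d2 <- descriptiveStats(5, 5, 5, 5)
  expect_equal(unlist(d2), c(odds_ratio = 1, sensitivity = 0.5,
                             specificity = 0.5))
  d3 <- descriptiveStats(8, 2, 1, 9)
  expect_equal(d3$odds_ratio, 36)
  expect_equal(d3$sensitivity, 8 / 9)
  expect_equal(d3$specificity, 9 / 11)
  expect_true(is.na(descriptiveStats(0, 3, 0, 4)$odds_ratio))
})

test_that("multiple-testing correction follows each method's definition", {
  expect_equal(correctPvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1.0))
  expect_equal(correctPvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh"),
               rep(0.04, 4))
  p <- runif(10)
  expect_identical(correctPvalues(p, "native"), p)
  # BH q-values against the step-up definition, random vectors
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(correctPvalues(p, "fdr_bh"), bhQvalues(p))
    q <- correctPvalues(p, "fdr_bh")
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    # thresholding q <= alpha reproduces step-up rejection
    for (alpha in c(0.05, 0.2, 0.5)) {
      ps <- sort(p)
      k <- which(ps <= alpha * seq_along(ps) / length(ps))
      rejected <- if (length(k)) p <= ps[max(k)] else rep(FALSE, length(p))
      expect_equal(q <= alpha, rejected)
    }
  }
})

test_that("method:alpha configuration strings are validated", {
  expect_equal(parseMultipleTesting("fdr_bh:0.1"),
               list(method = "fdr_bh", alpha = 0.1))
  expect_equal(parseMultipleTesting("bonferroni:0.999")$alpha, 0.999)
  expect_error(parseMultipleTesting("bonferroni:1.5"), "\\(0, 1\\]")
  expect_error(parseMultipleTesting("tukey:0.1"), "unknown")
  expect_error(parseMultipleTesting("fdr_bh"), "method:alpha")
})

test_that("analyzeTrait gates on q, sorts by p, and truncates", {
  fix <- makeFixture(40, 40, seed = 50)
  bt <- binarizeTraits(fix$traits, method = "gmm")
  lab <- bt$labels[, "causal_metab"]
  cfg <- pipelineConfig(multipleTesting = "fdr_bh:0.1", maxGenes = 5,
                        nPermut = 200, seed = 4)
  res <- analyzeTrait(lab, fix$sim$genotype, fix$sim$tree, config = cfg,
                      traitId = "causal_metab")
  expect_true(res$significant)
  expect_lte(nrow(res$records), 5)
  expect_true(all(diff(res$records$p_fisher) >= 0))
  expect_true(all(res$records$q_fisher <= 0.1))
  expect_equal(res$records$orthogroup[1], fix$sim$causal)
  expect_true(all(res$records$p_empirical >= 1 / 201 &
                  res$records$p_empirical <= 1))
  # full Fisher table covers every orthogroup
  expect_setequal(res$fisher$orthogroup, orthogroupIds(fix$sim$genotype))
})

test_that("a constant gene column can never be significant", {
  fix <- makeFixture(20, 10, seed = 51)
  cts <- geneCounts(fix$sim$genotype)
  cts[, 5] <- 1L
  g <- GenotypeMatrix(cts)
  lab <- binarizeTraits(fix$traits, method = "kmeans")$labels[, "causal_metab"]
  res <- analyzeTrait(lab, g, fix$sim$tree, config = pipelineConfig(seed = 1))
  og5 <- res$fisher[res$fisher$orthogroup == orthogroupIds(g)[5], ]
  expect_equal(og5$p_fisher, 1)
  expect_false(orthogroupIds(g)[5] %in% res$records$orthogroup)
})

test_that("duplicated orthogroups yield identical records", {
  fix <- makeFixture(24, 30, seed = 52)
  cts <- geneCounts(fix$sim$genotype)
  dup <- cbind(cts, zz_dup = cts[, fix$sim$causal])
  g <- GenotypeMatrix(dup)
  lab <- binarizeTraits(fix$traits, method = "kmeans")$labels[, "causal_metab"]
  res <- analyzeTrait(lab, g, fix$sim$tree,
                      config = pipelineConfig(nPermut = 200, seed = 2))
  a <- res$records[res$records$orthogroup == fix$sim$causal, -1]
  b <- res$records[res$records$orthogroup == "zz_dup", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("global pooling changes q-values but not p-values", {
  fix <- makeFixture(24, 25, seed = 53)
  bt <- binarizeTraits(fix$traits, method = "kmeans")
  g <- fix$sim$genotype
  presence <- genePresence(g)
  ids <- colnames(bt$labels)
  pAll <- unlist(lapply(ids, function(id) {
    ct <- pairGWAS:::contingencyTables(presence, bt$labels[, id])
    fisherExact(ct$tp, ct$fp, ct$fn, ct$tn)
  }))
  qAll <- correctPvalues(pAll, "fdr_bh")
  expect_equal(length(qAll), length(ids) * ncol(presence))
  # pooled correction with the larger m is never more liberal than
  # trait-wise on the smallest p
  qTrait <- correctPvalues(pAll[seq_len(ncol(presence))], "fdr_bh")
  expect_gte(min(qAll[seq_len(ncol(presence))]), min(qTrait) - 1e-12)
})
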