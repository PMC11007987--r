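test_that("k-means splits well-separated clusters and orients by mean", {
  v <- setNames(c(0, 0.1, 0.2, 5.0, 5.1, 5.2), paste0("i", 1:6))
  r <- binarizeKmeans(v)
  expect_equal(unname(binaryLabels(r)), c(0, 0, 0, 1, 1, 1))
  v2 <- setNames(c(-3, -3, -3, 3, 3, 3), paste0("i", 1:6))
  r2 <- binarizeKmeans(v2)
  expect_equal(unname(binaryLabels(r2)), c(0, 0, 0, 1, 1, 1))
  expect_equal(r2@means, c(-3, 3))
  expect_equal(r2@nExcluded, 0L)
})

test_that("k-means matches the exhaustive 2-partition minimizer and is
           affine invariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- setNames(round(rnorm(n, sd = 2), 3), paste0("i", seq_len(n)))
    if (length(unique(x)) < 2) next
    ref <- bestTwoPartition(unname(x))
    expect_equal(unname(binaryLabels(binarizeKmeans(x))), ref)
    a <- runif(1, 0.5, 4); b <- rnorm(1, sd = 10)
    expect_equal(unname(binaryLabels(binarizeKmeans(a * x + b))), ref)
  }
})

test_that("missing values stay missing and constants are rejected", {
  v <- setNames(c(0, 0, NA, 5, 5, NA), paste0("i", 1:6))
  r <- binarizeKmeans(v)
  expect_equal(unname(is.na(binaryLabels(r))), c(F, F, T, F, F, T))
  expect_error(binarizeKmeans(setNames(rep(2, 5), paste0("i", 1:5))),
               "constant")
})

test_that("GMM labels confident isolates and abstains near the midpoint", {
  set.seed(5)
  v <- setNames(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)), paste0("i", 1:20))
  r <- binarizeGmm(v)
  expect_equal(r@nExcluded, 0L)
  expect_equal(unname(binaryLabels(r)), rep(c(0L, 1L), each = 10))
  post <- r@posterior[!is.na(r@posterior)]
  expect_true(all(pmax(post, 1 - post) > 0.999))
  # abstention contract: with overlapping clusters every labeled isolate
  # has max posterior >= cutoff and every excluded one falls below it
  set.seed(6)
  v2 <- setNames(c(rnorm(60, 0), rnorm(60, 2.5)), paste0("i", 1:120))
  r2 <- binarizeGmm(v2, posteriorCutoff = 0.85)
  expect_gt(r2@nExcluded, 0)
  maxPost <- pmax(r2@posterior, 1 - r2@posterior)
  lab2 <- binaryLabels(r2)
  expect_true(all(maxPost[!is.na(lab2)] >= 0.85))
  expect_true(all(maxPost[is.na(lab2)] < 0.85))
  expect_equal(r2@nExcluded, sum(is.na(lab2)))
  # a fitted symmetric two-component model scores its exact midpoint at
  # posterior 1/2: the mixture responsibility identity
  w <- c(0.5, 0.5); mu <- c(0, 10); s <- c(1, 1)
  d <- w * dnorm(5, mu, s)
  expect_equal(d[2] / sum(d), 0.5)
})

test_that("raising the posterior cutoff never decreases exclusions", {
  set.seed(8)
  v <- setNames(c(rnorm(30, 0), rnorm(30, 2.2)), paste0("i", 1:60))
  cuts <- c(0.5, 0.7, 0.85, 0.95, 0.99)
  nExcl <- vapply(cuts, function(ct)
    binarizeGmm(v, posteriorCutoff = ct)@nExcluded, integer(1))
  expect_true(all(diff(nExcl) >= 0))
})

test_that("GMM labels are invariant under increasing affine transforms", {
  set.seed(9)
  v <- setNames(c(rnorm(20, 0), rnorm(20, 3)), paste0("i", 1:40))
  ref <- binaryLabels(binarizeGmm(v))
  tr <- binaryLabels(binarizeGmm(3.7 * v + 11))
  expect_identical(ref, tr)
})

test_that("GMM and k-means agree on well-separated data", {
  set.seed(10)
  v <- setNames(c(rnorm(25, 0), rnorm(25, 3)), paste0("i", 1:50))
  km <- binaryLabels(binarizeKmeans(v))
  gm <- binaryLabels(binarizeGmm(v))
  lab <- !is.na(gm)
  expect_gte(mean(km[lab] == gm[lab]), 0.95)
})

test_that("GMM component means agree with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  set.seed(12)
  v <- setNames(c(rnorm(40, 0, 0.5), rnorm(40, 5, 0.5)), paste0("i", 1:80))
  r <- binarizeGmm(v)
  m <- mclust::Mclust(unname(v), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(r@means, sort(unname(m$parameters$mean)), tolerance = 0.05)
})

test_that("GMM failure policy falls back to k-means or skips", {
  # two distinct values only: variance collapse is unavoidable
  v <- setNames(rep(c(0, 1), each = 5), paste0("i", 1:10))
  r <- binarizeGmm(v, onFailure = "kmeans")
  expect_equal(r@method, "gmm_kmeans_fallback")
  expect_equal(unname(binaryLabels(r)), rep(c(0L, 1L), each = 5))
  expect_error(binarizeGmm(v, onFailure = "skip"),
               class = "pairGWAS_binarization_skip")
})

test_that("binarizeTraits passes binary traits through and logs outcomes", {
  set.seed(13)
  vals <- cbind(num = c(rnorm(10, 0, 0.1), rnorm(10, 8, 0.1)),
                bin = rbinom(20, 1, 0.5))
  rownames(vals) <- paste0("i", 1:20)
  bt <- binarizeTraits(TraitTable(vals), method = "gmm")
  expect_identical(unname(bt$labels[, "bin"]), as.integer(vals[, "bin"]))
  expect_equal(bt$log$outcome[bt$log$trait == "num"], "ok")
  expect_equal(bt$log$outcome[bt$log$trait == "bin"], "passthrough")
  expect_s4_class(bt$results$num, "BinarizationResult")
})
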