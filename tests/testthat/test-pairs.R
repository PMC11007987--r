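# Leaf labels: gene/trait in {0,1}; a contrasting pair differs in both.

test_that("canonical small configurations match first-principles values", {
  tr <- parseNewick("((A,B),(C,D));")
  # two supporting pairs on disjoint cherries
  r <- maxContrastingPairs(tr, c(A = 1, B = 0, C = 1, D = 0),
                           c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(r[c("maxPairs", "bestSupporting", "worstSupporting")],
               list(maxPairs = 2L, bestSupporting = 2L,
                    worstSupporting = 2L))
  expect_equal(r$pBest, 0.25)   # P[Bin(2,1/2) >= 2]
  # no contrast at all
  r0 <- maxContrastingPairs(tr, c(A = 1, B = 1, C = 1, D = 1),
                            c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(r0$maxPairs, 0L)
  expect_equal(r0$pBest, 1)
  # caterpillar with all four states present: frozen against the
  # exhaustive pairing oracle
  cat4 <- parseNewick("(((A,B),C),D);")
  g <- c(A = 1, B = 0, C = 1, D = 0)
  t <- c(A = 1, B = 1, C = 0, D = 0)
  bf <- pairGWAS:::bruteForcePairSummary(cat4, unname(g[cat4$tip.label]),
                                         unname(t[cat4$tip.label]))
  r2 <- maxContrastingPairs(cat4, g, t)
  expect_equal(r2$maxPairs, bf$maxPairs)
  expect_equal(r2$bestSupporting, bf$bestSupporting)
  expect_equal(r2$worstSupporting, bf$worstSupporting)
})

test_that("pair summaries satisfy ordering and bound invariants", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, br = NULL)
    g <- rbinom(n, 1, 0.5); t <- rbinom(n, 1, 0.5)
    r <- maxContrastingPairs(tr, g, t)
    expect_lte(r$worstSupporting, r$bestSupporting)
    expect_lte(r$bestSupporting, r$maxPairs)
    expect_lte(r$maxPairs, min(sum(g == 1), sum(g == 0)))
    expect_lte(r$maxPairs, min(sum(t == 1), sum(t == 0)))
    expect_lte(r$pBest, r$pWorst)
  }
})

test_that("gene/trait swap and double complement are symmetries; single
           complement exchanges supporting and opposing", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, br = NULL)
    g <- rbinom(n, 1, 0.5); t <- rbinom(n, 1, 0.5)
    a <- maxContrastingPairs(tr, g, t)
    swap <- maxContrastingPairs(tr, t, g)
    expect_equal(swap[1:3], a[1:3])
    dbl <- maxContrastingPairs(tr, 1 - g, 1 - t)
    expect_equal(dbl[1:3], a[1:3])
    one <- maxContrastingPairs(tr, 1 - g, t)
    expect_equal(one$maxPairs, a$maxPairs)
    expect_equal(one$bestSupporting, a$maxPairs - a$worstSupporting)
    expect_equal(one$worstSupporting, a$maxPairs - a$bestSupporting)
  }
})

test_that("excluded leaves are pruned before pair analysis", {
  tr <- parseNewick("((A,B),(C,D));")
  g <- c(A = 1, B = 0, C = 1, D = 0)
  t <- c(A = 1, B = 0, C = NA, D = NA)
  r <- maxContrastingPairs(tr, g, t)
  ref <- maxContrastingPairs(pruneTree(tr, c("A", "B")), g[1:2], t[1:2])
  expect_equal(r, ref)
})

test_that("permutation p is bounded, deterministic, and 1 without contrast", {
  tr <- parseNewick("((A,B),(C,D));")
  g <- c(A = 1, B = 0, C = 1, D = 0)
  t <- c(A = 1, B = 0, C = 1, D = 0)
  p1 <- permutationTest(tr, g, t, nPermut = 500, seed = 3)
  p2 <- permutationTest(tr, g, t, nPermut = 500, seed = 3)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 501)
  expect_lte(p1, 1)
  # all leaves share the gene state: no permutation can create a contrast
  expect_equal(permutationTest(tr, c(A = 1, B = 1, C = 1, D = 1), t,
                               nPermut = 500, seed = 1), 1)
})

test_that("empirical permutation p approaches the exhaustive value", {
  # moderate-n spot check; the full 4/5-leaf sweep runs in the acceptance
  # suite
  tr <- parseNewick("(((A,B),C),(D,E));")
  g <- c(A = 1, B = 0, C = 1, D = 0, E = 1)
  t <- c(A = 1, B = 0, C = 0, D = 1, E = 1)
  exact <- exhaustivePermP(tr, unname(g[tr$tip.label]),
                           unname(t[tr$tip.label]))
  emp <- permutationTest(tr, g, t, nPermut = 20000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(emp - (1 + 20000 * exact) / 20001), 3 * se + 1e-9)
})

test_that("canonical gene keys identify isomorphic labelings", {
  trA <- parseNewick("((A,B),(C,D));")
  trB <- parseNewick("((C,D),(A,B));")   # children of the root swapped
  g <- c(A = 1, B = 0, C = 0, D = 0)
  expect_identical(canonicalGeneKey(trA, g), canonicalGeneKey(trB, g))
  # complemented pattern maps to a different key
  expect_false(canonicalGeneKey(trA, g) == canonicalGeneKey(trA, 1 - g))
  # different patterns on the same tree differ
  g2 <- c(A = 1, B = 1, C = 0, D = 0)
  expect_false(canonicalGeneKey(trA, g) == canonicalGeneKey(trA, g2))
})

test_that("duplicated orthogroups share one cached null computation", {
  set.seed(30)
  n <- 12
  tr <- ape::rtree(n, br = NULL)
  g <- rbinom(n, 1, 0.5)
  t <- rbinom(n, 1, 0.5)
  cache <- newPermCache()
  p1 <- permutationTest(tr, g, t, nPermut = 300, seed = 9, cache = cache)
  expect_length(ls(cache), 1)
  # an identical presence pattern (a duplicated orthogroup) hits the cache
  p2 <- permutationTest(tr, g, t, nPermut = 300, seed = 9, cache = cache)
  expect_identical(p1, p2)
  expect_length(ls(cache), 1)
  # cache hit must be bit-identical to a fresh computation
  expect_identical(p1, permutationTest(tr, g, t, nPermut = 300, seed = 9))
})

test_that("the cache persists to disk and reloads", {
  set.seed(31)
  n <- 8
  tr <- ape::rtree(n, br = NULL)
  g <- rbinom(n, 1, 0.5); t <- rbinom(n, 1, 0.5)
  path <- withr::local_tempfile(fileext = ".cache")
  c1 <- newPermCache(path)
  p1 <- permutationTest(tr, g, t, nPermut = 200, seed = 2, cache = c1)
  savePermCache(c1)
  c2 <- newPermCache(path)
  expect_setequal(ls(c2), ls(c1))
  p2 <- permutationTest(tr, g, t, nPermut = 200, seed = 2, cache = c2)
  expect_identical(p1, p2)
})
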