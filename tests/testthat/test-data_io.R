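test_that("gene-list tables parse into counts and per-cell identifiers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tisoA\tisoB\tisoC",
               "og1\tgeneA,geneB\t\tgeneC",
               "og2\tgeneD\tgeneE; geneF\t"), path)
  g <- readGenotype(path)
  expect_equal(unname(geneCounts(g)["isoA", "og1"]), 2L)
  expect_equal(geneLists(g)[["isoA", "og1"]], c("geneA", "geneB"))
  expect_equal(geneLists(g)[["isoB", "og2"]], c("geneE", "geneF"))
  # empty cell encodes absence
  expect_equal(unname(geneCounts(g)["isoB", "og1"]), 0L)
  expect_equal(unname(genePresence(g)["isoB", "og1"]), 0L)
})

test_that("gene-count tables binarize at count >= 1", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Gene,i1,i2,i3", "og1,1,0,2", "og2,0,1,1"), path)
  g <- readGenotype(path)
  expect_equal(unname(genePresence(g)[, "og1"]), c(1L, 0L, 1L))
  expect_equal(unname(genePresence(g)[, "og2"]), c(0L, 1L, 1L))
  expect_equal(unname(geneCounts(g)["i3", "og1"]), 2L)
})

test_that("duplicate identifiers and ragged rows are fatal with context", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\ti1\ti2", "og1\t1\t0", "og1\t0\t1"), p1)
  expect_error(readGenotype(p1), "duplicate")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\ti1\ti2", "og1\t1\t0", "og2\t1"), p2)
  expect_error(readGenotype(p2), "row 3")
})

test_that("orientation detection transposes Roary-style tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tog1\tog2", "i1\t1\t0", "i2\t0\t1", "i3\t1\t1"), path)
  g <- readGenotype(path, isolateIdsHint = c("i1", "i2", "i3"))
  expect_setequal(isolateIds(g), c("i1", "i2", "i3"))
  expect_setequal(orthogroupIds(g), c("og1", "og2"))
})

test_that("trait kinds are detected and uninformative traits dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isolate\tbin\tnum\tflat",
               "i1\t0\t0.1\t1", "i2\t1\t5.2\t1",
               "i3\t1\t5.3\t1", "i4\t0\tNA\t1"), path)
  expect_warning(tt <- readTraits(path), "flat")
  expect_equal(unname(traitKinds(tt)[c("bin", "num")]),
               c("binary", "numeric"))
  expect_false("flat" %in% traitIds(tt))
  expect_equal(sum(is.na(traitValues(tt)[, "num"])), 1)
})

test_that("non-numeric trait cells are fatal with a cell address", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isolate\tnum", "i1\t0.1", "i2\toops", "i3\t2", "i4\t3"),
             path)
  expect_error(readTraits(path), "oops.*i2|i2.*oops")
})

test_that("alignInputs intersects, canonicalizes and enforces >= 4 isolates", {
  m <- matrix(1L, 5, 3, dimnames = list(paste0("i", 5:1), paste0("og", 3:1)))
  m[2, 1] <- 0L
  g <- GenotypeMatrix(m)
  tv <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("i", c(1:4, 9)), paste0("t", 1:4)))
  tt <- TraitTable(tv)
  al <- alignInputs(g, tt)
  expect_equal(isolateIds(al$genotype), sort(c("i1", "i2", "i3", "i4")))
  expect_equal(isolateIds(al$genotype), isolateIds(al$traits))
  expect_equal(orthogroupIds(al$genotype), sort(paste0("og", 1:3)))
  # idempotent
  al2 <- alignInputs(al$genotype, al$traits)
  expect_identical(geneCounts(al2$genotype), geneCounts(al$genotype))
  expect_identical(traitValues(al2$traits), traitValues(al$traits))
  # too-small intersection is fatal
  tvSmall <- tv[1:2, , drop = FALSE]
  expect_error(alignInputs(g, TraitTable(rbind(tvSmall))), "at least 4")
})

test_that("alignInputs prunes the tree to shared isolates", {
  m <- matrix(1L, 4, 2, dimnames = list(paste0("i", 1:4), c("a", "b")))
  tv <- matrix(rnorm(16), 4, 4,
               dimnames = list(paste0("i", 1:4), paste0("t", 1:4)))
  tree <- parseNewick("(((i1,i2),(i3,i4)),extra);")
  al <- alignInputs(GenotypeMatrix(m), TraitTable(tv), tree)
  expect_setequal(al$tree$tip.label, paste0("i", 1:4))
  expect_equal(ape::Nnode(al$tree), 3)
})

test_that("genotype write/read round-trips counts and gene lists", {
  counts <- matrix(c(2L, 0L, 1L, 1L, 0L, 3L), 3, 2,
                   dimnames = list(c("i1", "i2", "i3"), c("ogA", "ogB")))
  lists <- lapply(as.vector(counts), function(k)
    if (k == 0) character(0) else sprintf("g%02d", seq_len(k)))
  g <- GenotypeMatrix(counts, lists)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotype(g, p1, format = "gene_count")
  expect_identical(geneCounts(readGenotype(p1)), counts)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotype(g, p2, format = "gene_list")
  g2 <- readGenotype(p2)
  expect_identical(geneCounts(g2), counts)
  expect_identical(geneLists(g2)[["i3", "ogB"]], c("g01", "g02", "g03"))
})

test_that("GenotypeMatrix validity enforces count/list agreement", {
  counts <- matrix(c(1L, 2L), 1, 2, dimnames = list("i1", c("a", "b")))
  expect_error(GenotypeMatrix(counts, list("g1", "g2")), "length")
  expect_silent(GenotypeMatrix(counts, list("g1", c("g2", "g3"))))
})
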