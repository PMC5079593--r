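test_that("Nei DA matches hand-worked cases and satisfies distance axioms", {
  expect_equal(neiDa(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(neiDa(rep(1, 5), rep(0, 5)), 1)     # fixed for opposite alleles
  expect_equal(neiDa(0.5, 1), 1 - sqrt(0.5), tolerance = 1e-12)
  # axioms over random frequency pairs; invariance to locus order
  set.seed(12)
  for (i in 1:100) {
    x <- runif(10); y <- runif(10)
    d <- neiDa(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, neiDa(y, x))
    expect_lte(neiDa(x, x), 1e-12)
    perm <- sample(10)
    expect_equal(d, neiDa(x[perm], y[perm]), tolerance = 1e-12)
  }
  # pairwise deletion of missing loci
  expect_equal(neiDa(c(0.5, NA, 1), c(1, 0.2, NA)), 1 - sqrt(0.5),
               tolerance = 1e-12)
  expect_error(neiDa(NA_real_, 0.5), "no shared loci")
  # the literal (no square root) variant is exposed but is not a metric
  expect_equal(neiDa(0.5, 0.5, sqrtForm = FALSE), 0.5)
})

test_that("distance matrices agree with the per-pair oracle", {
  p <- randomPanel(5, 30, missing = 0.1, seed = 21)
  d <- neiDistance(p, "individuals")
  ft <- alleleFreqTable(p, "individuals")
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], oracleNeiDa(ft[i, ], ft[j, ]), tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  # identical individuals at zero distance
  x <- genotypeCalls(p); x[2, ] <- x[1, ]
  d2 <- neiDistance(SnpPanel(x), "individuals")
  expect_equal(unname(d2[1, 2]), 0)
  # all-missing unit rejected by name
  x[3, ] <- NA
  expect_error(neiDistance(SnpPanel(x), "individuals"), "I03")
})

test_that("UPGMA reproduces the textbook 3-taxon worked example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(d)
  expect_equal(tr@heights, c(1, 2))
  cl <- maizediv:::treeClusters(tr)
  expect_equal(cl[[1]], c("A", "B"))
  expect_equal(cl[[2]], c("A", "B", "C"))
  # two leaves: single node at half the distance
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgmaTree(d2)@heights, 0.25)
  expect_error(upgmaTree(matrix(c(0, Inf, Inf, 0), 2,
                                dimnames = list(c("A", "B"), NULL))),
               "non-finite")
})

test_that("equal distances resolve by the lexicographic tie-break rule", {
  labs <- c("D", "B", "C", "A")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr <- upgmaTree(d)
  cl <- maizediv:::treeClusters(tr)
  expect_equal(cl[[1]], c("A", "B"))       # smallest label pair merges first
  expect_equal(cl[[2]], c("A", "B", "C"))
  expect_equal(tr@heights, rep(0.5, 3))    # all merge heights equal
})

test_that("UPGMA trees are ultrametric and match average-linkage hclust", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    m <- matrix(runif(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tr <- upgmaTree(m)
    coph <- as.matrix(stats::cophenetic(asHclust(tr)))
    expectUltrametric(coph)
    ref <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(m),
                                                     method = "average")))
    expect_equal(coph[letters[1:n], letters[1:n]],
                 ref[letters[1:n], letters[1:n]], tolerance = 1e-12)
  }
  # ultrametric input is reproduced exactly by the cophenetic matrix
  base <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  coph <- as.matrix(stats::cophenetic(asHclust(upgmaTree(base))))
  expect_equal(coph[c("A", "B", "C"), c("A", "B", "C")], base)
})

test_that("UPGMA agrees with the phangorn reference implementation", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(LETTERS[1:8], LETTERS[1:8])
  mine <- as.matrix(stats::cophenetic(asHclust(upgmaTree(m))))
  ref <- ape::cophenetic.phylo(phangorn::upgma(stats::as.dist(m)))
  expect_equal(mine[LETTERS[1:8], LETTERS[1:8]],
               ref[LETTERS[1:8], LETTERS[1:8]], tolerance = 1e-9)
})

test_that("bootstrap support is 100 everywhere for resampling-invariant data", {
  x <- matrix(rep(c(0L, 1L, 2L, 0L, 2L), 30), 5, 30,
              dimnames = list(paste0("u", 1:5), NULL))
  tr <- bootstrapSupport(SnpPanel(x), "individuals", nReps = 50, seed = 3)
  expect_equal(unname(tr@support), rep(100, 4))
})

test_that("bootstrap supports are seed-deterministic and order-invariant", {
  sim <- simulateAdmixed(simConfig(nMarkers = 60, K = 2, F = 0.4,
                                   nPerPop = c(3, 3), seed = 8))
  t1 <- bootstrapSupport(sim$panel, "individuals", nReps = 60, seed = 42)
  t2 <- bootstrapSupport(sim$panel, "individuals", nReps = 60, seed = 42)
  expect_identical(t1@support, t2@support)
  # permuting the input marker columns does not change the supports
  perm <- sample(nMarkers(sim$panel))
  t3 <- bootstrapSupport(sim$panel[, perm], "individuals", nReps = 60,
                         seed = 42)
  expect_identical(unname(t1@support), unname(t3@support))
})

test_that("Newick export round-trips through ape and quotes odd labels", {
  p <- randomPanel(6, 40, missing = 0, seed = 51)
  tr <- bootstrapSupport(p, "individuals", nReps = 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, tr@labels)
  # cophenetic distances survive the round trip
  mine <- as.matrix(stats::cophenetic(asHclust(tr)))
  theirs <- ape::cophenetic.phylo(ph)
  expect_equal(theirs[rownames(mine), colnames(mine)], mine,
               tolerance = 1e-6)
  # supports ride along as node labels
  expect_equal(sort(as.numeric(ph$node.label)), sort(unname(tr@support)),
               tolerance = 1e-6)
  # labels with spaces are quoted
  d <- matrix(c(0, 1, 1, 0), 2,
              dimnames = list(c("my hybrid", "B"), c("my hybrid", "B")))
  s <- maizediv:::newickString(upgmaTree(d))
  expect_match(s, "'my hybrid'", fixed = TRUE)
  tip <- gsub("'", "", ape::read.tree(text = s)$tip.label)
  expect_true("my hybrid" %in% tip)
})
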