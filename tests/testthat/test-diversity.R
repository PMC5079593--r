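test_that("gene diversity and PIC match hand-worked frequency cases", {
  expect_equal(geneDiversity(c(0.5, 0.5)), 0.5)
  expect_equal(geneDiversity(c(1, 0)), 0)
  expect_equal(geneDiversity(c(0.9, 0.1)), 0.18)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1, 0)), 0)
  expect_error(geneDiversity(c(-0.1, 1.1)), "negative")
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  # PIC never exceeds gene diversity, both invariant to relabeling
  set.seed(4)
  for (i in 1:50) {
    p <- runif(1)
    f <- c(p, 1 - p)
    expect_lte(pic(f), geneDiversity(f) + 1e-15)
    expect_equal(pic(f), pic(rev(f)))
    expect_equal(geneDiversity(f), geneDiversity(rev(f)))
  }
})

test_that("count-based MAF and heterozygosity follow allele counting", {
  expect_equal(minorAlleleFreq(3, 2, 1), 4 / 12)
  expect_equal(minorAlleleFreq(6, 0, 0), 0)
  expect_equal(minorAlleleFreq(0, 0, 6), 0)   # orientation invariance
  expect_equal(heterozygosity(2, 2, 2), 2 / 6)
  expect_equal(heterozygosity(0, 5, 0), 1)
  expect_equal(heterozygosity(3, 0, 3), 0)
  expect_true(is.na(minorAlleleFreq(0, 0, 0)))
})

test_that("per-locus statistics equal the brute-force allele-counting oracle", {
  for (seed in 1:10) {
    p <- randomPanel(20, 50, missing = 0.1, seed = seed)
    ls <- locusStats(p)
    oracle <- oracleLocusStats(genotypeCalls(p))
    expect_equal(ls$gd, unname(oracle[, "gd"]), tolerance = 1e-12)
    expect_equal(ls$pic, unname(oracle[, "pic"]), tolerance = 1e-12)
    expect_equal(ls$het, unname(oracle[, "het"]), tolerance = 1e-12)
    expect_equal(ls$maf, unname(oracle[, "maf"]), tolerance = 1e-12)
    expect_true(all(ls$maf <= 0.5 + 1e-12, na.rm = TRUE))
    expect_true(all(ls$pic <= ls$gd + 1e-12, na.rm = TRUE))
    # biallelic gene diversity is exactly 2pq
    expect_equal(ls$gd, 2 * ls$p_a * (1 - ls$p_a), tolerance = 1e-12)
  }
})

test_that("group summaries average per-locus values over the full panel", {
  # a single fully heterozygous F1: p = q = 0.5 at every locus
  x1 <- matrix(1L, 1, 10, dimnames = list("F1", NULL))
  gs1 <- groupSummary(SnpPanel(x1), groups = c(F1 = "g"))
  expect_equal(gs1$gd, 0.5)
  expect_equal(gs1$het, 1.0)
  expect_equal(gs1$maf, 0.5)
  # clones of a homozygous line: no variation at all
  x2 <- matrix(rep(c(0L, 2L), each = 12), 4, 6,
               dimnames = list(paste0("c", 1:4), NULL))
  gs2 <- groupSummary(SnpPanel(x2), groups = stats::setNames(rep("g", 4),
                                                             paste0("c", 1:4)))
  expect_equal(gs2$gd, 0); expect_equal(gs2$pic, 0)
  expect_equal(gs2$het, 0); expect_equal(gs2$maf, 0)
  # 4-individual group: means match brute-force recomputation
  p <- randomPanel(4, 15, missing = 0.1, seed = 9)
  gs <- groupSummary(p, groups = stats::setNames(rep("g", 4), indNames(p)))
  oracle <- oracleLocusStats(genotypeCalls(p))
  oracle <- oracle[!is.na(oracle[, "gd"]), , drop = FALSE]
  expect_equal(gs$gd, mean(oracle[, "gd"]), tolerance = 1e-12)
  expect_equal(gs$pic, mean(oracle[, "pic"]), tolerance = 1e-12)
  expect_equal(gs$het, mean(oracle[, "het"]), tolerance = 1e-12)
  expect_equal(gs$maf, mean(oracle[, "maf"]), tolerance = 1e-12)
  expect_equal(gs$n_loci, nrow(oracle))
  # replicating a group leaves its summary unchanged
  x <- genotypeCalls(p)
  xx <- rbind(x, x); rownames(xx) <- paste0("I", 1:8)
  gs2x <- groupSummary(SnpPanel(xx),
                       groups = stats::setNames(rep("g", 8), paste0("I", 1:8)))
  expect_equal(gs2x$gd, gs$gd, tolerance = 1e-12)
  expect_equal(gs2x$maf, gs$maf, tolerance = 1e-12)
})

test_that("group summary errors on unknown or empty groups", {
  p <- randomPanel(4, 5, missing = 0, seed = 1)
  x <- genotypeCalls(p); x[1, ] <- NA
  pan <- SnpPanel(x)
  expect_error(groupSummary(pan, groups = c(I01 = "lonely")), "lonely")
})

test_that("planted private alleles are recovered exactly", {
  p <- privateFixture()
  pa <- privateAlleles(p)
  counts <- table(pa$group)
  expect_equal(as.integer(counts[c("g1", "g2", "g3")]), c(1L, 3L, 11L))
  # brute-force verification: every reported allele absent elsewhere
  x <- genotypeCalls(p); grp <- groupAssignment(p); mk <- markerInfo(p)
  for (i in seq_len(nrow(pa))) {
    j <- match(pa$marker_id[i], mk$marker_id)
    isB <- pa$allele[i] == mk$allele_b[j]
    for (g in unique(grp)) {
      xg <- x[names(grp)[grp == g], j]
      cnt <- if (isB) sum(xg, na.rm = TRUE) else sum(2 - xg, na.rm = TRUE)
      if (g == pa$group[i]) expect_gt(cnt, 0) else expect_equal(cnt, 0)
    }
  }
  # merging all groups leaves nothing private
  one <- stats::setNames(rep("all", nInd(p)), indNames(p))
  expect_equal(nrow(privateAlleles(p, groups = one)), 0L)
})

test_that("allele-frequency correlations match the covariance oracle", {
  ft <- rbind(a = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.6, 0.8, 0.35),
              b = c(0.2, 0.25, 0.45, 0.8, 0.85, 0.15, 0.5, 0.55, 0.75, 0.3),
              c = rep(0.5, 10))
  res <- alleleFreqCorrelation(ft, "a", "b")
  x <- ft["a", ]; y <- ft["b", ]
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r0, tolerance = 1e-12)
  tstat <- r0 * sqrt(8 / (1 - r0^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tstat), df = 8), tolerance = 1e-12)
  # identity and degenerate cases
  expect_equal(alleleFreqCorrelation(rbind(a = x, b = x), "a", "b")$r, 1)
  expect_error(alleleFreqCorrelation(ft[, 1:2], "a", "b"), "fewer than 3")
  expect_identical(alleleFreqCorrelation(ft, "a", "c")$flag, "zero_variance")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(7)
  ft <- matrix(runif(40), 4, 10, dimnames = list(letters[1:4], NULL))
  cm <- correlationMatrix(ft)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_true(all(is.na(diag(cm$p))))
})
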