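# Fixture builders and brute-force oracles shared across the suite.
# Oracles deliberately use naive per-cell loops, independent of the
# vectorized implementation paths they check.

randomPanel <- function(n, L, missing = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(L, 0.05, 0.95)
  x <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (missing > 0) x[matrix(runif(n * L) < missing, n, L)] <- NA
  rownames(x) <- sprintf("I%02d", seq_len(n))
  SnpPanel(x)
}

# Per-marker diversity statistics by explicit allele counting.
oracleLocusStats <- function(x) {
  t(apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n == 0) return(c(gd = NA, pic = NA, het = NA, maf = NA))
    nA <- 0; nB <- 0; nhet <- 0
    for (g in col) {
      nA <- nA + (2 - g); nB <- nB + g
      if (g == 1) nhet <- nhet + 1
    }
    p <- nA / (nA + nB); q <- 1 - p
    c(gd = 1 - p^2 - q^2,
      pic = 1 - p^2 - q^2 - 2 * p^2 * q^2,
      het = nhet / n,
      maf = min(p, q))
  }))
}

# Nei DA by direct per-locus summation over both alleles.
oracleNeiDa <- function(x, y) {
  x <- unname(x); y <- unname(y)
  tot <- 0; r <- 0
  for (j in seq_along(x)) {
    if (is.na(x[j]) || is.na(y[j])) next
    r <- r + 1
    tot <- tot + (1 - (sqrt(x[j] * y[j]) + sqrt((1 - x[j]) * (1 - y[j]))))
  }
  tot / r
}

# Cophenetic ultrametricity: the two largest pairwise cophenetic
# distances of every leaf triple must coincide.
expectUltrametric <- function(coph, tol = 1e-9) {
  labs <- rownames(coph)
  for (trip in combn(labs, 3, simplify = FALSE)) {
    d <- sort(c(coph[trip[1], trip[2]], coph[trip[1], trip[3]],
                coph[trip[2], trip[3]]), decreasing = TRUE)
    expect_lt(d[1] - d[2], tol)
  }
}

# 10-marker QC fixture: 20 individuals; markers 1-3 fail call rate
# (<90% called), markers 4-5 fail MAF (<5%), markers 6-10 pass.
qcFixture <- function() {
  n <- 20
  x <- matrix(0L, n, 10)
  for (j in 1:10) x[, j] <- c(rep(0L, 10), rep(1L, 4), rep(2L, 6))
  x[1:3, 1] <- NA; x[1:4, 2] <- NA; x[1:6, 3] <- NA   # call rates .85 .80 .70
  x[, 4] <- 0L                                         # monomorphic, maf 0
  x[, 5] <- c(1L, rep(0L, n - 1))                      # maf 1/40 = 0.025
  x[1:2, 6] <- NA                                      # call rate exactly 0.90
  x[, 7] <- c(1L, 1L, rep(0L, n - 2))                  # maf 2/40 = 0.05 boundary
  rownames(x) <- sprintf("I%02d", 1:n)
  SnpPanel(x)
}

# Three-group fixture with exactly 1, 3 and 11 private alleles planted
# for groups g1, g2, g3 (plus shared filler markers).
privateFixture <- function() {
  counts <- c(g1 = 1L, g2 = 3L, g3 = 11L)
  nPriv <- sum(counts)
  nFill <- 5L
  n <- 9L                                  # 3 individuals per group
  grp <- rep(names(counts), each = 3)
  x <- matrix(0L, n, nPriv + nFill)
  j <- 0L
  for (g in seq_along(counts)) for (k in seq_len(counts[g])) {
    j <- j + 1L
    x[, j] <- 0L
    x[3 * (g - 1) + 1, j] <- 1L            # allele B only in group g
  }
  for (j2 in (nPriv + 1):(nPriv + nFill)) x[, j2] <- rep(c(0L, 1L, 2L), 3)
  rownames(x) <- sprintf("I%02d", 1:n)
  SnpPanel(x, groups = stats::setNames(grp, rownames(x)))
}
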