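## Per-locus and per-group diversity statistics, private alleles, and
## between-group allele-frequency correlations.

#' Gene diversity (expected heterozygosity) of an allele-frequency vector
#'
#' \eqn{D = 1 - \sum_i p_i^2}, the probability that two alleles drawn at
#' random from the locus differ.
#'
#' @param freqs numeric vector of allele frequencies summing to 1
#' @return gene diversity in [0, 1]
#' @export
geneDiversity <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Polymorphism information content of an allele-frequency vector
#'
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}; always at most
#' the gene diversity, with maximum 0.375 for a biallelic locus.
#'
#' @param freqs numeric vector of allele frequencies summing to 1
#' @return PIC in [0, 1]
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  s2 <- sum(freqs^2)
  cross <- (s2^2 - sum(freqs^4)) / 2      # sum_{i<j} p_i^2 p_j^2
  1 - s2 - 2 * cross
}

#' Minor allele frequency from genotype counts
#'
#' With P homozygotes for the major allele, Q heterozygotes and R
#' homozygotes for the minor allele, MAF = (Q + 2R) / (2(P + Q + R)) —
#' the minor-allele count over the total allele count.
#'
#' @param P,Q,R non-negative genotype counts (major hom, het, minor hom)
#' @return MAF in [0, 0.5]; \code{NA} when no calls
#' @export
minorAlleleFreq <- function(P, Q, R) {
  n <- P + Q + R
  if (n < 1) return(NA_real_)
  f <- (Q + 2 * R) / (2 * n)
  min(f, 1 - f)                           # orientation-safe
}

#' Heterozygosity from genotype counts
#'
#' @inheritParams minorAlleleFreq
#' @return Q / (P + Q + R); \code{NA} when no calls
#' @export
heterozygosity <- function(P, Q, R) {
  n <- P + Q + R
  if (n < 1) return(NA_real_)
  Q / n
}

#' Genotype counts per marker
#'
#' @param panel a \code{SnpPanel}
#' @return data.frame \code{marker_id, P, Q, R, n} where P counts
#'   homozygotes for the major (more frequent) allele, Q heterozygotes and
#'   R homozygotes for the minor allele, over non-missing calls
#' @export
genotypeCounts <- function(panel) {
  x <- genotypeCalls(panel)
  n0 <- colSums(x == 0L, na.rm = TRUE)
  nh <- colSums(x == 1L, na.rm = TRUE)
  n2 <- colSums(x == 2L, na.rm = TRUE)
  n <- n0 + nh + n2
  pa <- (2 * n0 + nh) / (2 * pmax(n, 1L)) # freq of allele A
  majA <- pa >= 0.5                       # ties: allele A is major
  data.frame(marker_id = markerIds(panel),
             P = ifelse(majA, n0, n2), Q = nh, R = ifelse(majA, n2, n0),
             n = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Allele-A frequency table per unit (group or individual)
#'
#' Frequencies are computed over non-missing allele copies only; units
#' with no calls at a marker get \code{NA} there.  Allele A is the
#' alphabetically first allele, so orientation is consistent between
#' units.
#'
#' @param panel a \code{SnpPanel}
#' @param units \code{"groups"} (requires a group assignment) or
#'   \code{"individuals"} (each individual a 1-member frequency unit: a
#'   heterozygote contributes frequencies (0.5, 0.5))
#' @param groups optional named character vector overriding the panel's
#'   group assignment
#' @return units x markers numeric matrix of allele-A frequencies
#' @export
alleleFreqTable <- function(panel, units = c("groups", "individuals"),
                            groups = NULL) {
  units <- match.arg(units)
  x <- genotypeCalls(panel)
  if (units == "individuals") {
    ft <- 1 - x / 2
    rownames(ft) <- rownames(x)
    return(ft)
  }
  if (is.null(groups)) groups <- groupAssignment(panel)
  if (!length(groups)) stop("no group assignment available")
  labs <- sort(unique(groups))
  ft <- matrix(NA_real_, length(labs), ncol(x),
               dimnames = list(labs, colnames(x)))
  for (g in labs) {
    xg <- x[rownames(x) %in% names(groups)[groups == g], , drop = FALSE]
    n <- colSums(!is.na(xg))
    ft[g, ] <- ifelse(n > 0, (2 * n - colSums(xg, na.rm = TRUE)) / (2 * n), NA)
  }
  ft
}

#' Per-locus diversity statistics
#'
#' Gene diversity, PIC, heterozygosity and MAF for every marker of the
#' panel, computed from non-missing calls.
#'
#' @param panel a \code{SnpPanel}
#' @return data.frame \code{marker_id, n_called, p_a, gd, pic, het, maf}
#'   (NA at markers with no calls)
#' @export
locusStats <- function(panel) {
  x <- genotypeCalls(panel)
  n0 <- colSums(x == 0L, na.rm = TRUE)
  nh <- colSums(x == 1L, na.rm = TRUE)
  n2 <- colSums(x == 2L, na.rm = TRUE)
  n <- n0 + nh + n2
  p <- (2 * n0 + nh) / (2 * n)            # NaN when n = 0
  q <- 1 - p
  gd <- 1 - p^2 - q^2
  picv <- gd - 2 * p^2 * q^2
  out <- data.frame(marker_id = markerIds(panel), n_called = n, p_a = p,
                    gd = gd, pic = picv, het = nh / n, maf = pmin(p, q),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[n == 0, c("p_a", "gd", "pic", "het", "maf")] <- NA_real_
  out
}

#' Per-group diversity summary
#'
#' For each group, per-locus statistics are computed on the group's
#' sub-matrix at every marker of the panel — markers monomorphic within
#' the group contribute zeros — and averaged across the markers with at
#' least one call in the group.
#'
#' @param panel a \code{SnpPanel}
#' @param groups optional named character vector overriding the panel's
#'   group assignment
#' @return data.frame \code{group, nh, gd, pic, het, maf, n_loci}
#' @export
groupSummary <- function(panel, groups = NULL) {
  if (is.null(groups)) groups <- groupAssignment(panel)
  if (!length(groups)) stop("no group assignment available")
  labs <- sort(unique(groups))
  rows <- lapply(labs, function(g) {
    ids <- names(groups)[groups == g]
    sub <- panel[indNames(panel) %in% ids, ]
    if (nInd(sub) == 0L) stop("group ", g, " has no individuals in the panel")
    ls <- locusStats(sub)
    ls <- ls[ls$n_called > 0, ]
    if (nrow(ls) == 0L) stop("group ", g, " has no genotype calls")
    data.frame(group = g, nh = nInd(sub), gd = mean(ls$gd),
               pic = mean(ls$pic), het = mean(ls$het), maf = mean(ls$maf),
               n_loci = nrow(ls), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Private alleles of each group
#'
#' An allele is private to a group when its count over non-missing calls
#' is positive in exactly one group and zero in all others.  Records are
#' emitted in marker order, allele A before allele B.
#'
#' @param panel a \code{SnpPanel}
#' @param groups optional named character vector overriding the panel's
#'   group assignment
#' @return data.frame \code{marker_id, allele, group} (0 rows if none)
#' @export
privateAlleles <- function(panel, groups = NULL) {
  if (is.null(groups)) groups <- groupAssignment(panel)
  if (!length(groups)) stop("no group assignment available")
  labs <- sort(unique(groups))
  if (length(labs) < 2L)
    return(data.frame(marker_id = character(), allele = character(),
                      group = character(), stringsAsFactors = FALSE))
  x <- genotypeCalls(panel)
  mk <- markerInfo(panel)
  cntA <- cntB <- matrix(0L, length(labs), ncol(x), dimnames = list(labs, NULL))
  for (g in labs) {
    xg <- x[rownames(x) %in% names(groups)[groups == g], , drop = FALSE]
    n <- colSums(!is.na(xg))
    nb <- colSums(xg, na.rm = TRUE)
    cntA[g, ] <- 2L * n - nb
    cntB[g, ] <- nb
  }
  out <- list()
  for (j in seq_len(ncol(x))) {
    for (al in c("a", "b")) {
      cnt <- if (al == "a") cntA[, j] else cntB[, j]
      owner <- labs[cnt > 0]
      if (length(owner) == 1L)
        out[[length(out) + 1L]] <- data.frame(
          marker_id = mk$marker_id[j],
          allele = if (al == "a") mk$allele_a[j] else mk$allele_b[j],
          group = owner, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(marker_id = character(), allele = character(),
                      group = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Pearson correlation between two groups' allele frequencies
#'
#' Correlates allele-A frequencies over the markers defined in both
#' groups; the two-sided p-value comes from the t statistic with L - 2
#' degrees of freedom.
#'
#' @param freqTable units x markers matrix from \code{\link{alleleFreqTable}}
#' @param groupX,groupY row labels to correlate
#' @return list \code{r}, \code{p}, \code{n} (shared markers);
#'   \code{r = NA} with \code{flag = "zero_variance"} when either vector
#'   is constant
#' @export
alleleFreqCorrelation <- function(freqTable, groupX, groupY) {
  x <- freqTable[groupX, ]
  y <- freqTable[groupY, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("fewer than 3 shared markers between ", groupX, " and ", groupY)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                flag = "zero_variance"))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Allele-frequency correlation matrix over all groups
#'
#' @param freqTable units x markers matrix from \code{\link{alleleFreqTable}}
#' @return list of two symmetric matrices, \code{r} (unit diagonal) and
#'   \code{p} (NA diagonal)
#' @export
correlationMatrix <- function(freqTable) {
  labs <- rownames(freqTable)
  k <- length(labs)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(labs, labs)
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ct <- alleleFreqCorrelation(freqTable, labs[i], labs[j])
    r[i, j] <- r[j, i] <- ct$r
    p[i, j] <- p[j, i] <- ct$p
  }
  list(r = r, p = p)
}
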