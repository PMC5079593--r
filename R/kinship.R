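## Genomic relationship matrix, within-population inbreeding (Fst) from
## its diagonal, and effective population size.

#' Genomic relationship matrix
#'
#' VanRaden-style construction: with dosages centered by twice the
#' allele-B frequency (missing cells mean-imputed, i.e. zero after
#' centering), \eqn{G = WW' / \sum_i 2 p_i q_i}.  Allele frequencies are
#' estimated from the analyzed matrix itself.  Under panmixia the mean
#' diagonal of G is 1; in general it estimates 1 + F, which is what makes
#' "mean diagonal minus one" an inbreeding estimate.
#'
#' @param panel a \code{SnpPanel} (or a dosage matrix with rownames)
#' @return list with \code{G} (symmetric labeled matrix),
#'   \code{denominator} (\eqn{\sum 2 p q}) and \code{W} (the centered
#'   incidence matrix)
#' @export
gMatrix <- function(panel) {
  x <- if (is(panel, "SnpPanel")) genotypeCalls(panel) else as.matrix(panel)
  if (ncol(x) < 2L) stop("need at least 2 markers")
  n <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * pmax(n, 1L))  # allele-B frequency
  poly <- n > 0 & p > 0 & p < 1
  denom <- sum(2 * p[poly] * (1 - p[poly]))
  if (denom <= 0) stop("all markers monomorphic: zero denominator")
  W <- sweep(x, 2, 2 * p, "-")
  W[is.na(W)] <- 0                        # mean imputation, keeps G PSD
  G <- tcrossprod(W) / denom
  list(G = G, denominator = denom, W = W)
}

#' Within-population inbreeding coefficient from G
#'
#' Estimated as the mean of the diagonal of the genomic relationship
#' matrix minus one.  Negative estimates are reported as-is with a
#' warning.
#'
#' @param G square symmetric relationship matrix
#' @return Fst estimate
#' @export
fstFromG <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) == 0L) stop("empty relationship matrix")
  fst <- mean(diag(G)) - 1
  if (fst < 0) warning("negative Fst estimate (", signif(fst, 4), ")")
  fst
}

#' Effective population size from Fst
#'
#' Two variants are provided for each population.  For the hybrid panel
#' itself: \code{n_scaled} gives \eqn{N/(1+F_{st})}, \code{as_printed}
#' the literal \eqn{1/(1+F_{st})}.  For the hybrids' parents:
#' \code{n_scaled} gives \eqn{N/(2F_{st})}, \code{as_printed}
#' \eqn{1/(2F_{st})}.  The unscaled forms cannot exceed 1 and are kept
#' only for fidelity to their published typesetting; \code{n_scaled} is
#' the default and the form consistent with reported effective sizes.
#'
#' @param fst inbreeding coefficient (> -1; for parents > 0)
#' @param n census size N (>= 1); an explicit argument, never inferred
#' @param population \code{"hybrids"} or \code{"parents"}
#' @param mode \code{"n_scaled"} (default) or \code{"as_printed"}
#' @return effective population size
#' @export
effectiveSize <- function(fst, n, population = c("hybrids", "parents"),
                          mode = c("n_scaled", "as_printed")) {
  population <- match.arg(population)
  mode <- match.arg(mode)
  if (fst <= -1) stop("fst must exceed -1")
  if (n < 1) stop("n must be >= 1")
  num <- if (mode == "n_scaled") n else 1
  if (population == "hybrids") {
    num / (1 + fst)
  } else {
    if (fst <= 0) stop("parents mode requires fst > 0")
    num / (2 * fst)
  }
}

#' Full kinship / effective-size analysis of a panel
#'
#' @param panel a \code{SnpPanel}
#' @param n census size used in the Ne formulas (default: number of
#'   individuals in the panel)
#' @param mode passed to \code{\link{effectiveSize}}
#' @return a \code{\link{KinshipResult}}
#' @export
kinshipAnalysis <- function(panel, n = nInd(panel),
                            mode = c("n_scaled", "as_printed")) {
  mode <- match.arg(mode)
  gm <- gMatrix(panel)
  fst <- fstFromG(gm$G)
  neP <- if (fst > 0) effectiveSize(fst, n, "parents", mode) else NA_real_
  new("KinshipResult", G = gm$G, fst = fst, nInd = as.integer(nInd(panel)),
      neHybrid = effectiveSize(fst, n, "hybrids", mode),
      neParents = neP, mode = mode, denominator = gm$denominator)
}
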