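## Bayesian admixture inference (STRUCTURE-style), L(K) estimation,
## Evanno delta-K, replicate label alignment, and the 60% membership rule.

#' Configuration for admixture structure analysis
#'
#' Desk-scale defaults (10,000 sweeps / 5,000 burn-in) keep a full K-grid
#' run tractable on one CPU; production-scale chains (e.g. one million
#' sweeps, 500,000 burn-in) are available by setting the fields.
#'
#' @param kMin,kMax range of the number of ancestral populations
#' @param replicates independent chains per K
#' @param sweeps MCMC sweeps per chain
#' @param burnin sweeps discarded before recording (must be < sweeps)
#' @param alpha Dirichlet prior parameter for ancestry proportions
#'   (fixed; the sampler stays fully conjugate)
#' @param lambda Beta prior parameter for population allele frequencies
#' @param seed master seed; each (K, replicate) chain gets its own
#'   deterministic sub-seed, so adding replicates never perturbs earlier
#'   ones
#' @return a list of class \code{structureConfig}
#' @export
structureConfig <- function(kMin = 1, kMax = 10, replicates = 10,
                            sweeps = 10000, burnin = 5000,
                            alpha = 1.0, lambda = 1.0, seed = 1) {
  stopifnot(kMin >= 1, kMax >= kMin, replicates >= 1, burnin < sweeps,
            alpha > 0, lambda > 0)
  structure(list(kMin = as.integer(kMin), kMax = as.integer(kMax),
                 replicates = as.integer(replicates),
                 sweeps = as.integer(sweeps), burnin = as.integer(burnin),
                 alpha = alpha, lambda = lambda, seed = as.integer(seed)),
            class = "structureConfig")
}

## Deterministic sub-seed per (K, replicate): a fixed integer hash of the
## master seed and chain coordinates, kept inside 32-bit range.
deriveSeed <- function(master, K, rep) {
  h <- (as.double(master) * 2654435761 + K * 97003969 + rep * 15485863) %%
    2147483629
  as.integer(h) + 1L
}

#' Run one admixture Gibbs chain
#'
#' Each sweep (i) samples the ancestral origin of each of the two allele
#' copies per individual x marker from a categorical distribution
#' proportional to \eqn{q_{ik} f(allele | p_{kl})}, (ii) samples each
#' population allele frequency from its Beta conjugate posterior, and
#' (iii) samples each individual's ancestry vector from its Dirichlet
#' conjugate posterior.  Missing calls are skipped.  The data
#' log-likelihood is recorded at every post-burn-in sweep and Q is the
#' posterior mean.
#'
#' @param panel a \code{SnpPanel} (QC'd)
#' @param K number of ancestral populations (>= 1)
#' @param config a \code{\link{structureConfig}}
#' @param seed chain seed (default: derived from the config master seed
#'   for replicate 1)
#' @return an \code{\link{AncestryResult}}; non-convergence (split-half
#'   L(K) discrepancy) is flagged, not fatal
#' @export
gibbsAdmixture <- function(panel, K, config = structureConfig(),
                           seed = deriveSeed(config$seed, K, 1)) {
  stopifnot(K >= 1)
  x <- genotypeCalls(panel)
  if (K > nrow(x))
    warning("K (", K, ") exceeds the number of individuals (", nrow(x), ")")
  set.seed(seed)
  fit <- gibbs_admixture_cpp(x, as.integer(K), config$sweeps, config$burnin,
                             config$alpha, config$lambda)
  Q <- fit$Q
  dimnames(Q) <- list(rownames(x), paste0("pop", seq_len(K)))
  P <- fit$P
  dimnames(P) <- list(paste0("pop", seq_len(K)), colnames(x))
  tr <- fit$lnL
  half <- length(tr) %/% 2
  conv <- TRUE
  if (half >= 2) {
    l1 <- estimateLK(tr[seq_len(half)])
    l2 <- estimateLK(tr[(half + 1):length(tr)])
    spread <- stats::sd(tr)
    conv <- abs(l1 - l2) <= max(5 * spread, 1e-8)
  }
  new("AncestryResult", K = as.integer(K), Q = Q, P = P, lnL = tr,
      LofK = estimateLK(tr), seed = as.integer(seed), converged = conv)
}

#' Evanno L(K) summary of a log-likelihood trace
#'
#' The mean of the post-burn-in log-likelihood trace minus half its
#' (sample) variance — the standard model-evidence proxy used for
#' delta-K.
#'
#' @param lnLTrace numeric trace of length >= 1
#' @return mean(trace) - var(trace)/2 (a constant trace returns itself)
#' @export
estimateLK <- function(lnLTrace) {
  if (length(lnLTrace) == 0L) stop("empty log-likelihood trace")
  v <- if (length(lnLTrace) >= 2L) stats::var(lnLTrace) else 0
  mean(lnLTrace) - v / 2
}

#' Run the full K-grid of admixture chains
#'
#' @param panel a \code{SnpPanel}
#' @param config a \code{\link{structureConfig}}
#' @return list with \code{results} (nested list,
#'   \code{results[[as.character(K)]][[rep]]} an
#'   \code{\link{AncestryResult}} with replicate Q matrices label-aligned
#'   within each K) and \code{L} (data.frame \code{K, rep, L})
#' @export
runStructure <- function(panel, config = structureConfig()) {
  ks <- config$kMin:config$kMax
  results <- list()
  rows <- list()
  for (K in ks) {
    runs <- lapply(seq_len(config$replicates), function(r)
      gibbsAdmixture(panel, K, config, seed = deriveSeed(config$seed, K, r)))
    runs <- alignLabels(runs)
    results[[as.character(K)]] <- runs
    rows[[as.character(K)]] <- data.frame(
      K = K, rep = seq_len(config$replicates),
      L = vapply(runs, function(x) x@LofK, 0))
  }
  list(results = results, L = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Evanno delta-K table
#'
#' \eqn{\Delta K = m(|L(K+1) - 2L(K) + L(K-1)|) / s(L(K))}: the mean (over
#' replicate-paired runs) absolute second difference of L(K), divided by
#' the sample standard deviation of L(K) across replicates.  Defined only
#' at interior K; K values whose replicate sd is zero (or with a single
#' replicate) get \code{NA}.
#'
#' @param Ltable data.frame \code{K, rep, L} as returned by
#'   \code{\link{runStructure}}
#' @return data.frame \code{K, mean_L, sd_L, deltaK, argmax} covering the
#'   full K grid; \code{argmax} marks the interior K maximizing delta-K
#' @export
deltaK <- function(Ltable) {
  ks <- sort(unique(Ltable$K))
  if (length(ks) < 3L) stop("need >= 3 consecutive K values")
  meanL <- tapply(Ltable$L, Ltable$K, mean)
  sdL <- tapply(Ltable$L, Ltable$K, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    sub <- lapply(ks[(i - 1):(i + 1)], function(k)
      Ltable$L[Ltable$K == k][order(Ltable$rep[Ltable$K == k])])
    if (!length(unique(lengths(sub))) == 1L)
      stop("unequal replicate counts across K")
    second <- abs(sub[[3]] - 2 * sub[[2]] + sub[[1]])
    s <- sdL[as.character(ks[i])]
    if (is.na(s) || s == 0) next          # undefined, flagged as NA
    dk[i] <- mean(second) / s
  }
  best <- if (all(is.na(dk))) NA_integer_ else which.max(dk)
  data.frame(K = ks, mean_L = as.numeric(meanL[as.character(ks)]),
             sd_L = as.numeric(sdL[as.character(ks)]), deltaK = dk,
             argmax = seq_along(ks) == best & !is.na(dk),
             row.names = NULL)
}

#' Assign individuals to ancestral groups by the 60% rule
#'
#' An individual belongs to its maximum-Q population when that proportion
#' strictly exceeds the threshold, and to the \code{"mixed"} population
#' otherwise (a Q of exactly 0.60 is mixed).
#'
#' @param result an \code{\link{AncestryResult}} (or a Q matrix)
#' @param threshold membership threshold (default 0.60)
#' @return named character vector, individual -> population label or
#'   \code{"mixed"}
#' @export
assignGroups <- function(result, threshold = 0.60) {
  Q <- if (is(result, "AncestryResult")) result@Q else as.matrix(result)
  labs <- colnames(Q)
  if (is.null(labs)) labs <- paste0("pop", seq_len(ncol(Q)))
  out <- apply(Q, 1, function(row) {
    k <- which.max(row)
    if (row[k] > threshold) labs[k] else "mixed"
  })
  stats::setNames(as.character(out), rownames(Q))
}

#' Align replicate runs across label switching
#'
#' Greedily permutes the Q columns (and P rows) of each replicate to
#' maximize column-wise agreement with the first replicate; deterministic.
#'
#' @param results list of \code{\link{AncestryResult}} objects with the
#'   same K and individuals
#' @return the list with columns permuted into a common labeling
#' @export
alignLabels <- function(results) {
  if (length(results) <= 1L) return(results)
  K <- results[[1]]@K
  ref <- results[[1]]@Q
  if (K == 1L) return(results)
  for (r in seq_along(results)[-1]) {
    Q <- results[[r]]@Q
    ## similarity: negative column RMSE (robust when a column is constant)
    sim <- matrix(0, K, K)
    for (a in seq_len(K)) for (b in seq_len(K))
      sim[a, b] <- -sqrt(mean((ref[, a] - Q[, b])^2))
    perm <- integer(K)
    usedA <- usedB <- logical(K)
    for (step in seq_len(K)) {
      masked <- sim
      masked[usedA, ] <- -Inf
      masked[, usedB] <- -Inf
      ij <- which(masked == max(masked), arr.ind = TRUE)[1, ]
      perm[ij[1]] <- ij[2]
      usedA[ij[1]] <- TRUE
      usedB[ij[2]] <- TRUE
    }
    res <- results[[r]]
    res@Q <- Q[, perm, drop = FALSE]
    colnames(res@Q) <- colnames(ref)
    res@P <- res@P[perm, , drop = FALSE]
    rownames(res@P) <- rownames(results[[1]]@P)
    results[[r]] <- res
  }
  results
}

#' Average the aligned replicate Q matrices for one K
#'
#' @param runs list of label-aligned \code{\link{AncestryResult}} objects
#' @return the element-wise mean Q matrix
#' @export
meanQ <- function(runs) {
  Reduce(`+`, lapply(runs, function(x) x@Q)) / length(runs)
}
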