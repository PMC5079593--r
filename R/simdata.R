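## Balding-Nichols synthetic genotypes: admixed/pure outbred populations,
## fully inbred line panels, F1 single-cross hybrids, MCAR missingness,
## and a study-scale wrapper emulating a commercial hybrid panel plus a
## diverse inbred reference panel.  Truth records accompany every output
## so recovery tests are self-contained.

#' Simulation configuration
#'
#' @param nMarkers number of SNP markers
#' @param K number of ancestral populations
#' @param F Balding-Nichols differentiation parameter in (0, 1):
#'   population allele frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F)
#'   around the ancestral frequency p
#' @param freqRange ancestral frequencies are Uniform on this interval
#' @param alpha Dirichlet admixture parameter for individual ancestry, or
#'   \code{"pure"} for one-hot ancestry
#' @param nPerPop individuals per population (scalar or length-K vector)
#' @param missingRate MCAR missingness rate in [0, 1)
#' @param mode \code{"outbred"} or \code{"inbred_lines"}
#' @param seed master seed; all randomness flows from it through named
#'   substreams (frequencies, ancestry, allele copies, missingness)
#' @return list of class \code{simConfig}
#' @export
simConfig <- function(nMarkers = 768, K = 2, F = 0.2,
                      freqRange = c(0.1, 0.9), alpha = "pure",
                      nPerPop = 10, missingRate = 0,
                      mode = c("outbred", "inbred_lines"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(nMarkers >= 1, K >= 1, missingRate >= 0, missingRate < 1,
            freqRange[1] > 0, freqRange[2] < 1, freqRange[1] <= freqRange[2])
  if (F <= 0 || F >= 1) stop("F must lie strictly inside (0, 1)")
  if (length(nPerPop) == 1L) nPerPop <- rep(nPerPop, K)
  stopifnot(length(nPerPop) == K)
  structure(list(nMarkers = as.integer(nMarkers), K = as.integer(K), F = F,
                 freqRange = freqRange, alpha = alpha,
                 nPerPop = as.integer(nPerPop), missingRate = missingRate,
                 mode = mode, seed = as.integer(seed)),
            class = "simConfig")
}

## Substream seeds derived deterministically from the master seed.
subSeed <- function(master, what) {
  offs <- c(freqs = 11, ancestry = 23, copies = 37, missing = 53,
            markers = 71)
  as.integer((as.double(master) * 48271 + offs[[what]] * 69621) %% 2147483629) + 1L
}

## Random marker metadata: distinct nucleotide pairs, 10 chromosomes.
simMarkers <- function(nMarkers, seed, prefix = "M") {
  set.seed(seed)
  pair <- t(vapply(seq_len(nMarkers),
                   function(i) sort(sample(nucleotides, 2)), c("", "")))
  data.frame(marker_id = sprintf("%s%05d", prefix, seq_len(nMarkers)),
             chromosome = as.character(sample(1:10, nMarkers, replace = TRUE)),
             position = sample.int(3e8, nMarkers),
             allele_a = pair[, 1], allele_b = pair[, 2],
             stringsAsFactors = FALSE)
}

## Balding-Nichols population frequencies around ancestral p.
bnFreq <- function(p, F) {
  f <- rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pmin(pmax(f, 1e-6), 1 - 1e-6)
}

drawQ <- function(n, K, alpha) {
  if (identical(alpha, "pure")) stop("drawQ called with pure alpha")
  g <- matrix(rgamma(n * K, shape = alpha), n, K)
  g / rowSums(g)
}

## Draw diploid dosages given per-individual ancestry Q and K x L
## population allele-B frequencies.
drawGenotypes <- function(Q, popFreq) {
  n <- nrow(Q); L <- ncol(popFreq); K <- nrow(popFreq)
  dosage <- matrix(0L, n, L)
  cum <- t(apply(Q, 1, cumsum))
  for (copy in 1:2) {
    u <- matrix(runif(n * L), n, L)
    origin <- matrix(1L, n, L)
    if (K > 1) for (k in 1:(K - 1))
      origin <- origin + (u > cum[, k])
    pr <- matrix(popFreq[cbind(as.vector(origin), rep(seq_len(L), each = n))],
                 n, L)
    dosage <- dosage + (matrix(runif(n * L), n, L) < pr)
  }
  storage.mode(dosage) <- "integer"
  dosage
}

#' Simulate admixed (or pure) outbred genotypes
#'
#' Ancestral allele frequencies are Uniform on \code{freqRange};
#' population frequencies follow the Balding-Nichols Beta model with
#' differentiation \code{F}; individual ancestry Q is Dirichlet
#' (\code{alpha}) or one-hot (\code{alpha = "pure"}); each of the two
#' allele copies draws its origin from Q and its allele from the origin
#' population's frequency.  Deterministic under the config seed.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{panel} (a \code{\link{SnpPanel}} with groups
#'   \code{pop1..popK} for pure ancestry) and \code{truth} (ancestral and
#'   per-population frequencies of allele B, true Q, realized per-marker
#'   Fst)
#' @export
simulateAdmixed <- function(config) {
  L <- config$nMarkers; K <- config$K
  markers <- simMarkers(L, subSeed(config$seed, "markers"))
  set.seed(subSeed(config$seed, "freqs"))
  pAnc <- runif(L, config$freqRange[1], config$freqRange[2])
  popFreq <- t(vapply(seq_len(K), function(k) bnFreq(pAnc, config$F),
                      numeric(L)))
  n <- sum(config$nPerPop)
  set.seed(subSeed(config$seed, "ancestry"))
  if (identical(config$alpha, "pure")) {
    popOf <- rep(seq_len(K), config$nPerPop)
    Q <- matrix(0, n, K)
    Q[cbind(seq_len(n), popOf)] <- 1
  } else {
    Q <- drawQ(n, K, config$alpha)
    popOf <- max.col(Q)
  }
  set.seed(subSeed(config$seed, "copies"))
  dosage <- drawGenotypes(Q, popFreq)
  ids <- sprintf("I%03d", seq_len(n))
  dimnames(dosage) <- list(ids, markers$marker_id)
  rownames(Q) <- ids
  colnames(Q) <- paste0("pop", seq_len(K))
  groups <- stats::setNames(paste0("pop", popOf), ids)
  panel <- SnpPanel(dosage, markers, groups)
  if (config$missingRate > 0)
    panel <- applyMissingness(panel, config$missingRate,
                              subSeed(config$seed, "missing"))
  pbar <- colMeans(popFreq)
  fstMark <- apply(popFreq, 2, stats::var) * (K - 1) / K / (pbar * (1 - pbar))
  list(panel = panel,
       truth = list(ancestralFreq = pAnc, popFreq = popFreq, Q = Q,
                    fstPerMarker = fstMark, popOf = popOf))
}

#' Simulate a panel of fully inbred lines
#'
#' One allele per locus is drawn from the line's population frequency and
#' duplicated, so every call is homozygous (dosage 0 or 2).
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{panel} and \code{truth} as in
#'   \code{\link{simulateAdmixed}}
#' @export
simulateInbredPanel <- function(config) {
  L <- config$nMarkers; K <- config$K
  markers <- simMarkers(L, subSeed(config$seed, "markers"))
  set.seed(subSeed(config$seed, "freqs"))
  pAnc <- runif(L, config$freqRange[1], config$freqRange[2])
  popFreq <- t(vapply(seq_len(K), function(k) bnFreq(pAnc, config$F),
                      numeric(L)))
  n <- sum(config$nPerPop)
  popOf <- rep(seq_len(K), config$nPerPop)
  set.seed(subSeed(config$seed, "copies"))
  pr <- popFreq[popOf, , drop = FALSE]
  dosage <- 2L * (matrix(runif(n * L), n, L) < pr)
  storage.mode(dosage) <- "integer"
  ids <- sprintf("L%03d", seq_len(n))
  dimnames(dosage) <- list(ids, markers$marker_id)
  Q <- matrix(0, n, K, dimnames = list(ids, paste0("pop", seq_len(K))))
  Q[cbind(seq_len(n), popOf)] <- 1
  groups <- stats::setNames(paste0("pop", popOf), ids)
  panel <- SnpPanel(dosage, markers, groups)
  if (config$missingRate > 0)
    panel <- applyMissingness(panel, config$missingRate,
                              subSeed(config$seed, "missing"))
  list(panel = panel,
       truth = list(ancestralFreq = pAnc, popFreq = popFreq, Q = Q,
                    popOf = popOf))
}

#' Cross inbred lines into F1 single-cross hybrids
#'
#' Each F1 dosage is the parental mean: opposite homozygotes give a
#' heterozygote, identical homozygotes breed true, and a missing call in
#' either parent is missing in the F1.
#'
#' @param lines a \code{SnpPanel} of fully homozygous lines
#' @param pairs 2-column matrix or data.frame of parent ids, one row per
#'   hybrid
#' @param hybridNames optional hybrid ids (default "p1 x p2")
#' @return a \code{SnpPanel} of the F1 hybrids, with a \code{pedigree}
#'   data.frame attribute
#' @export
crossHybrids <- function(lines, pairs, hybridNames = NULL) {
  pairs <- as.matrix(pairs)
  x <- genotypeCalls(lines)
  if (!all(pairs %in% rownames(x)))
    stop("unknown parent id: ", setdiff(as.vector(pairs), rownames(x))[1])
  hetIdx <- which(x == 1L, arr.ind = TRUE)
  used <- unique(as.vector(pairs))
  bad <- hetIdx[rownames(x)[hetIdx[, 1]] %in% used, , drop = FALSE]
  if (nrow(bad))
    stop("heterozygous parent call: parent ", rownames(x)[bad[1, 1]],
         " at marker ", colnames(x)[bad[1, 2]])
  f1 <- (x[pairs[, 1], , drop = FALSE] + x[pairs[, 2], , drop = FALSE]) / 2L
  storage.mode(f1) <- "integer"
  if (is.null(hybridNames))
    hybridNames <- paste(pairs[, 1], pairs[, 2], sep = "x")
  rownames(f1) <- hybridNames
  out <- SnpPanel(f1, markerInfo(lines))
  attr(out, "pedigree") <- data.frame(hybrid = hybridNames,
                                      parent1 = pairs[, 1],
                                      parent2 = pairs[, 2],
                                      stringsAsFactors = FALSE)
  out
}

#' Set calls missing completely at random
#'
#' @param panel a \code{SnpPanel}
#' @param rate per-call missingness probability in [0, 1)
#' @param seed RNG seed (deterministic output)
#' @return the panel with calls masked
#' @export
applyMissingness <- function(panel, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  x <- genotypeCalls(panel)
  set.seed(seed)
  x[matrix(runif(length(x)) < rate, nrow(x), ncol(x))] <- NA_integer_
  new("SnpPanel", calls = x, markers = markerInfo(panel),
      groups = groupAssignment(panel))
}

#' Simulate study-scale hybrid and inbred reference panels
#'
#' Emulates a commercial single-cross hybrid panel and a diverse inbred
#' reference panel that share part of their marker sets: 20 F1 hybrids in
#' 7 company groups genotyped at 768 SNPs (2% missing calls), and 27
#' fully inbred reference lines at 1,536 SNPs (1% missing), of which 340
#' marker ids are common to both arrays.  Company breeding pools are
#' Balding-Nichols populations (F = 0.10) around a shared elite pool;
#' each company's hybrids are single crosses of inbred parents drawn from
#' its pool.  Reference lines are drawn from 4 diverse ancestral
#' populations (F = 0.30), except the first line, which is drawn from the
#' hybrids' elite pool (a founder-line analogue expected to co-cluster
#' with the hybrids).
#'
#' @param seed master seed
#' @param nSharedMarkers number of marker ids common to both arrays
#' @return list with \code{hybrids} and \code{lines} (\code{SnpPanel}s
#'   with groups) and \code{truth}
#' @export
simulateStudyPanels <- function(seed = 1, nSharedMarkers = 340) {
  nHyb <- 768L; nLin <- 1536L
  companies <- c(Agromen = 1L, Biomatrix = 3L, Dekalb = 4L, Dow = 5L,
                 Pioneer = 2L, SantaHelena = 1L, Syngenta = 4L)
  nComp <- length(companies)
  ## one global marker universe; the hybrid array takes nSharedMarkers of
  ## its ids from the shared block
  markersAll <- simMarkers(nHyb + nLin - nSharedMarkers,
                           subSeed(seed, "markers"), prefix = "PZ")
  sharedIdx <- seq_len(nSharedMarkers)
  hybIdx <- seq_len(nHyb)                              # shared block first
  linIdx <- c(sharedIdx, (nHyb + 1):(nHyb + nLin - nSharedMarkers))
  set.seed(subSeed(seed, "freqs"))
  pAnc <- runif(nrow(markersAll), 0.1, 0.9)
  pElite <- bnFreq(pAnc, 0.15)                         # elite commercial pool
  compFreq <- t(vapply(seq_len(nComp), function(k) bnFreq(pElite, 0.10),
                       numeric(length(pAnc))))
  refFreq <- t(vapply(1:4, function(k) bnFreq(pAnc, 0.30),
                      numeric(length(pAnc))))
  ## inbred parents per company, then single crosses
  set.seed(subSeed(seed, "copies"))
  nPar <- pmax(2L, companies + 1L)
  parentDos <- NULL; parentCompany <- integer(0)
  for (k in seq_len(nComp)) {
    pr <- matrix(rep(compFreq[k, hybIdx], each = nPar[k]), nPar[k])
    d <- 2L * (matrix(runif(nPar[k] * nHyb), nPar[k]) < pr)
    parentDos <- rbind(parentDos, d)
    parentCompany <- c(parentCompany, rep(k, nPar[k]))
  }
  storage.mode(parentDos) <- "integer"
  parentIds <- sprintf("P_%s_%d", names(companies)[parentCompany],
                       as.integer(stats::ave(parentCompany, parentCompany,
                                             FUN = seq_along)))
  rownames(parentDos) <- parentIds
  mh <- markersAll[hybIdx, ]; rownames(mh) <- NULL
  parents <- SnpPanel(parentDos, mh)
  pairs <- NULL; hybGroup <- character(0); hybIds <- character(0)
  for (k in seq_len(nComp)) {
    ids <- parentIds[parentCompany == k]
    for (h in seq_len(companies[k])) {
      pq <- sample(ids, 2)
      pairs <- rbind(pairs, pq)
      nm <- sprintf("H_%s_%d", names(companies)[k], h)
      hybIds <- c(hybIds, nm)
      hybGroup <- c(hybGroup, names(companies)[k])
    }
  }
  hybrids <- crossHybrids(parents, pairs, hybridNames = hybIds)
  ped <- attr(hybrids, "pedigree")
  groupAssignment(hybrids) <- stats::setNames(hybGroup, hybIds)
  hybrids <- applyMissingness(hybrids, 0.02, subSeed(seed, "missing"))
  ## reference lines: 27 inbreds, line 1 from the elite pool
  set.seed(subSeed(seed, "ancestry"))
  linPop <- c(0L, sample(1:4, 26, replace = TRUE))     # 0 = elite pool
  freqOf <- function(p) if (p == 0L) pElite[linIdx] else refFreq[p, linIdx]
  linDos <- t(vapply(linPop, function(p)
    2L * as.integer(runif(nLin) < freqOf(p)), integer(nLin)))
  storage.mode(linDos) <- "integer"
  linIds <- sprintf("NAM%02d", seq_len(27))
  rownames(linDos) <- linIds
  ml <- markersAll[linIdx, ]; rownames(ml) <- NULL
  lines <- SnpPanel(linDos, ml,
                    stats::setNames(ifelse(linPop == 0L, "elite",
                                           paste0("ref", linPop)), linIds))
  lines <- applyMissingness(lines, 0.01, subSeed(seed, "missing") + 1L)
  list(hybrids = hybrids, lines = lines,
       truth = list(sharedMarkers = markersAll$marker_id[sharedIdx],
                    companies = companies, pedigree = ped,
                    linePop = linPop, pAnc = pAnc, pElite = pElite,
                    compFreq = compFreq, refFreq = refFreq))
}
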