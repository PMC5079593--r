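#' @import methods
#' @importFrom stats cor cor.test cophenetic rbinom runif rbeta rgamma var sd
#' @importFrom utils write.table read.delim
#' @useDynLib maizediv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MISSING_TOKENS <- c("NN", "--", "NA", "", "??")

#' SnpPanel: diploid biallelic SNP genotypes
#'
#' The central data container: an individuals x markers matrix of allele-B
#' dosages (0 = homozygous allele A, 1 = heterozygous, 2 = homozygous
#' allele B, \code{NA} = missing), marker metadata, and an optional group
#' (company / population) assignment.  Allele A is always the
#' alphabetically first allele observed at the marker, so dosage coding is
#' deterministic regardless of file row order.
#'
#' @slot calls integer matrix, individuals in rows (rownames = ids),
#'   markers in columns (colnames = marker ids); values 0/1/2/NA.
#' @slot markers data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{position}, \code{allele_a}, \code{allele_b};
#'   one row per column of \code{calls}.
#' @slot groups named character vector mapping individual id to group
#'   label; may be empty.
#'
#' @export
setClass("SnpPanel",
         slots = c(calls = "matrix", markers = "data.frame",
                   groups = "character"))

setValidity("SnpPanel", function(object) {
  x <- object@calls
  mk <- object@markers
  msg <- character()
  if (nrow(x) > 0 && is.null(rownames(x)))
    msg <- c(msg, "calls must have individual ids as rownames")
  if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicate individual ids")
  need <- c("marker_id", "chromosome", "position", "allele_a", "allele_b")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(mk) != ncol(x)) msg <- c(msg, "markers rows must match calls columns")
    if (anyDuplicated(mk$marker_id)) msg <- c(msg, "duplicate marker ids")
    if (any(mk$allele_a == mk$allele_b)) msg <- c(msg, "allele_a must differ from allele_b")
  }
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% 0:2)) msg <- c(msg, "non-missing calls must be 0, 1 or 2")
  if (length(object@groups)) {
    if (is.null(names(object@groups))) msg <- c(msg, "groups must be named by individual id")
    else if (!all(names(object@groups) %in% rownames(x)))
      msg <- c(msg, "groups refer to individuals absent from the panel")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpPanel
#'
#' @param calls numeric/integer matrix of allele-B dosages (0/1/2/NA) with
#'   individuals in rows and markers in columns.  Rownames are required;
#'   missing colnames are taken from \code{markers$marker_id}.
#' @param markers optional marker metadata data.frame
#'   (\code{marker_id, chromosome, position, allele_a, allele_b}).  When
#'   omitted, placeholder A/B alleles and unknown positions are used.
#' @param groups optional named character vector (individual id -> group
#'   label) or a 2-column data.frame \code{individual_id, group}.
#' @return a \code{SnpPanel}
#' @export
SnpPanel <- function(calls, markers = NULL, groups = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(markers)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("M%04d", seq_len(ncol(calls)))
    nm <- ncol(calls)
    markers <- data.frame(marker_id = ids, chromosome = rep("0", nm),
                          position = seq_len(nm),
                          allele_a = rep("A", nm), allele_b = rep("B", nm),
                          stringsAsFactors = FALSE)
  }
  colnames(calls) <- markers$marker_id
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  if (is.null(groups)) groups <- character()
  new("SnpPanel", calls = calls, markers = markers, groups = groups)
}

#' @describeIn SnpPanel number of individuals
#' @param object,x a \code{SnpPanel}
#' @export
nInd <- function(object) nrow(object@calls)

#' @describeIn SnpPanel number of markers
#' @export
nMarkers <- function(object) ncol(object@calls)

#' @describeIn SnpPanel individual identifiers
#' @export
indNames <- function(object) rownames(object@calls)

#' @describeIn SnpPanel marker identifiers
#' @export
markerIds <- function(object) object@markers$marker_id

#' @describeIn SnpPanel marker metadata data.frame
#' @export
markerInfo <- function(object) object@markers

#' @describeIn SnpPanel dosage matrix (individuals x markers, 0/1/2/NA)
#' @export
genotypeCalls <- function(object) object@calls

#' @describeIn SnpPanel group assignment (named character vector)
#' @export
groupAssignment <- function(object) object@groups

#' Assign groups to a panel
#'
#' @param object a \code{SnpPanel}
#' @param value named character vector or 2-column data.frame
#' @return the updated panel
#' @export
`groupAssignment<-` <- function(object, value) {
  if (is.data.frame(value))
    value <- stats::setNames(as.character(value[[2]]), as.character(value[[1]]))
  object@groups <- value
  validObject(object)
  object
}

#' Subset a SnpPanel
#'
#' @param x a \code{SnpPanel}
#' @param i individual index/names
#' @param j marker index/names
#' @param ... ignored
#' @param drop ignored, always \code{FALSE}
#' @export
setMethod("[", "SnpPanel", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  mk <- x@markers
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, mk$marker_id) else j
    calls <- calls[, jj, drop = FALSE]
    mk <- mk[jj, , drop = FALSE]
    rownames(mk) <- NULL
  }
  grp <- x@groups[names(x@groups) %in% rownames(calls)]
  new("SnpPanel", calls = calls, markers = mk, groups = grp)
})

setMethod("show", "SnpPanel", function(object) {
  cat("SnpPanel:", nInd(object), "individuals x", nMarkers(object), "markers\n")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (length(object@groups)) {
    tb <- table(object@groups)
    cat("  groups:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "), "\n")
  }
})

#' ClusterTree: rooted ultrametric UPGMA tree
#'
#' Stores an average-linkage dendrogram in \code{hclust}-style merge order
#' with node heights (half the merge distance) and optional bootstrap
#' support percentages per internal node.
#'
#' @slot labels leaf labels in input order
#' @slot merge (n-1) x 2 integer matrix, \code{hclust} convention
#'   (negative = leaf index, positive = earlier internal node)
#' @slot heights internal-node heights, one per merge (leaves at 0)
#' @slot support bootstrap support per internal node in [0, 100], or NA
#'   when no bootstrap has been run
#' @export
setClass("ClusterTree",
         slots = c(labels = "character", merge = "matrix",
                   heights = "numeric", support = "numeric"))

setValidity("ClusterTree", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "merge must have n-1 rows")
  if (length(object@heights) != n - 1L) msg <- c(msg, "one height per merge")
  if (is.unsorted(object@heights)) msg <- c(msg, "heights must be non-decreasing")
  if (any(object@heights < 0)) msg <- c(msg, "heights must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterTree", function(object) {
  cat("ClusterTree:", length(object@labels), "leaves, root height",
      signif(max(object@heights), 4), "\n")
  if (!all(is.na(object@support)))
    cat("  bootstrap support: ",
        paste(round(object@support), collapse = " "), "\n", sep = "")
})

#' KinshipResult: genomic relationship matrix and derived quantities
#'
#' @slot G individuals x individuals relationship matrix
#' @slot fst within-population inbreeding coefficient,
#'   mean(diag(G)) - 1
#' @slot nInd number of individuals
#' @slot neHybrid effective size of the panel itself
#' @slot neParents effective size of the panel's parents
#' @slot mode "n_scaled" or "as_printed"
#' @slot denominator the 2*sum(p*q) scaling of G
#' @export
setClass("KinshipResult",
         slots = c(G = "matrix", fst = "numeric", nInd = "integer",
                   neHybrid = "numeric", neParents = "numeric",
                   mode = "character", denominator = "numeric"))

setMethod("show", "KinshipResult", function(object) {
  cat("KinshipResult:", object@nInd, "individuals\n")
  cat(sprintf("  Fst = %.4f  Ne(panel) = %.2f  Ne(parents) = %.2f  [%s]\n",
              object@fst, object@neHybrid, object@neParents, object@mode))
})

#' AncestryResult: posterior summary of one admixture run
#'
#' @slot K number of ancestral populations
#' @slot Q individuals x K posterior-mean ancestry proportions
#' @slot P K x markers posterior allele-B frequency draws (final sweep)
#' @slot lnL per-sweep data log-likelihood after burn-in
#' @slot LofK mean(lnL) - var(lnL)/2, the Evanno L(K) summary
#' @slot seed RNG seed of the chain
#' @slot converged split-half L agreement flag
#' @export
setClass("AncestryResult",
         slots = c(K = "integer", Q = "matrix", P = "matrix",
                   lnL = "numeric", LofK = "numeric", seed = "integer",
                   converged = "logical"))

setMethod("show", "AncestryResult", function(object) {
  cat("AncestryResult: K =", object@K, ",", nrow(object@Q), "individuals\n")
  cat(sprintf("  L(K) = %.2f over %d post-burn-in sweeps%s\n",
              object@LofK, length(object@lnL),
              if (isTRUE(object@converged)) "" else "  [convergence flagged]"))
})
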