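## Nei DA genetic distances, UPGMA clustering with deterministic
## tie-breaking, locus-bootstrap node support, and Newick export.

#' Nei DA distance between two frequency units
#'
#' For biallelic loci with allele-A frequencies \eqn{x_j, y_j} in the two
#' units, \eqn{D_A = \frac{1}{r}\sum_j (1 - \sqrt{x_j y_j} -
#' \sqrt{(1-x_j)(1-y_j)})} over the r loci defined in both units (pairwise
#' deletion of missing loci).  \code{sqrtForm = FALSE} gives the variant
#' without the square root (\eqn{1 - \sum_i x_{ij} y_{ij}}), kept for
#' comparison; note that variant is not zero for identical non-fixed
#' profiles.
#'
#' @param x,y numeric vectors of allele-A frequencies (NA = locus missing
#'   in that unit)
#' @param sqrtForm logical; use the square-root (Nei et al. 1983) form
#' @return distance in [0, 1]
#' @export
neiDa <- function(x, y, sqrtForm = TRUE) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no shared loci between units")
  x <- x[ok]; y <- y[ok]
  s <- if (sqrtForm) sqrt(x * y) + sqrt((1 - x) * (1 - y))
       else x * y + (1 - x) * (1 - y)
  d <- mean(1 - s)
  min(max(d, 0), 1)                       # guard FP noise at the ends
}

## All pairwise DA distances from a unit x marker frequency table.
freqTableDistance <- function(ft, sqrtForm = TRUE) {
  n <- nrow(ft)
  d <- matrix(0, n, n, dimnames = list(rownames(ft), rownames(ft)))
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- neiDa(ft[i, ], ft[j, ], sqrtForm = sqrtForm)
  d
}

#' Nei DA distance matrix over individuals or groups
#'
#' Individuals are treated as one-member frequency units (a heterozygote
#' contributes frequencies (0.5, 0.5) at that locus); groups use pooled
#' allele frequencies.  Loci missing in either unit of a pair are dropped
#' pairwise.
#'
#' @param panel a \code{SnpPanel} (after QC)
#' @param units \code{"individuals"} or \code{"groups"}
#' @param groups optional named character vector overriding the panel's
#'   group assignment
#' @param sqrtForm passed to \code{\link{neiDa}}
#' @return symmetric labeled distance matrix with zero diagonal
#' @export
neiDistance <- function(panel, units = c("individuals", "groups"),
                        groups = NULL, sqrtForm = TRUE) {
  units <- match.arg(units)
  ft <- alleleFreqTable(panel, units = units, groups = groups)
  empty <- rowSums(!is.na(ft)) == 0
  if (any(empty))
    stop("unit with all-missing data: ", rownames(ft)[empty][1])
  freqTableDistance(ft, sqrtForm = sqrtForm)
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted average-linkage agglomeration.  Node heights are
#' half the merge distance, so the cophenetic distance between two leaves
#' equals the merge distance of their lowest common ancestor.  Ties are
#' broken deterministically on the lexicographically smallest
#' (smaller representative label, larger representative label) pair,
#' where a cluster is represented by its alphabetically first leaf.
#'
#' @param d symmetric labeled distance matrix (>= 2 labels, finite)
#' @return a \code{\link{ClusterTree}}
#' @export
upgmaTree <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 labels")
  if (any(!is.finite(d))) stop("non-finite distance entries")
  node <- -seq_len(n)                     # hclust coding for each active cluster
  size <- rep(1L, n)
  rep_lab <- labs                         # representative (min) leaf label
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(D)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- D[i, j]
      key <- sort(c(rep_lab[i], rep_lab[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node[i], node[j]))
    heights[step] <- best$d / 2
    ## average-linkage update into slot i, drop slot j
    newrow <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- 0
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    node[i] <- step
    keep <- setdiff(seq_len(m), j)
    D <- D[keep, keep, drop = FALSE]
    node <- node[keep]; size <- size[keep]; rep_lab <- rep_lab[keep]
  }
  ## enforce monotone heights against FP jitter (UPGMA is monotone in exact
  ## arithmetic)
  heights <- cummax(heights)
  new("ClusterTree", labels = labs, merge = merge, heights = heights,
      support = rep(NA_real_, n - 1L))
}

#' Convert a ClusterTree to an hclust object
#'
#' \code{hclust} heights are merge distances (twice the node heights), so
#' \code{stats::cophenetic} on the result gives leaf-to-leaf cophenetic
#' distances directly.
#'
#' @param tree a \code{ClusterTree}
#' @return an object of class \code{hclust}
#' @export
asHclust <- function(tree) {
  n <- length(tree@labels)
  structure(list(merge = tree@merge, height = 2 * tree@heights,
                 order = hclustOrder(tree@merge, n),
                 labels = tree@labels, method = "average",
                 call = match.call(), dist.method = "nei_da"),
            class = "hclust")
}

hclustOrder <- function(merge, n) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

## Leaf-label set of each internal node, as sorted character vectors.
treeClusters <- function(tree) {
  sets <- vector("list", nrow(tree@merge))
  for (k in seq_len(nrow(tree@merge))) {
    grab <- function(v) if (v < 0) tree@labels[-v] else sets[[v]]
    sets[[k]] <- sort(c(grab(tree@merge[k, 1]), grab(tree@merge[k, 2])))
  }
  sets
}

#' Locus-bootstrap node support for the UPGMA tree
#'
#' Builds the full-data UPGMA tree, then resamples loci with replacement
#' \code{nReps} times, rebuilds the tree each time, and annotates each
#' internal node of the full-data tree with the percentage of replicate
#' trees containing the same leaf cluster.  Nodes below 50% are flagged
#' (attribute \code{"weak_nodes"}): units under them are conventionally
#' left ungrouped.
#'
#' @param panel a \code{SnpPanel}
#' @param units,groups as in \code{\link{neiDistance}}
#' @param nReps number of bootstrap replicates (default 2000)
#' @param seed RNG seed; the same seed gives identical supports
#' @param sqrtForm passed to \code{\link{neiDa}}
#' @return the full-data \code{\link{ClusterTree}} with its
#'   \code{support} slot filled (percentages in [0, 100])
#' @export
bootstrapSupport <- function(panel, units = c("individuals", "groups"),
                             groups = NULL, nReps = 2000, seed = 1,
                             sqrtForm = TRUE) {
  units <- match.arg(units)
  if (nReps < 1) stop("nReps must be >= 1")
  ft <- alleleFreqTable(panel, units = units, groups = groups)
  if (nrow(ft) < 3L) stop("need at least 3 units for bootstrap support")
  if (ncol(ft) < 2L) stop("need at least 2 loci")
  ## canonical marker sort so the resampling index stream is invariant to
  ## input locus order
  ft <- ft[, order(colnames(ft)), drop = FALSE]
  full <- upgmaTree(freqTableDistance(ft, sqrtForm = sqrtForm))
  target <- treeClusters(full)
  key <- vapply(target, paste, "", collapse = "\r")
  hits <- numeric(length(target))
  L <- ncol(ft)
  set.seed(seed)
  for (r in seq_len(nReps)) {
    idx <- sample.int(L, L, replace = TRUE)
    bt <- upgmaTree(freqTableDistance(ft[, idx, drop = FALSE],
                                      sqrtForm = sqrtForm))
    bkey <- vapply(treeClusters(bt), paste, "", collapse = "\r")
    hits <- hits + (key %in% bkey)
  }
  full@support <- 100 * hits / nReps
  full
}

#' Internal nodes lacking consistency (support below a cutoff)
#'
#' Units under such nodes are conventionally left ungrouped when reading
#' the dendrogram.
#'
#' @param tree a \code{ClusterTree} with bootstrap support
#' @param cutoff support percentage below which a node is weak
#' @return integer indices of weak internal nodes
#' @export
weakNodes <- function(tree, cutoff = 50) {
  if (all(is.na(tree@support))) stop("tree has no bootstrap support")
  which(tree@support < cutoff)
}

quoteNewickLabel <- function(lab) {
  if (grepl("[][ (),:;']", lab))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

newickString <- function(tree, digits = 10) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  build <- function(v, parent_h) {
    if (v < 0) {
      paste0(quoteNewickLabel(tree@labels[-v]), ":", fmt(parent_h))
    } else {
      h <- tree@heights[v]
      sup <- tree@support[v]
      paste0("(", build(tree@merge[v, 1], h), ",",
             build(tree@merge[v, 2], h), ")",
             if (!is.na(sup)) fmt(sup) else "",
             ":", fmt(parent_h - h))
    }
  }
  root <- nrow(tree@merge)
  h <- tree@heights[root]
  sup <- tree@support[root]
  paste0("(", build(tree@merge[root, 1], h), ",",
         build(tree@merge[root, 2], h), ")",
         if (!is.na(sup)) fmt(sup) else "", ";")
}

#' Write a ClusterTree as Newick
#'
#' Branch lengths come from the ultrametric node heights; bootstrap
#' supports (if present) become internal-node labels.  Labels containing
#' Newick metacharacters are single-quoted.  The file parses back (e.g.
#' with \code{ape::read.tree}) to the same topology, heights and supports.
#'
#' @param tree a \code{ClusterTree}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeNewick <- function(tree, path) {
  writeLines(newickString(tree), path)
  invisible(path)
}

#' Convert a ClusterTree to an ape phylo object
#'
#' @param tree a \code{ClusterTree}
#' @return a rooted \code{ape::phylo} with node labels carrying bootstrap
#'   supports when present
#' @export
asPhylo <- function(tree) {
  ape::read.tree(text = newickString(tree))
}
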