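## Genotype file IO, numeric recoding, QC filtering and panel intersection.

nucleotides <- c("A", "C", "G", "T")

## Decode a character vector of diploid calls at one marker into dosages.
## Calls may be two-letter strings ("AA", "AG", unordered) or digits 0/1/2.
## Returns list(dosage, allele_a, allele_b).
decodeMarkerColumn <- function(calls, marker_id, alleles_hint = NULL) {
  calls <- toupper(trimws(calls))
  miss <- calls %in% MISSING_TOKENS | is.na(calls)
  obs <- calls[!miss]
  if (length(obs) && all(obs %in% c("0", "1", "2"))) {
    d <- suppressWarnings(as.integer(calls))
    d[miss] <- NA_integer_
    ab <- if (!is.null(alleles_hint)) alleles_hint else c("A", "B")
    return(list(dosage = d, allele_a = ab[1], allele_b = ab[2]))
  }
  if (any(nchar(obs) != 2L))
    stop("marker ", marker_id, ": calls must be two-letter diploid strings")
  letters_seen <- sort(unique(unlist(strsplit(obs, ""))))
  if (length(letters_seen) > 2L)
    stop("marker ", marker_id, ": more than 2 alleles observed (",
         paste(letters_seen, collapse = ","), ")")
  if (length(letters_seen) == 2L) {
    ab <- letters_seen                       # alphabetical: allele_a first
  } else if (length(letters_seen) == 1L) {
    other <- if (!is.null(alleles_hint)) setdiff(alleles_hint, letters_seen) else
      setdiff(nucleotides, letters_seen)[1]
    ab <- sort(c(letters_seen, other[1]))
  } else {
    ab <- if (!is.null(alleles_hint)) sort(alleles_hint) else c("A", "B")
  }
  d <- rep(NA_integer_, length(calls))
  nb <- vapply(strsplit(calls[!miss], ""), function(x) sum(x == ab[2]), 0L)
  d[!miss] <- nb
  list(dosage = d, allele_a = ab[1], allele_b = ab[2])
}

#' Read a genotype file into a SnpPanel
#'
#' Two dialects are supported.  \code{"individual"}: individual-major TSV
#' with header \code{id<TAB>marker1<TAB>...} and one row per individual;
#' calls are two-letter diploid strings (\code{AA}, \code{AG}; unordered)
#' or dosage digits 0/1/2; missing as \code{NN}, \code{--} or \code{NA}.
#' \code{"hapmap"}: marker-major TSV with columns
#' \code{rs# alleles chrom pos} followed by one column per individual with
#' diploid letter calls (\code{NN} missing).
#'
#' Alleles are inferred per marker from the observed calls; allele A is
#' the alphabetically first allele, so the dosage coding does not depend
#' on row order.
#'
#' @param path file path
#' @param format \code{"individual"} or \code{"hapmap"}
#' @return a \code{\link{SnpPanel}}
#' @export
readGenotypes <- function(path, format = c("individual", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  bad <- which(lengths(cells) != width)
  if (length(bad))
    stop("malformed row width at line ", bad[1], " of ", path,
         " (expected ", width, " fields, got ", lengths(cells)[bad[1]], ")")
  header <- cells[[1]]
  body <- cells[-1]
  if (format == "individual") {
    marker_ids <- header[-1]
    ind <- vapply(body, `[`, "", 1L)
    if (anyDuplicated(ind))
      stop("duplicate individual id: ", ind[duplicated(ind)][1])
    raw <- do.call(rbind, lapply(body, function(r) r[-1]))
    dimnames(raw) <- list(ind, marker_ids)
    dec <- lapply(seq_along(marker_ids), function(j)
      decodeMarkerColumn(raw[, j], marker_ids[j]))
    calls <- vapply(dec, `[[`, integer(length(ind)), "dosage")
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(ind))
    dimnames(calls) <- list(ind, marker_ids)
    markers <- data.frame(marker_id = marker_ids, chromosome = "0",
                          position = seq_along(marker_ids),
                          allele_a = vapply(dec, `[[`, "", "allele_a"),
                          allele_b = vapply(dec, `[[`, "", "allele_b"),
                          stringsAsFactors = FALSE)
  } else {
    ind <- header[-(1:4)]
    if (anyDuplicated(ind))
      stop("duplicate individual id: ", ind[duplicated(ind)][1])
    marker_ids <- vapply(body, `[`, "", 1L)
    if (anyDuplicated(marker_ids))
      stop("duplicate marker id: ", marker_ids[duplicated(marker_ids)][1])
    dec <- lapply(body, function(r) {
      hint <- strsplit(r[2], "/", fixed = TRUE)[[1]]
      if (length(hint) != 2L || hint[1] == hint[2]) hint <- NULL
      decodeMarkerColumn(r[-(1:4)], r[1], alleles_hint = hint)
    })
    calls <- vapply(dec, `[[`, integer(length(ind)), "dosage")
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(ind))
    dimnames(calls) <- list(ind, marker_ids)
    markers <- data.frame(marker_id = marker_ids,
                          chromosome = vapply(body, `[`, "", 3L),
                          position = as.integer(vapply(body, `[`, "", 4L)),
                          allele_a = vapply(dec, `[[`, "", "allele_a"),
                          allele_b = vapply(dec, `[[`, "", "allele_b"),
                          stringsAsFactors = FALSE)
  }
  SnpPanel(calls, markers)
}

#' Write a SnpPanel as individual-major genotype TSV
#'
#' Letter calls are reconstructed from the dosages and the marker alleles;
#' missing calls are written as \code{NN}.  The file reads back with
#' \code{\link{readGenotypes}}.
#'
#' @param panel a \code{SnpPanel}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeGenotypes <- function(panel, path) {
  x <- genotypeCalls(panel)
  mk <- markerInfo(panel)
  out <- matrix("NN", nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    g <- c(paste0(mk$allele_a[j], mk$allele_a[j]),
           paste0(mk$allele_a[j], mk$allele_b[j]),
           paste0(mk$allele_b[j], mk$allele_b[j]))
    ok <- !is.na(x[, j])
    out[ok, j] <- g[x[ok, j] + 1L]
  }
  df <- data.frame(id = rownames(x), out, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a group-assignment TSV (individual_id<TAB>group)
#'
#' @param path file path
#' @return named character vector, individual id -> group label
#' @export
readGroups <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a marker map TSV (marker_id, chromosome, position) onto a panel
#'
#' @param panel a \code{SnpPanel}
#' @param path marker map TSV
#' @return the panel with chromosome/position filled for mapped markers
#' @export
attachMarkerMap <- function(panel, path) {
  mp <- read.delim(path, colClasses = c("character", "character", "integer"))
  mk <- markerInfo(panel)
  i <- match(mk$marker_id, mp[[1]])
  mk$chromosome[!is.na(i)] <- mp[[2]][i[!is.na(i)]]
  mk$position[!is.na(i)] <- mp[[3]][i[!is.na(i)]]
  new("SnpPanel", calls = genotypeCalls(panel), markers = mk,
      groups = groupAssignment(panel))
}

#' Numeric recoding of genotype calls
#'
#' Recodes the dosage matrix to the conventional numeric digits 1/2/3
#' (1 = homozygous allele A, 2 = heterozygous, 3 = homozygous allele B);
#' missing stays \code{NA}.  \code{decodeNumeric} is the exact inverse.
#'
#' @param panel a \code{SnpPanel} (or a dosage matrix)
#' @return integer matrix of codes 1/2/3 with NA preserved
#' @export
recodeNumeric <- function(panel) {
  x <- if (is(panel, "SnpPanel")) genotypeCalls(panel) else panel
  x + 1L
}

#' @rdname recodeNumeric
#' @param codes matrix of numeric codes 1/2/3 (NA allowed)
#' @export
decodeNumeric <- function(codes) {
  v <- codes[!is.na(codes)]
  if (length(v) && !all(v %in% 1:3)) stop("numeric codes must be 1, 2 or 3")
  codes - 1L
}

markerCallRate <- function(x) colMeans(!is.na(x))

markerMAF <- function(x) {
  n <- colSums(!is.na(x))
  pb <- colSums(x, na.rm = TRUE) / (2 * n)
  pmin(pb, 1 - pb)
}

#' Quality-control filter on call rate and minor allele frequency
#'
#' Retains exactly the markers whose call rate and MAF both meet the
#' (inclusive) thresholds, computed over all individuals present in the
#' panel.  Defaults are the standard 90% call rate / 5% MAF minimums for
#' diversity panels.
#'
#' @param panel a \code{SnpPanel}
#' @param minCallRate minimum fraction of non-missing calls per marker
#' @param minMAF minimum minor allele frequency per marker
#' @return list with elements \code{panel} (filtered \code{SnpPanel},
#'   marker order preserved) and \code{report} (data.frame
#'   \code{marker_id, call_rate, maf, status, reason} with attributes
#'   \code{n_in}, \code{n_pass}, \code{n_fail})
#' @export
qcFilter <- function(panel, minCallRate = 0.90, minMAF = 0.05) {
  stopifnot(minCallRate >= 0, minCallRate <= 1, minMAF >= 0, minMAF <= 1)
  x <- genotypeCalls(panel)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty genotype matrix")
  cr <- markerCallRate(x)
  maf <- markerMAF(x)
  failCR <- cr < minCallRate
  failMAF <- !failCR & (is.na(maf) | maf < minMAF)
  pass <- !failCR & !failMAF
  reason <- rep("", ncol(x))
  reason[failCR] <- "call_rate"
  reason[failMAF] <- "maf"
  report <- data.frame(marker_id = markerIds(panel), call_rate = cr,
                       maf = maf, status = ifelse(pass, "pass", "fail"),
                       reason = reason, stringsAsFactors = FALSE,
                       row.names = NULL)
  attr(report, "n_in") <- ncol(x)
  attr(report, "n_pass") <- sum(pass)
  attr(report, "n_fail") <- sum(!pass)
  if (!any(pass)) warning("all markers removed by QC filter")
  list(panel = panel[, which(pass)], report = report)
}

#' Write a QC report TSV
#'
#' @param report the report data.frame from \code{\link{qcFilter}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeQCReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect two marker panels
#'
#' Restricts to the markers whose ids occur in both panels, re-orienting
#' the second panel's dosages wherever its allele A/B labels are swapped
#' relative to the first, and stacks the union of individuals (individuals
#' present in both panels keep the first panel's calls).  Marker order
#' follows panel \code{a}.
#'
#' @param a,b \code{SnpPanel} objects
#' @return a combined \code{SnpPanel} on the shared markers
#' @export
intersectPanels <- function(a, b) {
  shared <- intersect(markerIds(a), markerIds(b))
  if (length(shared) == 0L) stop("no shared markers between panels")
  pa <- a[, shared]
  pb <- b[, shared]
  ma <- markerInfo(pa); mb <- markerInfo(pb)
  xb <- genotypeCalls(pb)
  for (j in seq_along(shared)) {
    sa <- c(ma$allele_a[j], ma$allele_b[j])
    sb <- c(mb$allele_a[j], mb$allele_b[j])
    placeholder <- function(s) all(s %in% c("A", "B")) # dosage-digit input
    if (identical(sa, sb) || placeholder(sb) || placeholder(sa)) next
    if (identical(sa, rev(sb))) {
      xb[, j] <- 2L - xb[, j]
    } else if (!setequal(sa, sb)) {
      stop("irreconcilable alleles at marker ", shared[j], ": ",
           paste(sa, collapse = "/"), " vs ", paste(sb, collapse = "/"))
    }
  }
  onlyB <- setdiff(rownames(xb), indNames(pa))
  calls <- rbind(genotypeCalls(pa), xb[onlyB, , drop = FALSE])
  grp <- c(groupAssignment(a), groupAssignment(b))
  grp <- grp[!duplicated(names(grp)) & names(grp) %in% rownames(calls)]
  new("SnpPanel", calls = calls, markers = ma, groups = grp)
}
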