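## End-to-end workflow driver: QC -> diversity -> correlations -> private
## alleles -> distances/tree -> kinship/Ne -> structure/delta-K -> report.
## Every stage writes its outputs to the run directory, and downstream
## stages read the serialized files back, so the on-disk formats are the
## contract between stages.

#' Pipeline configuration
#'
#' Exactly one of \code{genotypes} (a file path, with optional
#' \code{map}/\code{groups} paths) or \code{simulate} must be supplied.
#'
#' @param outDir output directory (created if absent)
#' @param genotypes path to a genotype file (see
#'   \code{\link{readGenotypes}}), or \code{NULL} to simulate
#' @param format genotype file dialect
#' @param map optional marker map TSV
#' @param groups optional groups TSV (\code{individual_id<TAB>group})
#' @param simulate \code{TRUE} to simulate the default study-scale hybrid
#'   panel (see \code{\link{simulateStudyPanels}}), or a
#'   \code{\link{simConfig}} for a custom panel
#' @param minCallRate,minMAF QC thresholds
#' @param bootstrapReps locus-bootstrap replicates for node support
#' @param treeUnits \code{"individuals"} or \code{"groups"}
#' @param structure a \code{\link{structureConfig}}, or \code{NULL} to
#'   skip the admixture stage
#' @param neMode effective-size mode (see \code{\link{effectiveSize}})
#' @param neN census size for the Ne formulas (default: panel size)
#' @param seed master seed for every stochastic stage
#' @return list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(outDir, genotypes = NULL, format = "individual",
                           map = NULL, groups = NULL, simulate = NULL,
                           minCallRate = 0.90, minMAF = 0.05,
                           bootstrapReps = 2000,
                           treeUnits = "individuals",
                           structure = structureConfig(),
                           neMode = "n_scaled", neN = NULL, seed = 1) {
  if (is.null(genotypes) == is.null(simulate))
    stop("config error: exactly one of genotypes / simulate must be given")
  out <- list(outDir = outDir, genotypes = genotypes, format = format,
              map = map, groups = groups, simulate = simulate,
              minCallRate = minCallRate, minMAF = minMAF,
              bootstrapReps = bootstrapReps, treeUnits = treeUnits,
              structure = structure, neMode = neMode, neN = neN,
              seed = as.integer(seed))
  class(out) <- "pipelineConfig"
  out
}

writeTsvMatrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsvMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

stageLog <- function(logCon, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  if (!is.null(logCon)) writeLines(line, logCon)
  message(line)
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full diversity / vulnerability pipeline
#'
#' Executes QC, per-locus and per-group diversity, allele-frequency
#' correlations, private alleles, Nei DA distances with a bootstrap UPGMA
#' tree, genomic kinship with Fst and effective sizes, and (optionally)
#' the admixture K-grid with Evanno delta-K and the 60% membership rule.
#' All stage outputs are written under \code{config$outDir}; outputs are
#' byte-identical across runs with the same config and seed.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return a \code{ReportBundle}: list with \code{manifest} (named file
#'   paths) and \code{summary} (key numbers, also written as
#'   \code{summary.json})
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outDir, f)
  logCon <- file(p("pipeline.log"), open = "wt")
  on.exit(close(logCon))
  manifest <- c(log = p("pipeline.log"))
  summary <- list(seed = config$seed)

  ## stage: input
  runStage("input", {
    if (!is.null(config$simulate)) {
      sim <- if (inherits(config$simulate, "simConfig"))
        simulateAdmixed(config$simulate)$panel
      else simulateStudyPanels(config$seed)$hybrids
      writeGenotypes(sim, p("genotypes_raw.tsv"))
      grp <- groupAssignment(sim)
      write.table(data.frame(individual_id = names(grp), group = grp),
                  p("groups.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      stageLog(logCon, "input", sprintf("simulated %d x %d panel",
                                        nInd(sim), nMarkers(sim)))
    } else {
      samePath <- function(a, b)
        normalizePath(a, mustWork = FALSE) == normalizePath(b, mustWork = FALSE)
      if (!samePath(config$genotypes, p("genotypes_raw.tsv")))
        file.copy(config$genotypes, p("genotypes_raw.tsv"), overwrite = TRUE)
      if (!is.null(config$groups) &&
          !samePath(config$groups, p("groups.tsv")))
        file.copy(config$groups, p("groups.tsv"), overwrite = TRUE)
    }
  })
  manifest["genotypes_raw"] <- p("genotypes_raw.tsv")

  ## stage: qc (reads the raw genotype file back from disk)
  panel <- NULL
  runStage("qc", {
    raw <- readGenotypes(p("genotypes_raw.tsv"),
                         format = if (!is.null(config$genotypes))
                           config$format else "individual")
    if (!is.null(config$map) && file.exists(config$map %||% ""))
      raw <- attachMarkerMap(raw, config$map)
    qc <- qcFilter(raw, config$minCallRate, config$minMAF)
    writeQCReport(qc$report, p("qc_report.tsv"))
    writeGenotypes(qc$panel, p("genotypes_qc.tsv"))
    summary$markers_in <- attr(qc$report, "n_in")
    summary$markers_pass <- attr(qc$report, "n_pass")
    stageLog(logCon, "qc", sprintf("%d of %d markers retained",
                                   attr(qc$report, "n_pass"),
                                   attr(qc$report, "n_in")))
  })
  manifest["qc_report"] <- p("qc_report.tsv")
  manifest["genotypes_qc"] <- p("genotypes_qc.tsv")

  ## QC'd panel re-read from its serialized form
  panel <- readGenotypes(p("genotypes_qc.tsv"), format = "individual")
  haveGroups <- file.exists(p("groups.tsv"))
  if (haveGroups) {
    grp <- readGroups(p("groups.tsv"))
    groupAssignment(panel) <- grp[names(grp) %in% indNames(panel)]
  }

  ## stage: diversity
  runStage("diversity", {
    write.table(locusStats(panel), p("locus_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (haveGroups) {
      gs <- groupSummary(panel)
      write.table(gs, p("group_summary.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      summary$group_summary <- gs
    }
    stageLog(logCon, "diversity", "locus and group statistics written")
  })
  manifest["locus_stats"] <- p("locus_stats.tsv")
  if (haveGroups) manifest["group_summary"] <- p("group_summary.tsv")

  ## stage: correlations + private alleles (need >= 2 groups)
  if (haveGroups && length(unique(groupAssignment(panel))) >= 2) {
    runStage("correlations", {
      ft <- alleleFreqTable(panel, units = "groups")
      cm <- correlationMatrix(ft)
      writeTsvMatrix(round(cm$r, 10), p("correlations.tsv"))
      writeTsvMatrix(signif(cm$p, 10), p("correlations_p.tsv"))
      summary$mean_correlation <-
        mean(cm$r[upper.tri(cm$r)], na.rm = TRUE)
      stageLog(logCon, "correlations", "group correlation matrices written")
    })
    manifest["correlations"] <- p("correlations.tsv")
    manifest["correlations_p"] <- p("correlations_p.tsv")
    runStage("private_alleles", {
      pa <- privateAlleles(panel)
      write.table(pa, p("private_alleles.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      summary$n_private_alleles <- nrow(pa)
      stageLog(logCon, "private_alleles", sprintf("%d found", nrow(pa)))
    })
    manifest["private_alleles"] <- p("private_alleles.tsv")
  }

  ## stage: distances + bootstrap UPGMA tree
  runStage("tree", {
    d <- neiDistance(panel, units = config$treeUnits)
    writeTsvMatrix(signif(d, 12), p("distances.tsv"))
    tr <- bootstrapSupport(panel, units = config$treeUnits,
                           nReps = config$bootstrapReps, seed = config$seed)
    writeNewick(tr, p("tree.nwk"))
    writeLines(sprintf("bootstrap: %d replicates, seed %d",
                       config$bootstrapReps, config$seed),
               p("bootstrap.log"))
    summary$min_node_support <- min(tr@support)
    stageLog(logCon, "tree", sprintf("UPGMA + %d bootstrap replicates",
                                     config$bootstrapReps))
  })
  manifest["distances"] <- p("distances.tsv")
  manifest["tree"] <- p("tree.nwk")
  manifest["bootstrap_log"] <- p("bootstrap.log")

  ## stage: kinship / Ne
  runStage("kinship", {
    nN <- if (is.null(config$neN)) nInd(panel) else config$neN
    kr <- kinshipAnalysis(panel, n = nN, mode = config$neMode)
    writeTsvMatrix(signif(kr@G, 12), p("G.tsv"))
    jsonlite::write_json(
      list(fst = kr@fst, n = nN, ne_hybrid = kr@neHybrid,
           ne_parents = kr@neParents, mode = kr@mode,
           denominator = kr@denominator),
      p("kinship.json"), auto_unbox = TRUE, digits = NA)
    summary$fst <- kr@fst
    summary$ne_hybrid <- kr@neHybrid
    summary$ne_parents <- kr@neParents
    stageLog(logCon, "kinship", sprintf("Fst = %.4f", kr@fst))
  })
  manifest["G"] <- p("G.tsv")
  manifest["kinship"] <- p("kinship.json")

  ## stage: structure / delta-K
  if (!is.null(config$structure)) {
    runStage("structure", {
      sc <- config$structure
      sc$seed <- config$seed
      rs <- runStructure(panel, sc)
      for (K in names(rs$results))
        for (r in seq_along(rs$results[[K]])) {
          q <- rs$results[[K]][[r]]@Q
          writeTsvMatrix(signif(q, 8),
                         p(sprintf("q_matrix.K%s.rep%d.tsv", K, r)))
        }
      write.table(rs$L, p("structure_L.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (length(unique(rs$L$K)) >= 3 && sc$replicates >= 2) {
        dk <- deltaK(rs$L)
        write.table(dk, p("deltaK.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        bestK <- dk$K[which(dk$argmax)]
        summary$optimal_k <- if (length(bestK)) bestK else NA
        if (length(bestK)) {
          qbar <- meanQ(rs$results[[as.character(bestK)]])
          asg <- assignGroups(qbar)
          write.table(data.frame(individual = names(asg), group = asg),
                      p("assignments.tsv"), sep = "\t", quote = FALSE,
                      row.names = FALSE)
        }
      }
      stageLog(logCon, "structure", sprintf(
        "K grid %d..%d x %d replicates done", sc$kMin, sc$kMax,
        sc$replicates))
    })
    manifest["structure_L"] <- p("structure_L.tsv")
    if (file.exists(p("deltaK.tsv"))) manifest["deltaK"] <- p("deltaK.tsv")
    if (file.exists(p("assignments.tsv")))
      manifest["assignments"] <- p("assignments.tsv")
  }

  ## stage: report
  runStage("report", {
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    stageLog(logCon, "report", "summary.json written")
  })
  manifest["summary"] <- p("summary.json")

  structure(list(manifest = manifest, summary = summary),
            class = "ReportBundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle with", length(x$manifest), "outputs:\n")
  for (nm in names(x$manifest)) cat(" ", nm, "->", x$manifest[[nm]], "\n")
  invisible(x)
}

#' Combined-panel analysis of hybrids and reference lines
#'
#' Intersects the two marker panels, re-runs QC on the combined matrix,
#' and builds the bootstrap UPGMA tree (and optionally the admixture
#' structure) on the union of individuals — the standard way to place a
#' commercial hybrid panel among reference inbred lines.
#'
#' @param hybrids,lines \code{SnpPanel} objects
#' @param config a \code{\link{pipelineConfig}} (its \code{genotypes} /
#'   \code{simulate} fields are ignored; QC, tree, structure and seed
#'   settings apply)
#' @return a \code{ReportBundle}; the summary includes the shared-marker
#'   count before QC
#' @export
combinedAnalysis <- function(hybrids, lines, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  combined <- intersectPanels(hybrids, lines)
  nShared <- nMarkers(combined)
  writeGenotypes(combined, file.path(config$outDir, "combined_raw.tsv"))
  grp <- groupAssignment(combined)
  write.table(data.frame(individual_id = names(grp), group = grp),
              file.path(config$outDir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$simulate <- NULL
  cfg$genotypes <- file.path(config$outDir, "combined_raw.tsv")
  cfg$format <- "individual"
  cfg$groups <- file.path(config$outDir, "groups.tsv")
  bundle <- runPipeline(cfg)
  bundle$summary$shared_markers <- nShared
  jsonlite::write_json(bundle$summary,
                       file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  bundle
}
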