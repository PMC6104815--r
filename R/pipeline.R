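#' @importFrom stats median setNames
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Quality control and normalisation of a single-cell experiment
#'
#' Applies the preprocessing chain in a fixed order: MAD outlier filtering
#' of cells (library size, detected genes, mitochondrial fraction), removal
#' of low-abundance genes, library-size size factors, log2 normalisation,
#' then flagging and removal of proliferating cells and (optionally)
#' contaminating doublets spanning exclusive marker sets.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param mitoGenes,cycleGenes gene lists for the mitochondrial fraction and
#'   the proliferation score.
#' @param config a [RunConfig-class].
#' @param contaminantPairs optional list of marker-set pairs for
#'   [flagContaminants()].
#' @return the filtered SingleCellExperiment with added `logcounts` assay,
#'   per-cell QC metrics and size factors in `colData`, and a QC audit in
#'   `metadata(.)$qc`.
#' @export
qcNormalize <- function(sce, mitoGenes, cycleGenes, config = RunConfig(),
                        contaminantPairs = NULL) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  metrics <- computeCellQC(counts, mitoGenes)
  keep <- madOutlierFilter(metrics, nMads = config@nMads)
  sce <- sce[, keep]
  metrics <- metrics[keep, , drop = FALSE]

  geneKeep <- filterLowAbundanceGenes(
    SummarizedExperiment::assay(sce, "counts"), config@minMeanCount
  )
  sce <- sce[geneKeep, ]

  counts <- SummarizedExperiment::assay(sce, "counts")
  sf <- computeSizeFactors(counts)
  norm <- normalizeLogCounts(counts, sf)

  prolif <- if (length(intersect(cycleGenes, rownames(norm)))) {
    flagProliferating(norm, cycleGenes, config@zThreshold)
  } else {
    warning("no cycle genes present; proliferation flagging skipped")
    rep(FALSE, ncol(norm))
  }
  contam <- if (length(contaminantPairs)) {
    flagContaminants(norm, contaminantPairs)
  } else {
    rep(FALSE, ncol(norm))
  }
  keep2 <- !(prolif | contam)

  SummarizedExperiment::assays(sce)$logcounts <- norm
  SummarizedExperiment::colData(sce) <- cbind(
    SummarizedExperiment::colData(sce), metrics,
    S4Vectors::DataFrame(sizeFactor = unname(sf))
  )
  out <- sce[, keep2]
  S4Vectors::metadata(out)$qc <- list(
    nInput = length(keep), nOutlier = sum(!keep),
    nLowAbundanceGenes = sum(!geneKeep), nProliferating = sum(prolif),
    nContaminant = sum(contam), nKept = sum(keep2)
  )
  out
}

#' Cluster a preprocessed experiment and assign genotype groups
#'
#' Runs HVG selection, PCA, mutual-kNN label-propagation clustering and
#' genotype-group assignment, then differential expression of the
#' knockout-labelled cells against the control-labelled cells. Group labels
#' (never raw genotype labels) define the DE comparison, so heterozygous
#' escaper cells in the CRE+ sample do not contaminate the knockout group.
#'
#' @param sce output of [qcNormalize()] (must carry `logcounts` and a
#'   `genotype` column).
#' @param gainMarkers,targetGene marker genes for [assignGroups()].
#' @param config a [RunConfig-class].
#' @return list with elements `sce`, `clusters` ([ClusterResult-class]),
#'   `groups` ([GroupAssignment-class]) and `de` ([DEResult-class], or
#'   `NULL` with a warning when no knockout or control cluster was found).
#' @export
analyzeTissue <- function(sce, gainMarkers, targetGene,
                          config = RunConfig()) {
  norm <- SummarizedExperiment::assay(sce, "logcounts")
  hvgs <- selectHVGs(norm, min(config@nHVGs, nrow(norm)))
  emb <- reduceCellDims(norm[hvgs, , drop = FALSE],
                        min(config@nComponents, length(hvgs) - 1L,
                            ncol(norm) - 1L))
  clusters <- clusterCells(emb, config@kNeighbors, config@seed)
  groups <- assignGroups(
    clusters, sce$genotype, SummarizedExperiment::assay(sce, "counts"),
    norm, gainMarkers, targetGene, config@crePurity,
    config@markerPrevalenceMin
  )
  gr <- cellGroups(groups)
  de <- NULL
  if (any(gr == "KO") && any(gr == "control")) {
    de <- findDEGenes(norm, which(gr == "KO"), which(gr == "control"),
                      fdrThreshold = config@fdrThreshold,
                      logfcThreshold = config@logfcThreshold,
                      minPrevalence = config@dePrevalenceMin,
                      groupA = "KO", groupB = "control")
  } else {
    warning("no knockout and/or control cluster found; DE skipped")
  }
  list(sce = sce, clusters = clusters, groups = groups, de = de)
}

#' Derive conserved-core and tissue-specific signatures
#'
#' Detects confounded tissue pairs, mutually excludes them, derives each
#' tissue's specific signature with the strict max-over-others fold rule,
#' applies the single-cell prevalence filter against that tissue's control
#' cells, and derives the conserved core.
#'
#' @param bulk bulk profile panel (genes x tissues).
#' @param controlCountsList named list (by tissue) of control-cell count
#'   matrices for the prevalence filter; tissues without an entry skip it.
#' @param config a [RunConfig-class].
#' @param mitoGenes mitochondrial genes, excluded from the conserved core.
#' @return a [SignatureSet-class].
#' @export
deriveSignatures <- function(bulk, controlCountsList = list(),
                             config = RunConfig(),
                             mitoGenes = character()) {
  M <- .bulkMatrix(bulk)
  pairs <- detectConfoundedPairs(M, config@fcThreshold,
                                 config@overlapThreshold)
  exclusions <- setNames(vector("list", ncol(M)), colnames(M))
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      exclusions[[pairs[r, 1L]]] <- c(exclusions[[pairs[r, 1L]]],
                                      pairs[r, 2L])
      exclusions[[pairs[r, 2L]]] <- c(exclusions[[pairs[r, 2L]]],
                                      pairs[r, 1L])
    }
  }
  sigs <- list()
  prevalence <- list()
  for (t in colnames(M)) {
    s <- deriveTissueSignature(M, t, exclusions = exclusions[[t]],
                               fcThreshold = config@fcThreshold)
    if (!is.null(controlCountsList[[t]])) {
      s <- prevalenceFilter(s, controlCountsList[[t]],
                            config@prevalenceMin)
      prevalence[[t]] <- attr(s, "prevalence")
    }
    sigs[[t]] <- as.character(s)
  }
  core <- deriveConservedCore(M, exprMin = NULL,
                              controlCountsList = controlCountsList,
                              minPrevalence = config@prevalenceMin,
                              excludeGenes = mitoGenes)
  methods::new("SignatureSet",
    conservedCore = core, tissueSignatures = sigs,
    confoundedPairs = pairs,
    filters = list(fcThreshold = config@fcThreshold,
                   overlapThreshold = config@overlapThreshold,
                   prevalenceMin = config@prevalenceMin,
                   exclusions = exclusions, prevalence = prevalence)
  )
}

#' Run the complete identity-erosion study on simulated data
#'
#' Emulates the full analysis: simulate bulk profiles, then for every
#' tissue simulate a mosaic knockout single-cell experiment, preprocess,
#' cluster, assign genotype groups and compute knockout-versus-control
#' differential expression; derive signatures (with confound exclusion and
#' the control-cell prevalence filter), score identity erosion per tissue,
#' subtract origin-associated genes and partition DE genes across tissues.
#'
#' @param simConfig a [SimConfig-class].
#' @param runConfig a [RunConfig-class].
#' @param tissues optional subset of tissue names to profile (all by
#'   default).
#' @return list with elements `bulk`, `signatures` ([SignatureSet-class]),
#'   `tissues` (per-tissue list: `analysis`, `report`
#'   ([ErosionReport-class])), `conservation`
#'   (see [crossTissueConservation()]) and the two configs.
#' @export
runErosionStudy <- function(simConfig = SimConfig(),
                            runConfig = RunConfig(), tissues = NULL) {
  bulk <- simulateBulkProfiles(simConfig)
  layout <- S4Vectors::metadata(bulk)$planted
  if (is.null(tissues)) tissues <- layout$tissues
  analyses <- list()
  controlCounts <- list()
  for (t in tissues) {
    sce <- simulateTissueExperiment(simConfig, t, bulk)
    qc <- qcNormalize(sce, layout$mito, layout$cycle, runConfig)
    analyses[[t]] <- analyzeTissue(qc, layout$gainMarkers[[t]],
                                   layout$target, runConfig)
    gr <- cellGroups(analyses[[t]]$groups)
    ctrl <- gr == "control" & qc$genotype == "CRE-"
    controlCounts[[t]] <-
      SummarizedExperiment::assay(qc, "counts")[, ctrl, drop = FALSE]
  }
  signatures <- deriveSignatures(bulk, controlCounts, runConfig,
                                 mitoGenes = layout$mito)

  perTissue <- list()
  deLists <- list()
  for (t in tissues) {
    de <- analyses[[t]]$de
    rep_t <- NULL
    if (!is.null(de) && length(tissueSignatures(signatures)[[t]])) {
      rep_t <- identityErosion(tissueSignatures(signatures)[[t]], de, t)
      rep_t@originSubtracted <- subtractOriginGenes(rep_t@deGenes,
                                                    layout$origin)
      deLists[[t]] <- rep_t@deGenes
    }
    perTissue[[t]] <- list(analysis = analyses[[t]], report = rep_t)
  }
  conservation <- if (length(deLists) >= 2L) {
    crossTissueConservation(deLists)
  } else {
    NULL
  }
  list(bulk = bulk, signatures = signatures, tissues = perTissue,
       conservation = conservation, simConfig = simConfig,
       runConfig = runConfig)
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "list", function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sigs <- x$signatures
  if (!is.null(sigs)) {
    tab <- do.call(rbind, lapply(names(tissueSignatures(sigs)), function(t) {
      g <- tissueSignatures(sigs)[[t]]
      if (length(g)) data.frame(tissue = t, gene = g) else NULL
    }))
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(dir, "tissue_signatures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(conservedCore(sigs), file.path(dir, "conserved_core.txt"))
  }
  for (t in names(x$tissues)) {
    rep_t <- x$tissues[[t]]$report
    if (!is.null(rep_t)) writeReport(rep_t, dir)
  }
  if (!is.null(x$conservation)) {
    cons <- x$conservation
    jsonlite::write_json(
      list(partition = cons$partition,
           sharedAll = as.list(cons$sharedAll),
           nSharedAll = length(cons$sharedAll),
           uniqueCounts = lapply(cons$unique, length)),
      file.path(dir, "conservation.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  if (!is.null(x$simConfig)) {
    yaml::write_yaml(.configAsList(x$simConfig),
                     file.path(dir, "sim_config.yaml"))
  }
  if (!is.null(x$runConfig)) {
    yaml::write_yaml(.configAsList(x$runConfig),
                     file.path(dir, "run_config.yaml"))
  }
  invisible(dir)
})
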