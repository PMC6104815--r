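#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration for mosaic conditional-knockout experiments
#'
#' `SimConfig` holds every parameter of the synthetic-data generator: the
#' bulk tissue panel (number of tissues, signature and conserved-core sizes,
#' an optional confounded tissue pair sharing part of their signatures), the
#' single-cell experiment design (cells per sample, the mixture of
#' homozygous-knockout and heterozygous-escaper cells within the CRE+
#' sample), the planted perturbation (fraction of signature genes eroded in
#' knockout cells and the fold change applied), nuisance cell classes
#' (QC outliers, doublets, proliferating cells) and the negative binomial
#' count model (dispersion, mean library size). A single integer seed fully
#' determines all output.
#'
#' @slot nTissues number of tissues in the bulk panel.
#' @slot genesTotal total number of genes simulated.
#' @slot sigSizePerTissue planted tissue-specific signature size per tissue.
#' @slot coreSize planted conserved-core size (shared across all tissues).
#' @slot confoundedPair integer pair of tissue indices sharing part of their
#'   signatures, or `integer(0)` for none.
#' @slot sharedFraction fraction of the confounded pair's signatures shared.
#' @slot cellsPerSample cells per sample (one CRE- and one CRE+ sample).
#' @slot koFraction,hetFraction proportions of CRE+ cells that are
#'   homozygous-deleted or heterozygous escapers (sum must be <= 1).
#' @slot erosionFraction proportion of signature genes down-regulated in
#'   knockout cells.
#' @slot effectFold fold change (>= 1) for eroded genes (divided), gain
#'   markers and escaper origin genes (multiplied).
#' @slot gainMarkersPerTissue number of knockout gain-of-expression markers
#'   per tissue.
#' @slot nOriginGenes size of the origin-associated gene module elevated in
#'   heterozygous escaper cells.
#' @slot nbDispersion negative binomial dispersion (variance =
#'   mu + mu^2 / dispersion).
#' @slot meanLibrarySize expected UMI count per cell.
#' @slot librarySdLog log-normal sd of per-cell library sizes.
#' @slot outlierFraction,doubletFraction,proliferatingFraction proportions
#'   of planted nuisance cells per sample.
#' @slot truncBoost fold increase of the floxed target gene's counts in
#'   knockout cells (truncated-transcript emulation).
#' @slot mitoShare,outlierMitoShare baseline and outlier-cell share of
#'   counts carried by the mitochondrial gene block.
#' @slot nMitoGenes,nCycleGenes sizes of the mitochondrial and cell-cycle
#'   gene blocks.
#' @slot seed integer seed determining all randomness.
#'
#' @examples
#' cfg <- SimConfig(nTissues = 2, genesTotal = 400, cellsPerSample = 100)
#' cfg
#' @export
setClass("SimConfig", representation(
  nTissues = "integer",
  genesTotal = "integer",
  sigSizePerTissue = "integer",
  coreSize = "integer",
  confoundedPair = "integer",
  sharedFraction = "numeric",
  cellsPerSample = "integer",
  koFraction = "numeric",
  hetFraction = "numeric",
  erosionFraction = "numeric",
  effectFold = "numeric",
  gainMarkersPerTissue = "integer",
  nOriginGenes = "integer",
  nbDispersion = "numeric",
  meanLibrarySize = "numeric",
  librarySdLog = "numeric",
  outlierFraction = "numeric",
  doubletFraction = "numeric",
  proliferatingFraction = "numeric",
  truncBoost = "numeric",
  mitoShare = "numeric",
  outlierMitoShare = "numeric",
  nMitoGenes = "integer",
  nCycleGenes = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(
    nTissues = object@nTissues, genesTotal = object@genesTotal,
    sigSizePerTissue = object@sigSizePerTissue, coreSize = object@coreSize,
    cellsPerSample = object@cellsPerSample
  )
  if (any(is.na(cnt)) || any(cnt < 1L)) {
    msg <- c(msg, "all count parameters must be >= 1")
  }
  for (p in c("koFraction", "hetFraction", "erosionFraction",
              "outlierFraction", "doubletFraction", "proliferatingFraction",
              "sharedFraction", "mitoShare", "outlierMitoShare")) {
    v <- slot(object, p)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msg <- c(msg, sprintf("'%s' must be a proportion in [0, 1]", p))
    }
  }
  if (!length(msg) && object@koFraction + object@hetFraction > 1 + 1e-12) {
    msg <- c(msg, "koFraction + hetFraction must be <= 1")
  }
  if (object@effectFold < 1) msg <- c(msg, "effectFold must be >= 1")
  if (object@truncBoost < 1) msg <- c(msg, "truncBoost must be >= 1")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be positive")
  if (object@meanLibrarySize <= 0) {
    msg <- c(msg, "meanLibrarySize must be positive")
  }
  if (length(object@confoundedPair) %in% c(0L, 2L)) {
    if (length(object@confoundedPair) == 2L) {
      cp <- object@confoundedPair
      if (any(cp < 1L) || any(cp > object@nTissues) || cp[1] == cp[2]) {
        msg <- c(msg, "confoundedPair must be two distinct tissue indices")
      }
    }
  } else {
    msg <- c(msg, "confoundedPair must have length 0 or 2")
  }
  nSpecial <- object@nTissues * object@sigSizePerTissue + object@coreSize +
    object@nMitoGenes + object@nCycleGenes + object@nOriginGenes +
    object@nTissues * object@gainMarkersPerTissue + 1L
  if (nSpecial > object@genesTotal) {
    msg <- c(msg, sprintf(
      "configuration error: %d planted genes exceed genesTotal = %d",
      nSpecial, object@genesTotal
    ))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nTissues,genesTotal,sigSizePerTissue,coreSize,confoundedPair,sharedFraction,cellsPerSample,koFraction,hetFraction,erosionFraction,effectFold,gainMarkersPerTissue,nOriginGenes,nbDispersion,meanLibrarySize,librarySdLog,outlierFraction,doubletFraction,proliferatingFraction,truncBoost,mitoShare,outlierMitoShare,nMitoGenes,nCycleGenes,seed see slot documentation.
#' @return `SimConfig()` returns a validated [SimConfig-class] object.
#' @export
SimConfig <- function(nTissues = 5, genesTotal = 1500, sigSizePerTissue = 80,
                      coreSize = 67, confoundedPair = c(1L, 3L),
                      sharedFraction = 0.5, cellsPerSample = 400,
                      koFraction = 0.5, hetFraction = 0.5,
                      erosionFraction = 0.6, effectFold = 4,
                      gainMarkersPerTissue = 2, nOriginGenes = 30,
                      nbDispersion = 2, meanLibrarySize = 4000,
                      librarySdLog = 0.15, outlierFraction = 0.05,
                      doubletFraction = 0.02, proliferatingFraction = 0.03,
                      truncBoost = 2, mitoShare = 0.05,
                      outlierMitoShare = 0.20, nMitoGenes = 10,
                      nCycleGenes = 12, seed = 1) {
  new("SimConfig",
    nTissues = as.integer(nTissues), genesTotal = as.integer(genesTotal),
    sigSizePerTissue = as.integer(sigSizePerTissue),
    coreSize = as.integer(coreSize),
    confoundedPair = as.integer(confoundedPair),
    sharedFraction = sharedFraction,
    cellsPerSample = as.integer(cellsPerSample),
    koFraction = koFraction, hetFraction = hetFraction,
    erosionFraction = erosionFraction, effectFold = effectFold,
    gainMarkersPerTissue = as.integer(gainMarkersPerTissue),
    nOriginGenes = as.integer(nOriginGenes),
    nbDispersion = nbDispersion, meanLibrarySize = meanLibrarySize,
    librarySdLog = librarySdLog, outlierFraction = outlierFraction,
    doubletFraction = doubletFraction,
    proliferatingFraction = proliferatingFraction,
    truncBoost = truncBoost, mitoShare = mitoShare,
    outlierMitoShare = outlierMitoShare,
    nMitoGenes = as.integer(nMitoGenes),
    nCycleGenes = as.integer(nCycleGenes), seed = as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTissues, "tissues,", object@genesTotal,
      "genes,", object@cellsPerSample, "cells/sample\n")
  cat("  signature:", object@sigSizePerTissue, "genes/tissue, core:",
      object@coreSize, "genes\n")
  cat(sprintf("  CRE+ mixture: %.0f%% KO, %.0f%% het; erosion %.2f at fold %.1f\n",
              100 * object@koFraction, 100 * object@hetFraction,
              object@erosionFraction, object@effectFold))
  cat("  NB dispersion", object@nbDispersion, "| mean library",
      object@meanLibrarySize, "| seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# RunConfig
# ---------------------------------------------------------------------------

#' Analysis thresholds for the identity-erosion pipeline
#'
#' Houses every tunable threshold used downstream: the MAD multiplier for
#' cell QC, the low-abundance gene cutoff, size of the HVG set and embedding,
#' clustering neighbourhood, CRE-purity and gain-marker prevalence rules for
#' genotype-group calls, the Wilcoxon/BH significance thresholds and the
#' signature-derivation constants (fold threshold, 20% single-cell
#' prevalence rule, Jaccard overlap threshold for confounded tissues).
#'
#' @slot nMads MAD multiplier for QC outlier calls (default 3).
#' @slot minMeanCount low-abundance gene filter: minimum mean count.
#' @slot prevalenceMin single-cell prevalence required of a signature gene in
#'   control cells (default 0.20).
#' @slot fcThreshold bulk fold-change threshold for tissue specificity.
#' @slot overlapThreshold Jaccard index above which two tissues are treated
#'   as confounded.
#' @slot fdrThreshold,logfcThreshold significance thresholds for DE calls.
#' @slot dePrevalenceMin minimum expression prevalence in either group for a
#'   gene to be tested.
#' @slot crePurity CRE+ fraction defining genotype-pure clusters.
#' @slot markerPrevalenceMin gain-marker prevalence separating knockout from
#'   escaper clusters.
#' @slot nHVGs,nComponents,kNeighbors clustering parameters.
#' @slot zThreshold z-score cutoff flagging proliferating cells.
#' @slot topN markers reported per group (default 15).
#' @slot seed seed for the clustering schedule.
#' @examples
#' RunConfig()
#' @export
setClass("RunConfig", representation(
  nMads = "numeric", minMeanCount = "numeric", prevalenceMin = "numeric",
  fcThreshold = "numeric", overlapThreshold = "numeric",
  fdrThreshold = "numeric", logfcThreshold = "numeric",
  dePrevalenceMin = "numeric", crePurity = "numeric",
  markerPrevalenceMin = "numeric", nHVGs = "integer",
  nComponents = "integer", kNeighbors = "integer", zThreshold = "numeric",
  topN = "integer", seed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@nMads <= 0) msg <- c(msg, "nMads must be > 0")
  for (p in c("prevalenceMin", "overlapThreshold", "fdrThreshold",
              "dePrevalenceMin", "crePurity", "markerPrevalenceMin")) {
    v <- slot(object, p)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msg <- c(msg, sprintf("'%s' must be a proportion in [0, 1]", p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param nMads,minMeanCount,prevalenceMin,fcThreshold,overlapThreshold,fdrThreshold,logfcThreshold,dePrevalenceMin,crePurity,markerPrevalenceMin,nHVGs,nComponents,kNeighbors,zThreshold,topN,seed see slot documentation.
#' @return `RunConfig()` returns a validated [RunConfig-class] object.
#' @export
RunConfig <- function(nMads = 3, minMeanCount = 0.01, prevalenceMin = 0.20,
                      fcThreshold = 2, overlapThreshold = 0.25,
                      fdrThreshold = 0.05, logfcThreshold = 0.25,
                      dePrevalenceMin = 0.1, crePurity = 0.8,
                      markerPrevalenceMin = 0.5, nHVGs = 1000,
                      nComponents = 20, kNeighbors = 15, zThreshold = 2,
                      topN = 15, seed = 0) {
  new("RunConfig",
    nMads = nMads, minMeanCount = minMeanCount,
    prevalenceMin = prevalenceMin, fcThreshold = fcThreshold,
    overlapThreshold = overlapThreshold, fdrThreshold = fdrThreshold,
    logfcThreshold = logfcThreshold, dePrevalenceMin = dePrevalenceMin,
    crePurity = crePurity, markerPrevalenceMin = markerPrevalenceMin,
    nHVGs = as.integer(nHVGs), nComponents = as.integer(nComponents),
    kNeighbors = as.integer(kNeighbors), zThreshold = zThreshold,
    topN = as.integer(topN), seed = as.integer(seed)
  )
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig thresholds:\n")
  cat(sprintf("  QC: %.1f MADs; gene mean >= %.3g; prevalence >= %.0f%%\n",
              object@nMads, object@minMeanCount, 100 * object@prevalenceMin))
  cat(sprintf("  DE: FDR <= %.3g, |logFC| >= %.2f, tested prevalence >= %.0f%%\n",
              object@fdrThreshold, object@logfcThreshold,
              100 * object@dePrevalenceMin))
  cat(sprintf("  groups: CRE purity %.2f, marker prevalence %.2f\n",
              object@crePurity, object@markerPrevalenceMin))
  cat(sprintf("  clustering: %d HVGs, %d PCs, k = %d, seed = %d\n",
              object@nHVGs, object@nComponents, object@kNeighbors,
              object@seed))
})

# ---------------------------------------------------------------------------
# ClusterResult
# ---------------------------------------------------------------------------

#' Clustering of cells on a reduced-dimension embedding
#'
#' Per-cell cluster labels are small integers, contiguous from 0, assigned in
#' order of decreasing cluster size.
#'
#' @slot labels integer vector of per-cell labels (contiguous from 0).
#' @slot params list of parameters used (kNeighbors, seed, ...).
#' @export
setClass("ClusterResult", representation(
  labels = "integer", params = "list"
))

setValidity("ClusterResult", function(object) {
  lab <- object@labels
  if (!length(lab)) return("no cells labelled")
  if (any(is.na(lab))) return("every kept cell must be labelled")
  u <- sort(unique(lab))
  if (!identical(u, seq(0L, max(lab)))) {
    return("labels must be contiguous integers starting at 0")
  }
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  sz <- table(object@labels)
  cat("ClusterResult:", length(object@labels), "cells in", length(sz),
      "clusters\n")
  cat("  sizes:", paste(sprintf("%s:%d", names(sz), sz), collapse = " "),
      "\n")
})

# ---------------------------------------------------------------------------
# GroupAssignment
# ---------------------------------------------------------------------------

#' Genotype-group assignment of clusters
#'
#' Clusters are labelled control / het / KO / mixed from their CRE+ sample
#' fraction and knockout gain-marker prevalence; cells inherit the label of
#' their cluster.
#'
#' @slot clusterTable per-cluster `DataFrame`: cluster id, group label, CRE+
#'   fraction, gain-marker prevalence, mean target-gene expression
#'   (supporting evidence only) and size.
#' @slot cellGroups factor of per-cell group labels.
#' @slot params list of thresholds used.
#' @export
setClass("GroupAssignment", representation(
  clusterTable = "DataFrame", cellGroups = "factor", params = "list"
))

setValidity("GroupAssignment", function(object) {
  tab <- object@clusterTable
  need <- c("cluster", "group", "crePosFraction", "markerPrevalence")
  if (!all(need %in% colnames(tab))) {
    return(paste("clusterTable must contain", paste(need, collapse = ", ")))
  }
  if (!all(tab$group %in% c("control", "het", "KO", "mixed"))) {
    return("group labels must be control/het/KO/mixed")
  }
  fr <- c(tab$crePosFraction, tab$markerPrevalence)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  TRUE
})

setMethod("show", "GroupAssignment", function(object) {
  cat("GroupAssignment:", length(object@cellGroups), "cells\n")
  print(as.data.frame(object@clusterTable))
})

# ---------------------------------------------------------------------------
# DEResult
# ---------------------------------------------------------------------------

#' Differential-expression result between two cell groups
#'
#' Per-gene Wilcoxon rank-sum statistics with log2 fold changes computed on
#' de-logged normalized means, Benjamini-Hochberg q-values across tested
#' genes, and a significance flag requiring both `q <= fdrThreshold` and
#' `|logFC| >= logfcThreshold`.
#'
#' @slot table per-gene `DataFrame` with columns gene, logFC, U, p, q,
#'   significant, direction.
#' @slot groupA,groupB labels of the compared groups (logFC is A over B).
#' @slot params thresholds used.
#' @export
setClass("DEResult", representation(
  table = "DataFrame", groupA = "character", groupB = "character",
  params = "list"
))

setValidity("DEResult", function(object) {
  tab <- object@table
  need <- c("gene", "logFC", "U", "p", "q", "significant", "direction")
  if (!all(need %in% colnames(tab))) {
    return(paste("table must contain", paste(need, collapse = ", ")))
  }
  if (nrow(tab)) {
    fdr <- object@params$fdrThreshold
    lfc <- object@params$logfcThreshold
    if (!is.null(fdr) && !is.null(lfc)) {
      ok <- tab$significant == (tab$q <= fdr & abs(tab$logFC) >= lfc)
      if (!all(ok)) {
        return("significance flag inconsistent with q/logFC thresholds")
      }
    }
  }
  TRUE
})

setMethod("show", "DEResult", function(object) {
  cat(sprintf("DEResult: %s vs %s; %d genes tested, %d significant\n",
              object@groupA, object@groupB, nrow(object@table),
              sum(object@table$significant)))
})

# ---------------------------------------------------------------------------
# SignatureSet
# ---------------------------------------------------------------------------

#' Conserved-core and tissue-specific identity signatures
#'
#' @slot conservedCore genes highly expressed in every tissue and prevalent
#'   in every control single-cell population.
#' @slot tissueSignatures named list of per-tissue specific gene lists
#'   (pairwise disjoint after derivation).
#' @slot confoundedPairs two-column matrix of tissue pairs whose preliminary
#'   signatures overlapped (mutually excluded during derivation).
#' @slot filters record of the thresholds and exclusions applied, including
#'   per-gene prevalence pass/fail when the prevalence filter was run.
#' @export
setClass("SignatureSet", representation(
  conservedCore = "character", tissueSignatures = "list",
  confoundedPairs = "matrix", filters = "list"
))

setValidity("SignatureSet", function(object) {
  sig <- object@tissueSignatures
  cp <- object@confoundedPairs
  isConfounded <- function(a, b) {
    nrow(cp) > 0L && any((cp[, 1L] == a & cp[, 2L] == b) |
                         (cp[, 1L] == b & cp[, 2L] == a))
  }
  nm <- names(sig)
  if (length(sig) > 1L) {
    for (i in seq_along(sig)) {
      for (j in seq_along(sig)) {
        # confounded pairs are mutually excluded during derivation and may
        # legitimately share signature genes; all other pairs are disjoint
        if (i < j && !isConfounded(nm[i], nm[j]) &&
            length(intersect(sig[[i]], sig[[j]]))) {
          return("non-confounded tissue signatures must be pairwise disjoint")
        }
      }
    }
  }
  TRUE
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", length(object@conservedCore), "conserved-core genes\n")
  for (t in names(object@tissueSignatures)) {
    cat(sprintf("  %s: %d signature genes\n", t,
                length(object@tissueSignatures[[t]])))
  }
  if (nrow(object@confoundedPairs)) {
    cat("  confounded pairs:",
        paste(apply(object@confoundedPairs, 1, paste, collapse = "~"),
              collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# ErosionReport
# ---------------------------------------------------------------------------

#' Identity-erosion summary for one tissue
#'
#' The erosion fraction is the share of the tissue's identity-signature
#' genes called significantly differentially expressed between knockout and
#' control cells.
#'
#' @slot tissue tissue identifier.
#' @slot signature the identity-signature genes scored.
#' @slot erodedGenes signature genes significantly DE in KO vs control.
#' @slot erosionFraction `length(erodedGenes) / length(signature)`.
#' @slot deGenes all significant DE genes (KO vs control).
#' @slot originSubtracted DE genes after removing origin-associated genes.
#' @slot params thresholds and provenance.
#' @export
setClass("ErosionReport", representation(
  tissue = "character", signature = "character", erodedGenes = "character",
  erosionFraction = "numeric", deGenes = "character",
  originSubtracted = "character", params = "list"
))

setValidity("ErosionReport", function(object) {
  if (length(object@signature) &&
      !all(object@erodedGenes %in% object@signature)) {
    return("erodedGenes must be a subset of the signature")
  }
  f <- object@erosionFraction
  if (length(f) && (f < 0 || f > 1)) {
    return("erosionFraction must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "ErosionReport", function(object) {
  cat(sprintf(
    "ErosionReport [%s]: %d/%d signature genes DE (erosion %.1f%%); %d DE genes%s\n",
    object@tissue, length(object@erodedGenes), length(object@signature),
    100 * object@erosionFraction, length(object@deGenes),
    if (length(object@originSubtracted)) {
      sprintf(" (%d after origin subtraction)",
              length(object@originSubtracted))
    } else {
      ""
    }
  ))
})
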