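# Genotype-group assignment of clusters and bimodal stratification.

#' Assign clusters to genotype groups
#'
#' Each cluster is labelled from the genotype composition of its cells and
#' the prevalence of knockout gain-of-expression markers (fraction of cells
#' with any gain-marker UMI): `control` when the CRE+ fraction is at most
#' `1 - crePurity`; `KO` when the CRE+ fraction is at least `crePurity` and
#' marker prevalence reaches `markerPrevalenceMin`; `het` when the cluster
#' is CRE+-pure but marker-negative (heterozygous escaper cells); `mixed`
#' otherwise. Mean target-gene expression per cluster is reported as
#' supporting evidence only - the floxed construct yields a truncated 3'
#' transcript, so the target's measured level cannot classify deletion on
#' its own. Cells inherit their cluster's label.
#'
#' @param clusters a [ClusterResult-class] or integer label vector.
#' @param genotype per-cell genotype labels, `"CRE-"` or `"CRE+"`; at least
#'   one CRE- cell is required as the control reference.
#' @param counts genes x cells count matrix (marker presence is UMI > 0).
#' @param norm normalised log-expression matrix (target-gene evidence).
#' @param gainMarkers gain-marker gene identifiers (must be in `counts`).
#' @param targetGene the floxed target gene.
#' @param crePurity CRE+ fraction defining genotype-pure clusters
#'   (default 0.8).
#' @param markerPrevalenceMin gain-marker prevalence separating KO from het
#'   clusters (default 0.5).
#' @return a [GroupAssignment-class].
#' @export
assignGroups <- function(clusters, genotype, counts, norm, gainMarkers,
                         targetGene, crePurity = 0.8,
                         markerPrevalenceMin = 0.5) {
  labels <- if (methods::is(clusters, "ClusterResult")) {
    clusterLabels(clusters)
  } else {
    as.integer(clusters)
  }
  counts <- .countsMatrix(counts)
  if (!all(gainMarkers %in% rownames(counts))) {
    stop("gain markers absent from the count matrix: ",
         paste(setdiff(gainMarkers, rownames(counts)), collapse = ", "))
  }
  genotype <- as.character(genotype)
  if (!any(genotype == "CRE-")) {
    stop("no CRE- cells present: a control reference is required")
  }
  markerPos <- Matrix::colSums(
    counts[gainMarkers, , drop = FALSE] > 0
  ) > 0
  targetExpr <- if (!is.null(norm) && targetGene %in% rownames(norm)) {
    as.numeric(norm[targetGene, ])
  } else {
    rep(NA_real_, length(labels))
  }

  ids <- sort(unique(labels))
  creFrac <- markerPrev <- targetMean <- numeric(length(ids))
  size <- integer(length(ids))
  group <- character(length(ids))
  for (k in seq_along(ids)) {
    inC <- labels == ids[k]
    size[k] <- sum(inC)
    creFrac[k] <- mean(genotype[inC] == "CRE+")
    markerPrev[k] <- mean(markerPos[inC])
    targetMean[k] <- mean(targetExpr[inC])
    group[k] <- if (creFrac[k] <= 1 - crePurity) {
      "control"
    } else if (creFrac[k] >= crePurity) {
      if (markerPrev[k] >= markerPrevalenceMin) "KO" else "het"
    } else {
      "mixed"
    }
  }
  tab <- S4Vectors::DataFrame(
    cluster = ids, group = group, crePosFraction = creFrac,
    markerPrevalence = markerPrev, targetMean = targetMean, nCells = size
  )
  cellGroups <- factor(group[match(labels, ids)],
                       levels = c("control", "het", "KO", "mixed"))
  methods::new("GroupAssignment", clusterTable = tab,
               cellGroups = cellGroups,
               params = list(crePurity = crePurity,
                             markerPrevalenceMin = markerPrevalenceMin,
                             gainMarkers = gainMarkers,
                             targetGene = targetGene))
}

#' Stratify cells by a bimodally expressed gene
#'
#' The threshold on the gene's log expression is chosen by exhaustive scan
#' over midpoints of observed values, maximising between-class variance
#' (Otsu's criterion); cells above the threshold are `high`, the rest
#' `low`. Errors on constant genes and when either side ends up smaller
#' than `minCellsPerSide`.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param gene gene to stratify on.
#' @param minCellsPerSide minimum cells required on each side (default 20).
#' @return factor of `"low"`/`"high"` per cell with the chosen threshold as
#'   attribute `"threshold"`.
#' @export
stratifyByGene <- function(norm, gene, minCellsPerSide = 20) {
  if (!gene %in% rownames(norm)) stop("gene not present: ", gene)
  x <- as.numeric(norm[gene, ])
  if (length(unique(x)) < 2L) {
    stop(sprintf("gene '%s' has constant expression", gene))
  }
  thr <- .otsuThreshold(x)
  side <- factor(ifelse(x > thr, "high", "low"), levels = c("low", "high"))
  if (min(table(side)) < minCellsPerSide) {
    stop(sprintf(
      "stratification by '%s' leaves a side with fewer than %d cells",
      gene, minCellsPerSide
    ))
  }
  names(side) <- colnames(norm)
  attr(side, "threshold") <- thr
  side
}
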