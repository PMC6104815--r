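#' @importFrom stats kmeans sd
NULL

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the library size (total UMI counts), the number
#' of detected genes (nonzero counts) and the fraction of counts assigned to
#' mitochondrial genes. Cells with zero total counts get a mitochondrial
#' fraction of 0.
#'
#' @param counts genes x cells count matrix (dense or sparse) or a
#'   SingleCellExperiment with a `counts` assay.
#' @param mitoGenes character vector of mitochondrial gene identifiers;
#'   identifiers absent from the matrix trigger a warning.
#' @return a [S4Vectors::DataFrame] with columns `totalCounts`,
#'   `detectedGenes`, `mitoFraction`, one row per cell.
#' @examples
#' m <- matrix(c(5, 0, 3), nrow = 3,
#'             dimnames = list(c("a", "b", "mt-1"), "cell1"))
#' computeCellQC(m, "mt-1")
#' @export
computeCellQC <- function(counts, mitoGenes = character()) {
  counts <- .countsMatrix(counts)
  missing <- setdiff(mitoGenes, rownames(counts))
  if (length(missing)) {
    warning("mitochondrial genes absent from matrix: ",
            paste(missing, collapse = ", "))
  }
  mitoGenes <- intersect(mitoGenes, rownames(counts))
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- if (length(mitoGenes)) {
    Matrix::colSums(counts[mitoGenes, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mitoFraction <- ifelse(total > 0, mito / total, 0)
  S4Vectors::DataFrame(
    totalCounts = unname(total), detectedGenes = unname(detected),
    mitoFraction = unname(mitoFraction), row.names = colnames(counts)
  )
}

#' @noRd
.scaledMad <- function(x) 1.4826 * median(abs(x - median(x)))

#' Median-absolute-deviation outlier filter
#'
#' A cell is kept iff it is within `nMads` scaled MADs (constant 1.4826) of
#' the median on all three QC metrics, in the biologically meaningful
#' direction for each: lower tail for `log2(totalCounts + 1)` and
#' `log2(detectedGenes + 1)`, upper tail for the raw mitochondrial
#' fraction. A metric whose MAD is zero flags no cell.
#'
#' @param metrics output of [computeCellQC()] (or any data.frame with the
#'   same columns).
#' @param nMads the MAD multiplier (default 3).
#' @return logical keep-mask, one entry per cell, with a `"flags"` attribute
#'   holding the per-metric outlier calls.
#' @export
madOutlierFilter <- function(metrics, nMads = 3) {
  if (nrow(metrics) < 2L) stop("need at least 2 cells")
  lowTail <- function(x) {
    m <- .scaledMad(x)
    if (m == 0) rep(FALSE, length(x)) else x < median(x) - nMads * m
  }
  highTail <- function(x) {
    m <- .scaledMad(x)
    if (m == 0) rep(FALSE, length(x)) else x > median(x) + nMads * m
  }
  flags <- cbind(
    lowTotal = lowTail(log2(metrics$totalCounts + 1)),
    lowDetected = lowTail(log2(metrics$detectedGenes + 1)),
    highMito = highTail(metrics$mitoFraction)
  )
  keep <- !apply(flags, 1L, any)
  names(keep) <- rownames(metrics)
  attr(keep, "flags") <- flags
  keep
}

#' Low-abundance gene filter
#'
#' A gene is kept iff its mean count across cells is at least `minMean`.
#'
#' @param counts genes x cells count matrix or SingleCellExperiment.
#' @param minMean minimum mean count (default 0.01).
#' @return logical keep-mask over genes.
#' @export
filterLowAbundanceGenes <- function(counts, minMean = 0.01) {
  counts <- .countsMatrix(counts)
  keep <- Matrix::rowMeans(counts) >= minMean
  names(keep) <- rownames(counts)
  keep
}

#' Library-size size factors
#'
#' Size factors are proportional to the per-cell library size and rescaled
#' to have mean 1, so that normalisation preserves the average scale of the
#' data.
#'
#' @param counts genes x cells count matrix or SingleCellExperiment.
#' @return numeric vector of positive size factors with mean 1.
#' @export
computeSizeFactors <- function(counts) {
  counts <- .countsMatrix(counts)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    stop("cells with zero total counts must be removed by QC before ",
         "size-factor computation")
  }
  sf <- lib / mean(lib)
  names(sf) <- colnames(counts)
  sf
}

#' Log2 normalisation by size factors
#'
#' Normalised expression is `log2(1 + count / sizeFactor)`; the pseudocount
#' of 1 keeps zeros at zero and the transformation is monotone within each
#' cell, so within-cell ranks are preserved.
#'
#' @param counts genes x cells count matrix or SingleCellExperiment.
#' @param sizeFactors per-cell size factors; computed with
#'   [computeSizeFactors()] when `NULL`.
#' @return dense numeric matrix of log2 expression values (genes x cells)
#'   with the size factors attached as attribute `"sizeFactors"`.
#' @export
normalizeLogCounts <- function(counts, sizeFactors = NULL) {
  counts <- .countsMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  norm <- log2(1 + sweep(as.matrix(counts), 2L, sizeFactors, "/"))
  attr(norm, "sizeFactors") <- sizeFactors
  norm
}

#' Flag actively proliferating cells
#'
#' The mean log-expression of the cell-cycle genes is z-scored across cells;
#' cells above `zThreshold` are flagged. If the score has zero variance no
#' cell is flagged.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param cycleGenes cell-cycle gene identifiers; an empty intersection with
#'   the matrix is an error.
#' @param zThreshold z-score cutoff (default 2).
#' @return logical flag-mask over cells.
#' @export
flagProliferating <- function(norm, cycleGenes, zThreshold = 2) {
  cycleGenes <- intersect(cycleGenes, rownames(norm))
  if (!length(cycleGenes)) {
    stop("no cycle genes present in the expression matrix")
  }
  score <- Matrix::colMeans(norm[cycleGenes, , drop = FALSE])
  s <- stats::sd(score)
  if (is.na(s) || s == 0) {
    flag <- rep(FALSE, ncol(norm))
  } else {
    flag <- (score - mean(score)) / s > zThreshold
  }
  names(flag) <- colnames(norm)
  flag
}

#' Flag contaminating cells co-expressing exclusive marker sets
#'
#' For each supplied pair of disjoint marker-gene sets, the per-cell mean
#' expression of each set is thresholded at the midpoint between the two
#' modes of its distribution (located by 1-D 2-means); a cell is flagged iff
#' both set means of some pair exceed their thresholds, the signature of a
#' doublet spanning two populations.
#'
#' @param norm normalised log-expression matrix (genes x cells).
#' @param markerPairs list of pairs; each pair is a list of two disjoint
#'   character vectors of gene identifiers.
#' @return logical flag-mask over cells (all `FALSE` when no pairs given).
#' @export
flagContaminants <- function(norm, markerPairs = list()) {
  flag <- rep(FALSE, ncol(norm))
  names(flag) <- colnames(norm)
  setPositive <- function(genes) {
    genes <- intersect(genes, rownames(norm))
    if (!length(genes)) return(rep(FALSE, ncol(norm)))
    s <- Matrix::colMeans(norm[genes, , drop = FALSE])
    if (length(unique(s)) < 2L) return(rep(FALSE, ncol(norm)))
    km <- stats::kmeans(s, centers = matrix(c(min(s), max(s)), 2L, 1L))
    s > mean(km$centers)
  }
  for (pair in markerPairs) {
    if (length(intersect(pair[[1L]], pair[[2L]]))) {
      stop("marker pair sets must be disjoint")
    }
    flag <- flag | (setPositive(pair[[1L]]) & setPositive(pair[[2L]]))
  }
  flag
}
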