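# Signature derivation, identity-erosion scoring and set operations.

#' @noRd
.bulkMatrix <- function(bulk) {
  if (methods::is(bulk, "SummarizedExperiment")) {
    bulk <- SummarizedExperiment::assay(bulk, "meanExpr")
  }
  as.matrix(bulk)
}

#' Derive a tissue-specific identity signature from bulk profiles
#'
#' A gene belongs to the signature of `tissue` iff its expression there is
#' at least `exprMin` and at least `fcThreshold` times the reference summary
#' of all other non-excluded tissues. The reference is the per-gene
#' `"max"` over other tissues for the final, strict derivation; `"median"`
#' is used for preliminary signatures during confound detection, where a
#' single overlapping tissue must not mask shared genes.
#'
#' @param bulk tissues panel: output of [simulateBulkProfiles()] or a
#'   genes x tissues matrix.
#' @param tissue tissue column name.
#' @param exclusions tissue names excluded from the reference (e.g. the
#'   confounded partner); the tissue itself cannot be excluded.
#' @param fcThreshold fold-change threshold (default 2).
#' @param exprMin minimum expression in `tissue`; defaults to the median of
#'   the tissue's nonzero values.
#' @param against reference summary over other tissues, `"max"` (default)
#'   or `"median"`.
#' @return character vector of signature genes.
#' @export
deriveTissueSignature <- function(bulk, tissue, exclusions = character(),
                                  fcThreshold = 2, exprMin = NULL,
                                  against = c("max", "median")) {
  against <- match.arg(against)
  M <- .bulkMatrix(bulk)
  if (!tissue %in% colnames(M)) stop("unknown tissue: ", tissue)
  if (tissue %in% exclusions) stop("a tissue cannot exclude itself")
  others <- setdiff(colnames(M), c(tissue, exclusions))
  if (!length(others)) stop("all other tissues excluded")
  x <- M[, tissue]
  if (is.null(exprMin)) exprMin <- median(x[x > 0])
  ref <- apply(M[, others, drop = FALSE], 1L,
               if (against == "max") max else median)
  rownames(M)[x >= exprMin & x >= fcThreshold * ref]
}

#' Detect tissue pairs with confounded transcriptional profiles
#'
#' Preliminary signatures are derived per tissue with no exclusions, using
#' the median of the other tissues as reference (so genes shared by a pair
#' still enter both preliminary lists); a pair is flagged iff the Jaccard
#' index of its preliminary signatures exceeds `overlapThreshold`.
#'
#' @inheritParams deriveTissueSignature
#' @param overlapThreshold Jaccard cutoff (default 0.25).
#' @return two-column character matrix of flagged tissue pairs (zero rows
#'   when none).
#' @export
detectConfoundedPairs <- function(bulk, fcThreshold = 2,
                                  overlapThreshold = 0.25, exprMin = NULL) {
  M <- .bulkMatrix(bulk)
  tissues <- colnames(M)
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  prelim <- lapply(tissues, function(t) {
    deriveTissueSignature(M, t, fcThreshold = fcThreshold,
                          exprMin = exprMin, against = "median")
  })
  names(prelim) <- tissues
  pairs <- matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("tissue1", "tissue2")))
  for (i in seq_along(tissues)) {
    for (j in seq_along(tissues)) {
      if (i >= j) next
      a <- prelim[[i]]
      b <- prelim[[j]]
      u <- length(union(a, b))
      jac <- if (u == 0L) 0 else length(intersect(a, b)) / u
      if (jac > overlapThreshold) {
        pairs <- rbind(pairs, c(tissues[i], tissues[j]))
      }
    }
  }
  attr(pairs, "preliminary") <- prelim
  pairs
}

#' Single-cell prevalence filter for signature genes
#'
#' Bulk-derived signatures can contain genes contributed by contaminating
#' cells; a gene is retained only if it is expressed (UMI > 0) in at least
#' `minFraction` of the control (CRE-) cells.
#'
#' @param signature character vector of candidate genes.
#' @param controlCounts genes x cells count matrix of control cells only.
#' @param minFraction minimum expressed fraction (default 0.20).
#' @return the filtered signature (a subset of the input, order preserved),
#'   with the per-gene prevalence attached as attribute `"prevalence"`.
#' @export
prevalenceFilter <- function(signature, controlCounts, minFraction = 0.20) {
  controlCounts <- .countsMatrix(controlCounts)
  if (!ncol(controlCounts)) stop("empty control cell set")
  prev <- setNames(numeric(length(signature)), signature)
  present <- intersect(signature, rownames(controlCounts))
  prev[present] <- Matrix::rowMeans(
    controlCounts[present, , drop = FALSE] > 0
  )
  out <- signature[prev[signature] >= minFraction]
  attr(out, "prevalence") <- prev
  out
}

#' Derive the conserved macrophage core signature
#'
#' A gene belongs to the conserved core iff its bulk expression is at least
#' `exprMin` in every tissue and it passes the single-cell prevalence
#' filter in every supplied control population. When `exprMin` is `NULL` it
#' is chosen automatically on `log2(min expression across tissues + 1)` as
#' the midpoint of the largest gap among values above the median,
#' separating the small highly-expressed-everywhere mode from the bulk of
#' genes (a gap-based rule is robust to the extreme class imbalance that
#' defeats variance-based thresholds here).
#'
#' @inheritParams deriveTissueSignature
#' @param controlCountsList list of genes x cells control count matrices,
#'   one per profiled tissue (may be empty to skip the prevalence check).
#' @param minPrevalence single-cell prevalence threshold (default 0.20).
#' @param excludeGenes genes never admitted to the core (typically the
#'   mitochondrial genes, which are highly expressed everywhere but carry
#'   cell-quality rather than lineage-identity signal).
#' @return character vector of conserved-core genes.
#' @export
deriveConservedCore <- function(bulk, exprMin = NULL,
                                controlCountsList = list(),
                                minPrevalence = 0.20,
                                excludeGenes = character()) {
  M <- .bulkMatrix(bulk)
  if (ncol(M) < 2L) stop("need at least 2 tissues")
  M <- M[setdiff(rownames(M), excludeGenes), , drop = FALSE]
  lo <- apply(M, 1L, min)
  if (is.null(exprMin)) {
    v <- sort(log2(lo + 1))
    v <- v[v >= median(v)]
    if (length(unique(v)) < 2L) {
      stop("cannot choose exprMin automatically: constant expression")
    }
    gaps <- diff(v)
    i <- which.max(gaps)
    exprMin <- 2^((v[i] + v[i + 1L]) / 2) - 1
  }
  core <- rownames(M)[lo >= exprMin]
  for (cc in controlCountsList) {
    core <- as.character(prevalenceFilter(core, cc, minPrevalence))
  }
  core
}

#' Score identity erosion of a signature
#'
#' The erosion fraction is the share of signature genes whose significance
#' flag is set in the knockout-versus-control differential-expression
#' result; genes not tested (e.g. filtered by prevalence) count as not
#' differentially expressed.
#'
#' @param signature nonempty character vector of identity-signature genes.
#' @param de a [DEResult-class] comparing knockout with control cells.
#' @param tissue tissue identifier recorded in the report.
#' @return an [ErosionReport-class] (origin subtraction not yet applied).
#' @export
identityErosion <- function(signature, de, tissue = "") {
  if (!length(signature)) stop("empty signature")
  sigDE <- significantGenes(de)
  eroded <- signature[signature %in% sigDE]
  methods::new("ErosionReport",
    tissue = tissue, signature = as.character(signature),
    erodedGenes = as.character(eroded),
    erosionFraction = length(eroded) / length(signature),
    deGenes = sigDE, originSubtracted = character(),
    params = de@params
  )
}

#' Remove origin-associated genes from a DE list
#'
#' Set difference preserving the input order: genes differing between
#' monocyte-derived and embryonically derived macrophages are subtracted so
#' that replacement of the population is not mistaken for identity loss.
#'
#' @param genes character vector of DE genes.
#' @param originGenes origin-associated gene list.
#' @return `genes` without `originGenes`, order preserved.
#' @export
subtractOriginGenes <- function(genes, originGenes) {
  genes[!genes %in% originGenes]
}

#' Cross-tissue conservation partition of DE gene lists
#'
#' Computes the full Venn partition: every gene in the union is assigned to
#' the exact subset of tissues in which it is differentially expressed, by
#' exact membership-signature hashing. Counts are reported for every
#' nonempty tissue subset, alongside convenience fields.
#'
#' @param deLists named list (>= 2 entries) of per-tissue DE gene vectors.
#' @return list with elements `partition` (data.frame: subset label, count),
#'   `sharedAll` (genes DE in every tissue), `unique` (named list of
#'   per-tissue exclusive genes), `pairwise` (matrix of pairwise overlap
#'   counts) and `membership` (named list mapping each gene to its subset).
#' @export
crossTissueConservation <- function(deLists) {
  if (length(deLists) < 2L) stop("need at least 2 DE lists")
  if (is.null(names(deLists)) || any(!nzchar(names(deLists)))) {
    names(deLists) <- sprintf("tissue%d", seq_along(deLists))
  }
  tissues <- names(deLists)
  genes <- sort(unique(unlist(deLists, use.names = FALSE)))
  member <- vapply(deLists, function(l) genes %in% l,
                   logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(m) paste(tissues[m], collapse = "&"))
  # enumerate all nonempty subsets so empty cells are reported as zeros
  subsetLabels <- unlist(lapply(seq_along(tissues), function(k) {
    apply(utils::combn(tissues, k), 2L, paste, collapse = "&")
  }))
  counts <- integer(length(subsetLabels))
  names(counts) <- subsetLabels
  tabulated <- table(sig)
  counts[names(tabulated)] <- as.integer(tabulated)
  uniq <- lapply(tissues, function(t) genes[sig == t])
  names(uniq) <- tissues
  pw <- matrix(0L, length(tissues), length(tissues),
               dimnames = list(tissues, tissues))
  for (i in tissues) {
    for (j in tissues) {
      pw[i, j] <- length(intersect(deLists[[i]], deLists[[j]]))
    }
  }
  list(
    partition = data.frame(subset = subsetLabels, count = unname(counts)),
    sharedAll = genes[sig == paste(tissues, collapse = "&")],
    unique = uniq,
    pairwise = pw,
    membership = stats::setNames(as.list(sig), genes)
  )
}
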