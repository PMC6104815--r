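#' @importFrom utils read.delim write.table
#' @importFrom Matrix readMM writeMM
NULL

#' Read a single-cell count matrix
#'
#' Accepts either a Matrix Market trio directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, genes as rows - the
#' CellRanger-style layout) or a dense TSV matrix with gene rows and cell
#' columns. Duplicate gene identifiers are disambiguated by suffixing
#' (`GeneA`, `GeneA.1`, ...); cell identifiers are made unique the same way.
#'
#' @param path directory containing an MTX trio, or a TSV file.
#' @return a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#'   with an integer sparse `counts` assay, genes as rows.
#' @seealso [writeExperiment()] for the inverse operation.
#' @export
readCounts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx found in ", path)
    m <- Matrix::readMM(mtx)
    if (any(m@x != round(m@x))) {
      stop("non-integer entries in MTX file ", mtx)
    }
    featFile <- file.path(path, "features.tsv")
    if (!file.exists(featFile)) featFile <- file.path(path, "genes.tsv")
    feats <- readLines(featFile)
    bcs <- readLines(file.path(path, "barcodes.tsv"))
    if (length(feats) != nrow(m) || length(bcs) != ncol(m)) {
      stop(sprintf(
        "dimension mismatch: matrix is %d x %d but %d features / %d barcodes listed",
        nrow(m), ncol(m), length(feats), length(bcs)
      ))
    }
    counts <- methods::as(m, "CsparseMatrix")
    dimnames(counts) <- list(make.unique(feats), make.unique(bcs))
  } else {
    tab <- utils::read.delim(path, row.names = NULL, check.names = FALSE)
    genes <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    if (any(mat != round(mat))) stop("non-integer entries in TSV file ", path)
    dimnames(mat) <- list(make.unique(genes), make.unique(colnames(mat)))
    counts <- methods::as(mat, "CsparseMatrix")
  }
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

#' Write a count matrix as a Matrix Market trio
#'
#' Genes as rows, cells as columns, 1-based indices per Matrix Market
#' convention; `features.tsv` and `barcodes.tsv` hold the dimnames.
#'
#' @param counts matrix or sparse Matrix of counts (genes x cells).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCountsMtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a simulated experiment to disk
#'
#' Emits one MTX trio per sample, a ground-truth TSV (barcode, sample,
#' genotype, true class) and a YAML echo of the simulation configuration.
#'
#' @param sce output of [simulateTissueExperiment()].
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
writeExperiment <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd <- SummarizedExperiment::colData(sce)
  for (s in unique(cd$sample)) {
    keep <- cd$sample == s
    writeCountsMtx(counts[, keep, drop = FALSE], file.path(dir, s))
  }
  gt <- data.frame(
    barcode = cd$barcode, sample = cd$sample,
    genotype = as.character(cd$genotype),
    trueClass = as.character(cd$trueClass)
  )
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- S4Vectors::metadata(sce)$config
  if (!is.null(cfg)) {
    yaml::write_yaml(.configAsList(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @noRd
.configAsList <- function(config) {
  out <- lapply(methods::slotNames(config), function(s) slot(config, s))
  names(out) <- methods::slotNames(config)
  lapply(out, function(v) if (length(v) == 1L) unname(v) else v)
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` starts a comment; blank lines are ignored. The
#' returned list preserves order and drops duplicates.
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene list in file ", path)
  unique(lines)
}

#' Read analysis thresholds from a YAML or JSON config file
#'
#' Flat keys matching the arguments of [RunConfig()]; keys absent from the
#' file keep their defaults, and arguments passed through `...` override the
#' file.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @param ... overrides, e.g. `fdrThreshold = 0.01`.
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(RunConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    warning("ignoring unknown config keys: ", paste(bad, collapse = ", "))
    vals <- vals[intersect(names(vals), known)]
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(RunConfig, vals)
}

#' Summarise an erosion report as a plain list
#'
#' The list form is what [writeReport()] serialises to JSON; reading the
#' JSON back yields exactly this structure.
#'
#' @param report an [ErosionReport-class].
#' @return a named list of scalar summaries and gene lists.
#' @export
erosionSummary <- function(report) {
  list(
    tissue = report@tissue,
    signatureSize = length(report@signature),
    nEroded = length(report@erodedGenes),
    erosionFraction = report@erosionFraction,
    nDE = length(report@deGenes),
    nOriginSubtracted = length(report@originSubtracted),
    erodedGenes = as.list(report@erodedGenes),
    deGenes = as.list(report@deGenes),
    originSubtracted = as.list(report@originSubtracted)
  )
}

#' Write analysis reports to disk
#'
#' Reports are written as TSV tables plus a JSON summary; output is
#' deterministic so identical analyses produce byte-identical files.
#'
#' @param x an [ErosionReport-class] or an erosion-study list from
#'   [runErosionStudy()].
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
setGeneric("writeReport", function(x, dir) standardGeneric("writeReport"))

#' @rdname writeReport
#' @export
setMethod("writeReport", "ErosionReport", function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    gene = x@signature,
    eroded = x@signature %in% x@erodedGenes
  )
  utils::write.table(tab, file.path(dir, paste0(x@tissue, "_erosion.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(erosionSummary(x),
                       file.path(dir, paste0(x@tissue, "_summary.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
})
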