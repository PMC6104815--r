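# Accessor generics and methods for the package's result classes.

#' @rdname ClusterResult-class
#' @param x a result object.
#' @return `clusterLabels()` returns the integer per-cell labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname GroupAssignment-class
#' @param x a `GroupAssignment`.
#' @return `cellGroups()` returns the per-cell group factor; `clusterTable()`
#'   the per-cluster composition `DataFrame`.
#' @export
setGeneric("cellGroups", function(x) standardGeneric("cellGroups"))

#' @rdname GroupAssignment-class
#' @export
setMethod("cellGroups", "GroupAssignment", function(x) x@cellGroups)

#' @rdname GroupAssignment-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname GroupAssignment-class
#' @export
setMethod("clusterTable", "GroupAssignment", function(x) x@clusterTable)

#' @rdname DEResult-class
#' @param x a `DEResult`.
#' @return `deTable()` returns the per-gene statistics `DataFrame`;
#'   `significantGenes()` the character vector of significant genes.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname DEResult-class
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname DEResult-class
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))

#' @rdname DEResult-class
#' @export
setMethod("significantGenes", "DEResult", function(x) {
  as.character(x@table$gene[x@table$significant])
})

#' @rdname SignatureSet-class
#' @param x a `SignatureSet`.
#' @return `conservedCore()` returns the conserved-core gene list;
#'   `tissueSignatures()` the named list of per-tissue signatures;
#'   `confoundedPairs()` the matrix of mutually excluded tissue pairs.
#' @export
setGeneric("conservedCore", function(x) standardGeneric("conservedCore"))

#' @rdname SignatureSet-class
#' @export
setMethod("conservedCore", "SignatureSet", function(x) x@conservedCore)

#' @rdname SignatureSet-class
#' @export
setGeneric("tissueSignatures", function(x) standardGeneric("tissueSignatures"))

#' @rdname SignatureSet-class
#' @export
setMethod("tissueSignatures", "SignatureSet", function(x) x@tissueSignatures)

#' @rdname SignatureSet-class
#' @export
setGeneric("confoundedPairs", function(x) standardGeneric("confoundedPairs"))

#' @rdname SignatureSet-class
#' @export
setMethod("confoundedPairs", "SignatureSet", function(x) x@confoundedPairs)

#' @rdname ErosionReport-class
#' @param x an `ErosionReport`.
#' @return `erosionFraction()` returns the scalar erosion fraction;
#'   `erodedGenes()` the signature genes called DE.
#' @export
setGeneric("erosionFraction", function(x) standardGeneric("erosionFraction"))

#' @rdname ErosionReport-class
#' @export
setMethod("erosionFraction", "ErosionReport", function(x) x@erosionFraction)

#' @rdname ErosionReport-class
#' @export
setGeneric("erodedGenes", function(x) standardGeneric("erodedGenes"))

#' @rdname ErosionReport-class
#' @export
setMethod("erodedGenes", "ErosionReport", function(x) x@erodedGenes)
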