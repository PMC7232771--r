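#' Accessors for seascape objects
#'
#' Small accessor generics used across the package: grid dimensions, habitat
#' cell indices, cell center coordinates, connectivity matrices and node ids,
#' cluster labels, and genotype dosages/site metadata.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("habitatCells", function(x) standardGeneric("habitatCells"))

#' @rdname accessors
#' @export
setGeneric("cellCenters", function(x, ...) standardGeneric("cellCenters"))

#' @rdname accessors
#' @export
setGeneric("connProbs", function(x, ...) standardGeneric("connProbs"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("generations", function(x) standardGeneric("generations"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))

#' Symmetrize a connectivity matrix
#'
#' Combine elements `(i, j)` and `(j, i)` with the elementwise minimum,
#' maximum or mean, producing a symmetric matrix; the diagonal is preserved.
#' FST-style comparisons require a symmetric counterpart of the inherently
#' directed dispersal matrix.
#'
#' @param x a [ConnectivityMatrix-class] or plain square matrix.
#' @param mode one of `"min"`, `"max"`, `"mean"`.
#' @return Same class as `x`, symmetric.
#' @export
setGeneric("symmetrize", function(x, mode = c("mean", "min", "max"))
  standardGeneric("symmetrize"))

#' Log-transform a connectivity matrix
#'
#' Elementwise `log10(x + 1e-50)`, the transform used before comparing
#' connectivity with genetic differentiation; zero connectivity maps to -50.
#'
#' @param x a [ConnectivityMatrix-class] or nonnegative matrix.
#' @param offset the additive offset before taking log10.
#' @return A plain numeric matrix.
#' @export
setGeneric("logConnectivity", function(x, offset = 1e-50)
  standardGeneric("logConnectivity"))
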