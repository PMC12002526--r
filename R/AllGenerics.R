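#' @include utils.R
NULL

#' Accessor generics
#'
#' Small family of accessors used across the package's S4 containers.
#' Each class documents which of these it supports.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return the corresponding slot content (see the class documentation).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x, ...) standardGeneric("taxonIds"))

#' @rdname accessors
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

#' Fréchet mean: compute (SpherePoints) or retrieve (TangentCoordinates)
#'
#' @param x a [SpherePoints-class] (compute the intrinsic mean) or a
#'   [TangentCoordinates-class] (return the mean the projection was built at).
#' @param ... method arguments such as `tol` and `maxIter`.
#' @return a unit vector of length `d`.
#' @export
setGeneric("frechetMean", function(x, ...) standardGeneric("frechetMean"))

#' @rdname accessors
#' @export
setGeneric("rotation", function(x, ...) standardGeneric("rotation"))

#' @rdname accessors
#' @export
setGeneric("sampleAngles", function(x, ...) standardGeneric("sampleAngles"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))

#' @rdname accessors
#' @export
setGeneric("variances", function(x, ...) standardGeneric("variances"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x, ...) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x, ...) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setGeneric("collisionGroups", function(x, ...) standardGeneric("collisionGroups"))

#' @rdname accessors
#' @export
setGeneric("foregroundMask", function(x, ...) standardGeneric("foregroundMask"))

#' @rdname accessors
#' @export
setGeneric("images", function(x, ...) standardGeneric("images"))

#' @rdname accessors
#' @export
setGeneric("foldAucs", function(x, ...) standardGeneric("foldAucs"))

#' @rdname accessors
#' @export
setGeneric("meanAuc", function(x, ...) standardGeneric("meanAuc"))

#' Project sphere points into an existing tangent frame
#'
#' @param x a fitted [TangentCoordinates-class] object.
#' @param points new [SpherePoints-class] with the same taxa.
#' @param ... unused.
#' @return a numeric matrix of tangent coordinates, `n x (d-1)`.
#' @export
setGeneric("projectPoints", function(x, points, ...) standardGeneric("projectPoints"))
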