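#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- CountTable

#' Sample-by-taxon count table
#'
#' Holds a nonnegative integer matrix of sequencing counts with unique sample
#' identifiers as row names and unique taxon (OTU/ASV) identifiers as column
#' names. Every sample must have at least one positive count: a sample with
#' zero total reads carries no compositional information.
#'
#' @slot counts numeric matrix, samples x taxa, nonnegative integers.
#' @seealso [readCountTable()], [closure()], [zeroMask()]
#' @export
setClass("CountTable", representation(counts = "matrix"))

.validCountTable <- function(object) {
  x <- object@counts
  msg <- character()
  if (!is.numeric(x)) msg <- c(msg, "counts must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "counts must carry sample ids (rownames) and taxon ids (colnames)")
  if (anyDuplicated(rownames(x))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(x))) msg <- c(msg, "duplicate taxon ids")
  if (is.numeric(x)) {
    if (anyNA(x) || any(!is.finite(x))) msg <- c(msg, "counts contain NA/non-finite values")
    else {
      if (any(x < 0)) {
        bad <- which(x < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("negative count at sample '%s', taxon '%s'",
                              rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
      }
      if (any(x != trunc(x))) {
        bad <- which(x != trunc(x), arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("non-integer count at sample '%s', taxon '%s'",
                              rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
      }
      rs <- rowSums(x)
      if (any(rs <= 0)) {
        msg <- c(msg, sprintf("sample '%s' has an all-zero row",
                              rownames(x)[which(rs <= 0)[1L]]))
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("CountTable", .validCountTable)

#' Construct a CountTable
#'
#' @param counts numeric matrix, samples x taxa.
#' @param sampleIds,taxonIds identifiers; default to the matrix dimnames.
#' @return a validated [CountTable-class].
#' @examples
#' ct <- CountTable(matrix(c(2, 0, 3, 0, 5, 4), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' counts(ct)
#' @export
CountTable <- function(counts, sampleIds = rownames(counts),
                       taxonIds = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(taxonIds)) taxonIds <- paste0("taxon", seq_len(ncol(counts)))
  dimnames(counts) <- list(as.character(sampleIds), as.character(taxonIds))
  methods::new("CountTable", counts = counts)
}

#' @rdname accessors
#' @export
setMethod("counts", "CountTable", function(x, ...) x@counts)
#' @rdname accessors
#' @export
setMethod("sampleIds", "CountTable", function(x, ...) rownames(x@counts))
#' @rdname accessors
#' @export
setMethod("taxonIds", "CountTable", function(x, ...) colnames(x@counts))

setMethod("show", "CountTable", function(object) {
  x <- object@counts
  cat(sprintf("CountTable: %d samples x %d taxa, %.1f%% zero cells\n",
              nrow(x), ncol(x), 100 * mean(x == 0)))
})

# ----------------------------------------------------------- CompositionTable

#' Compositions on the (boundary-admitting) simplex
#'
#' Rows are relative abundances: nonnegative, summing to one. Exact zeros are
#' allowed on the boundary — zero-inflated data are the package's whole
#' concern — even though the classical simplex is defined with strictly
#' positive parts.
#'
#' @slot values numeric matrix, samples x taxa, rows sum to 1.
#' @seealso [closure()], [sqrtTransform()]
#' @export
setClass("CompositionTable", representation(values = "matrix"))

setValidity("CompositionTable", function(object) {
  x <- object@values
  if (!is.numeric(x) || anyNA(x)) return("values must be a numeric matrix without NA")
  if (any(x < 0)) return("negative composition entry")
  if (is.null(rownames(x)) || is.null(colnames(x))) return("missing dimnames")
  dev <- abs(rowSums(x) - 1)
  if (any(dev > 1e-12)) {
    return(sprintf("row sums deviate from 1 (max |dev| = %.3g)", max(dev)))
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("values", "CompositionTable", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("sampleIds", "CompositionTable", function(x, ...) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("taxonIds", "CompositionTable", function(x, ...) colnames(x@values))

setMethod("show", "CompositionTable", function(object) {
  cat(sprintf("CompositionTable: %d samples x %d parts (row sums = 1)\n",
              nrow(object@values), ncol(object@values)))
})

# ---------------------------------------------------------------- SpherePoints

#' Points on the nonnegative orthant of the unit hypersphere
#'
#' The image of compositions under the square-root transform: each row has
#' unit Euclidean norm and nonnegative entries, so all points lie in one open
#' hemisphere and intrinsic means are well defined.
#'
#' @slot values numeric matrix, samples x d, unit-norm nonnegative rows.
#' @seealso [sqrtTransform()], [tangentProjection()], [frechetMean()]
#' @export
setClass("SpherePoints", representation(values = "matrix"))

setValidity("SpherePoints", function(object) {
  x <- object@values
  if (!is.numeric(x) || anyNA(x)) return("values must be a numeric matrix without NA")
  if (any(x < -1e-12)) return("negative entry: points must lie in the nonnegative orthant")
  if (is.null(rownames(x)) || is.null(colnames(x))) return("missing dimnames")
  dev <- abs(sqrt(rowSums(x^2)) - 1)
  if (any(dev > 1e-8)) {
    return(sprintf("rows are not unit vectors (max |norm-1| = %.3g)", max(dev)))
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("values", "SpherePoints", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("sampleIds", "SpherePoints", function(x, ...) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("taxonIds", "SpherePoints", function(x, ...) colnames(x@values))

setMethod("show", "SpherePoints", function(object) {
  cat(sprintf("SpherePoints: %d points on the unit sphere in R^%d\n",
              nrow(object@values), ncol(object@values)))
})

# ---------------------------------------------------------- TangentCoordinates

#' Tangent-space coordinates at the Fréchet mean
#'
#' Result of rotating the fitted Fréchet mean to the pole (0, ..., 0, 1) and
#' applying the pole Log map row-wise. The norm of each row equals the
#' geodesic distance of that sample from the mean; `sampleAngles()` returns
#' those angles. The rotation is determined by the mean and is materialised
#' on demand by `rotation()` (it is never stored densely).
#'
#' @slot values numeric matrix, samples x (d-1).
#' @slot mu unit vector of length d: the Fréchet mean on the sphere.
#' @slot theta numeric vector of per-sample geodesic distances from the mean.
#' @seealso [tangentProjection()], [projectPoints()], [pga()]
#' @export
setClass("TangentCoordinates",
         representation(values = "matrix", mu = "numeric", theta = "numeric"))

setValidity("TangentCoordinates", function(object) {
  x <- object@values
  if (is.null(rownames(x))) return("missing sample ids")
  if (abs(sqrt(sum(object@mu^2)) - 1) > 1e-10) return("Fréchet mean is not unit norm")
  if (length(object@theta) != nrow(x)) return("theta length != number of samples")
  if (any(object@theta < 0 | object@theta >= pi)) return("theta outside [0, pi)")
  dev <- abs(sqrt(rowSums(x^2)) - object@theta)
  if (any(dev > 1e-10)) {
    return(sprintf("row norms do not equal geodesic distances (max dev %.3g)", max(dev)))
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("values", "TangentCoordinates", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("sampleIds", "TangentCoordinates", function(x, ...) rownames(x@values))
#' @export
#' @describeIn frechetMean stored mean of a fitted tangent projection.
setMethod("frechetMean", "TangentCoordinates", function(x, ...) x@mu)
#' @rdname accessors
#' @export
setMethod("sampleAngles", "TangentCoordinates", function(x, ...) x@theta)
#' @rdname accessors
#' @export
setMethod("rotation", "TangentCoordinates", function(x, ...) rotationToPole(x@mu))

setMethod("show", "TangentCoordinates", function(object) {
  cat(sprintf("TangentCoordinates: %d samples x %d, max angle %.3f rad\n",
              nrow(object@values), ncol(object@values),
              if (length(object@theta)) max(object@theta) else NA_real_))
})

# -------------------------------------------------------------------- PGAResult

#' Principal geodesic analysis result
#'
#' Centered PCA of the tangent coordinates: scores, orthonormal loading
#' directions and nonincreasing component variances.
#'
#' @slot scores samples x k matrix.
#' @slot loadings (d-1) x k matrix with orthonormal columns.
#' @slot variances length-k nonincreasing nonnegative vector.
#' @slot k integer, number of retained components.
#' @seealso [pga()]
#' @export
setClass("PGAResult",
         representation(scores = "matrix", loadings = "matrix",
                        variances = "numeric", k = "integer"))

setValidity("PGAResult", function(object) {
  k <- object@k
  if (ncol(object@scores) != k || ncol(object@loadings) != k ||
      length(object@variances) != k) return("inconsistent component count")
  if (is.unsorted(rev(object@variances))) return("variances must be nonincreasing")
  if (any(object@variances < -1e-12)) return("negative variance")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(k))) > 1e-8) return("loadings are not orthonormal")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("scores", "PGAResult", function(x, ...) x@scores)
#' @rdname accessors
#' @export
setMethod("loadings", "PGAResult", function(x, ...) x@loadings)
#' @rdname accessors
#' @export
setMethod("variances", "PGAResult", function(x, ...) x@variances)

setMethod("show", "PGAResult", function(object) {
  v <- object@variances
  cat(sprintf("PGAResult: %d components; leading variance share %.1f%%\n",
              object@k, if (sum(v) > 0) 100 * v[1] / sum(v) else NA_real_))
})

# ----------------------------------------------------------------- FeatureLayout

#' 2-D feature layout from dimensionality reduction of the transposed matrix
#'
#' @slot coords features x 2 matrix of plane coordinates (rownames = feature ids).
#' @slot method one of `"pca"`, `"kpca"`, `"tsne"`.
#' @slot seed integer seed the embedding was run with.
#' @slot fittedOn identifier of the training subset the layout was fit on.
#' @seealso [featureLayout()], [pixelAssignment()]
#' @export
setClass("FeatureLayout",
         representation(coords = "matrix", method = "character",
                        seed = "integer", fittedOn = "character"))

setValidity("FeatureLayout", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns")
  if (anyNA(object@coords) || any(!is.finite(object@coords)))
    return("non-finite layout coordinates")
  if (is.null(rownames(object@coords))) return("missing feature ids")
  if (!object@method %in% c("pca", "kpca", "tsne")) return("unknown method")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("values", "FeatureLayout", function(x, ...) x@coords)

setMethod("show", "FeatureLayout", function(object) {
  cat(sprintf("FeatureLayout: %d features embedded by %s (seed %d)\n",
              nrow(object@coords), object@method, object@seed))
})

# --------------------------------------------------------------------- PixelMap

#' Feature-to-pixel assignment on a fixed grid
#'
#' Records, for every feature, the (row, col) pixel it lands on (0-based,
#' row 0 at the top), the rotation angle of the minimum-area bounding
#' rectangle used to axis-align the layout, the resulting foreground mask and
#' the collision groups (features sharing one pixel).
#'
#' @slot gridH,gridW integer grid dimensions.
#' @slot rotationAngle radians: orientation of the minimum-area rectangle.
#' @slot pixels features x 2 integer matrix of (row, col), 0-based.
#' @slot foregroundMask gridH x gridW logical, TRUE where >= 1 feature lands.
#' @slot groups named list: pixel key "row,col" -> integer feature indices.
#' @seealso [pixelAssignment()], [renderImages()]
#' @export
setClass("PixelMap",
         representation(gridH = "integer", gridW = "integer",
                        rotationAngle = "numeric", pixels = "matrix",
                        foregroundMask = "matrix", groups = "list"))

setValidity("PixelMap", function(object) {
  p <- object@pixels
  if (is.null(rownames(p))) return("missing feature ids")
  if (any(p < 0) || any(p[, 1] >= object@gridH) || any(p[, 2] >= object@gridW))
    return("pixel out of grid bounds")
  if (!identical(dim(object@foregroundMask), c(object@gridH, object@gridW)))
    return("foreground mask dimensions do not match the grid")
  if (sum(object@foregroundMask) != length(object@groups))
    return("foreground mask does not match collision groups")
  got <- sort(unlist(object@groups, use.names = FALSE))
  if (!identical(got, seq_len(nrow(p))))
    return("collision groups are not a partition of the features")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("gridDim", "PixelMap", function(x, ...) c(x@gridH, x@gridW))
#' @rdname accessors
#' @export
setMethod("pixelCoords", "PixelMap", function(x, ...) x@pixels)
#' @rdname accessors
#' @export
setMethod("collisionGroups", "PixelMap", function(x, ...) x@groups)
#' @rdname accessors
#' @export
setMethod("foregroundMask", "PixelMap", function(x, ...) x@foregroundMask)

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d features -> %dx%d grid, %d foreground pixels, %d collisions\n",
              nrow(object@pixels), object@gridH, object@gridW,
              sum(object@foregroundMask),
              sum(lengths(object@groups) > 1L)))
})

# ------------------------------------------------------------------- ImageStack

#' Stack of rendered sample images
#'
#' `n x H x W` array of values in `[0, 1]`. Background pixels (foreground
#' mask FALSE) are exactly zero in every image. When `epsilon > 0` the stack
#' was rendered with the segmentation offset: every foreground pixel of every
#' image is at least `epsilon`, so all images share one support and a "true
#' zero" (a zero-valued feature) remains distinguishable from the background.
#'
#' @slot images numeric array n x H x W; `dimnames[[1]]` are sample ids.
#' @slot foregroundMask H x W logical.
#' @slot epsilon nonnegative offset; 0 means no segmentation was applied.
#' @slot scheme normalization scheme the values were produced with.
#' @seealso [renderImages()], [supportMask()], [writeImageStack()]
#' @export
setClass("ImageStack",
         representation(images = "array", foregroundMask = "matrix",
                        epsilon = "numeric", scheme = "character"))

setValidity("ImageStack", function(object) {
  a <- object@images
  if (length(dim(a)) != 3L) return("images must be an n x H x W array")
  if (dim(a)[1] < 1L) return("empty stack: at least one sample image required")
  if (is.null(dimnames(a)[[1]])) return("missing sample ids")
  if (anyNA(a) || any(a < 0) || any(a > 1)) return("image values must lie in [0, 1]")
  if (!identical(dim(object@foregroundMask), dim(a)[2:3]))
    return("foreground mask dimensions do not match images")
  bg <- !object@foregroundMask
  if (any(bg) && any(apply(a, 1, function(im) any(im[bg] != 0))))
    return("background pixels must be exactly zero")
  eps <- object@epsilon
  if (length(eps) != 1L || eps < 0 || eps >= 1) return("epsilon must lie in [0, 1)")
  if (eps > 0) {
    fg <- object@foregroundMask
    if (any(apply(a, 1, function(im) any(im[fg] < eps))))
      return("segmented stack has a foreground pixel below epsilon")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("images", "ImageStack", function(x, ...) x@images)
#' @rdname accessors
#' @export
setMethod("foregroundMask", "ImageStack", function(x, ...) x@foregroundMask)
#' @rdname accessors
#' @export
setMethod("sampleIds", "ImageStack", function(x, ...) dimnames(x@images)[[1]])

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("ImageStack: %d images of %dx%d, epsilon = %.4g (%s)\n",
              d[1], d[2], d[3], object@epsilon,
              if (object@epsilon > 0) "segmented" else "unsegmented"))
})

# --------------------------------------------------------------------- CVReport

#' Cross-validation report
#'
#' @slot foldAucs per-fold held-out AUC values.
#' @slot folds list of held-out index vectors, one per fold.
#' @slot configsEvaluated number of configurations evaluated to produce this.
#' @slot bestConfig the training configuration used (a `TrainConfig` list).
#' @slot seed master seed of the run.
#' @slot details per-fold bookkeeping (e.g. selected normalization scheme).
#' @seealso [crossValidate()], [runPipeline()]
#' @export
setClass("CVReport",
         representation(foldAucs = "numeric", folds = "list",
                        configsEvaluated = "integer", bestConfig = "list",
                        seed = "integer", details = "list"))

setValidity("CVReport", function(object) {
  if (length(object@foldAucs) != length(object@folds))
    return("fold AUC / fold index mismatch")
  if (any(object@foldAucs < 0 | object@foldAucs > 1)) return("AUC outside [0, 1]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("foldAucs", "CVReport", function(x, ...) x@foldAucs)
#' @rdname accessors
#' @export
setMethod("meanAuc", "CVReport", function(x, ...) mean(x@foldAucs))

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d folds, mean AUC %.3f (range %.3f-%.3f), seed %d\n",
              length(object@foldAucs), mean(object@foldAucs),
              min(object@foldAucs), max(object@foldAucs), object@seed))
})
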