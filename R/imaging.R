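#' @include AllClasses.R
NULL

#' Embed features in the plane (transposed-matrix dimensionality reduction)
#'
#' First step of the DeepInsight layout: the training matrix is transposed so
#' that *features* become the points, and a 2-D embedding of the features is
#' computed. Supported embeddings: `"pca"` (first two principal components),
#' `"kpca"` (Gaussian-kernel PCA via \pkg{kernlab}), `"tsne"` (exact t-SNE,
#' perplexity `min(30, (nFeatures - 1) / 3)` unless overridden in `params`).
#' The result is deterministic for a fixed `(method, seed, params, input)`.
#'
#' The layout must be fit on training samples only; `fittedOn` records which.
#'
#' @param trainingMatrix numeric matrix, training samples x features.
#' @param method `"pca"`, `"kpca"` or `"tsne"`.
#' @param seed integer seed for stochastic embeddings (recorded always).
#' @param params optional list of method parameters (`perplexity`, `maxIter`,
#'   `sigma` for kpca).
#' @param fittedOn free-text identifier of the training subset.
#' @return a [FeatureLayout-class].
#' @export
featureLayout <- function(trainingMatrix, method = c("pca", "kpca", "tsne"),
                          seed = 1L, params = list(), fittedOn = "training") {
  method <- match.arg(method)
  X <- as.matrix(trainingMatrix)
  if (ncol(X) < 3L) {
    stop("at least 3 features are required (a bounding rectangle needs them)",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  G <- t(X)                                      # features x samples
  coords <- switch(method,
    pca = {
      if (stats::sd(as.vector(G)) == 0) {
        stop("degenerate input: all features identical, PCA layout undefined",
             call. = FALSE)
      }
      pc <- stats::prcomp(G, center = TRUE, scale. = FALSE)
      if (ncol(pc$x) < 2L) {
        stop("degenerate input: fewer than two principal components", call. = FALSE)
      }
      pc$x[, 1:2, drop = FALSE]
    },
    kpca = {
      sig <- params$sigma
      kp <- withr::with_seed(as.integer(seed), {
        if (is.null(sig)) kernlab::kpca(G, features = 2L)
        else kernlab::kpca(G, kernel = "rbfdot", kpar = list(sigma = sig),
                           features = 2L)
      })
      kernlab::rotated(kp)[, 1:2, drop = FALSE]
    },
    tsne = {
      perp <- if (is.null(params$perplexity)) min(30, (nrow(G) - 1) / 3)
              else params$perplexity
      maxIter <- if (is.null(params$maxIter)) 400L else as.integer(params$maxIter)
      .tsneExact(G, perplexity = perp, maxIter = maxIter, seed = as.integer(seed))
    })
  coords <- as.matrix(coords)
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop(sprintf("embedding '%s' produced non-finite coordinates", method),
         call. = FALSE)
  }
  rownames(coords) <- rownames(G)
  colnames(coords) <- c("x", "y")
  methods::new("FeatureLayout", coords = coords, method = method,
               seed = as.integer(seed), fittedOn = fittedOn)
}

#' Minimum-area bounding rectangle of a 2-D point set
#'
#' Convex hull followed by rotating calipers: the minimum-area enclosing
#' rectangle has one side collinear with a hull edge, so it suffices to test
#' each hull edge direction. Returns the rectangle orientation (radians; the
#' rotation by `-angle` axis-aligns the rectangle), its four corners in the
#' original frame, and its area.
#'
#' Collinear inputs fall back to the segment direction with a zero-height
#' rectangle, flagged by `collinear = TRUE`.
#'
#' @param coords numeric matrix or [FeatureLayout-class]; >= 3 points.
#' @return a list with elements `angle`, `corners` (4 x 2), `area`,
#'   `collinear`.
#' @export
minAreaRectangle <- function(coords) {
  if (methods::is(coords, "FeatureLayout")) coords <- values(coords)
  P <- as.matrix(coords)
  if (nrow(P) < 3L) stop("need at least 3 points", call. = FALSE)
  hull <- P[rev(grDevices::chull(P)), , drop = FALSE]   # counter-clockwise
  h <- nrow(hull)
  collinear <- h < 3L
  if (collinear) {
    dir <- hull[min(2L, h), ] - hull[1L, ]
    if (sum(dir^2) == 0) dir <- c(1, 0)
    angle <- atan2(dir[2], dir[1])
    edges <- matrix(angle, 1L)
  } else {
    nxt <- c(2:h, 1L)
    d <- hull[nxt, , drop = FALSE] - hull
    edges <- matrix(atan2(d[, 2], d[, 1]), ncol = 1L)
  }
  best <- NULL
  for (ang in edges[, 1L]) {
    ca <- cos(-ang); sa <- sin(-ang)
    xr <- hull[, 1] * ca - hull[, 2] * sa
    yr <- hull[, 1] * sa + hull[, 2] * ca
    area <- (max(xr) - min(xr)) * (max(yr) - min(yr))
    if (is.null(best) || area < best$area - 1e-15) {
      best <- list(angle = ang, area = area,
                   xr = range(xr), yr = range(yr))
    }
  }
  # corners of the aligned rectangle, rotated back to the original frame
  cr <- cbind(best$xr[c(1, 2, 2, 1)], best$yr[c(1, 1, 2, 2)])
  ca <- cos(best$angle); sa <- sin(best$angle)
  corners <- cbind(cr[, 1] * ca - cr[, 2] * sa,
                   cr[, 1] * sa + cr[, 2] * ca)
  colnames(corners) <- c("x", "y")
  list(angle = best$angle, corners = corners, area = best$area,
       collinear = collinear)
}

#' Assign features to pixels on a fixed grid
#'
#' Rotates the layout coordinates by `-angle` (axis-aligning the minimum-area
#' rectangle), rescales the rectangle affinely onto
#' `[0, gridH - 1] x [0, gridW - 1]`, and rounds half-away-from-zero to
#' integer pixels (0-based; row 0 at the top, i.e. at maximal y). Features
#' that land on the same pixel form a collision group.
#'
#' @param layout a [FeatureLayout-class] (or plain coordinate matrix).
#' @param angle rectangle orientation from [minAreaRectangle()].
#' @param gridH,gridW grid dimensions, both >= 2.
#' @return a [PixelMap-class].
#' @export
pixelAssignment <- function(layout, angle, gridH = 224L, gridW = 224L) {
  coords <- if (methods::is(layout, "FeatureLayout")) values(layout) else as.matrix(layout)
  if (is.null(rownames(coords))) rownames(coords) <- paste0("f", seq_len(nrow(coords)))
  gridH <- as.integer(gridH); gridW <- as.integer(gridW)
  if (gridH < 2L || gridW < 2L) stop("grid dimensions must be >= 2", call. = FALSE)
  ca <- cos(-angle); sa <- sin(-angle)
  xr <- coords[, 1] * ca - coords[, 2] * sa
  yr <- coords[, 1] * sa + coords[, 2] * ca
  sx <- diff(range(xr)); sy <- diff(range(yr))
  col <- if (sx == 0) rep(0, length(xr)) else (xr - min(xr)) / sx * (gridW - 1L)
  row <- if (sy == 0) rep(0, length(yr)) else (max(yr) - yr) / sy * (gridH - 1L)
  px <- cbind(row = .clamp(.roundHalfAway(row), 0L, gridH - 1L),
              col = .clamp(.roundHalfAway(col), 0L, gridW - 1L))
  storage.mode(px) <- "integer"
  rownames(px) <- rownames(coords)
  key <- sprintf("%d,%d", px[, 1], px[, 2])
  groups <- split(seq_len(nrow(px)), key)
  mask <- matrix(FALSE, gridH, gridW)
  mask[px[, 1] + 1L + gridH * px[, 2]] <- TRUE
  methods::new("PixelMap", gridH = gridH, gridW = gridW,
               rotationAngle = as.numeric(angle), pixels = px,
               foregroundMask = mask, groups = groups)
}

#' Normalize feature values to [0, 1] with training-set statistics
#'
#' Two schemes, selectable per run (or per fold by validation error, see
#' [crossValidate()]):
#' \describe{
#'   \item{independent}{each feature is scaled by its own training minimum
#'     and maximum, `(v - min) / (max - min)`; constant features map to 0.}
#'   \item{topology_preserving}{all cells share one affine map, the global
#'     training minimum and range, so the ordering of values *across*
#'     features is preserved.}
#' }
#' Statistics are computed on `trainIdx` rows only; out-of-range values in
#' the remaining (test) rows are clipped to `[0, 1]`.
#'
#' @param matrix numeric matrix, all samples x features.
#' @param scheme `"independent"` or `"topology_preserving"`.
#' @param trainIdx integer indices of the training rows (statistics source).
#' @return a matrix of the same shape with values in `[0, 1]`.
#' @export
normalizeValues <- function(matrix, scheme = c("independent", "topology_preserving"),
                            trainIdx = seq_len(nrow(matrix))) {
  scheme <- match.arg(scheme)
  X <- as.matrix(matrix)
  trainIdx <- as.integer(trainIdx)
  if (length(trainIdx) == 0L) stop("empty training subset", call. = FALSE)
  if (any(trainIdx < 1L | trainIdx > nrow(X))) stop("trainIdx out of range", call. = FALSE)
  Xt <- X[trainIdx, , drop = FALSE]
  if (scheme == "independent") {
    mn <- apply(Xt, 2L, min)
    rg <- apply(Xt, 2L, max) - mn
    out <- sweep(X, 2L, mn)
    pos <- rg > 0
    out[, pos] <- sweep(out[, pos, drop = FALSE], 2L, rg[pos], "/")
    out[, !pos] <- 0
  } else {
    mn <- min(Xt)
    rg <- max(Xt) - mn
    out <- if (rg > 0) (X - mn) / rg else X * 0
  }
  .clamp(out, 0, 1)
}

#' Render normalized feature values as a sample image stack
#'
#' Each sample becomes one `gridH x gridW` image: every foreground pixel
#' takes the aggregate (arithmetic mean by default) of its collision group's
#' normalized values; background pixels are 0. With `segment = TRUE`, every
#' foreground value `v` is replaced by `max(v, epsilon)` — a zero-valued
#' feature ("true zero") is lifted to `epsilon` and remains distinguishable
#' from the featureless background ("fake zero"), so all images share one
#' support and hence one shape. Without the offset, samples whose features
#' are all zero produce an image indistinguishable from empty background.
#'
#' The default `epsilon = 1/255` is the smallest increment visible to an
#' 8-bit image consumer, guaranteeing foreground differs from background even
#' after quantization.
#'
#' @param normalized numeric matrix in `[0, 1]`, samples x features.
#' @param pmap a [PixelMap-class] for those features.
#' @param epsilon foreground offset in `[0, 1)`; values `>= 1` are errors.
#' @param segment logical: apply the foreground offset (modified pipeline) or
#'   not (original DeepInsight control arm).
#' @param aggregate collision aggregation, `"mean"` (default) or `"max"`.
#' @return an [ImageStack-class].
#' @export
renderImages <- function(normalized, pmap, epsilon = 1 / 255, segment = TRUE,
                         aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(methods::is(pmap, "PixelMap"))
  X <- as.matrix(normalized)
  if (nrow(X) < 1L) stop("empty stack: no samples to render", call. = FALSE)
  if (ncol(X) != nrow(pmap@pixels)) {
    stop("feature count does not match the pixel map", call. = FALSE)
  }
  if (anyNA(X) || any(X < -1e-12) || any(X > 1 + 1e-12)) {
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  }
  X <- .clamp(X, 0, 1)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon >= 1) {
    stop("epsilon must be a single value in [0, 1)", call. = FALSE)
  }
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(nrow(X)))
  groups <- pmap@groups
  # per-pixel aggregated value matrix: samples x foreground pixels
  if (aggregate == "mean") {
    grp <- integer(ncol(X))
    for (g in seq_along(groups)) grp[groups[[g]]] <- g
    sums <- rowsum(t(X), group = grp)     # rows in group-id order 1..G
    agg <- sweep(t(sums), 2L, lengths(groups), "/")
  } else {
    agg <- vapply(groups, function(ix) {
      apply(X[, ix, drop = FALSE], 1L, max)
    }, numeric(nrow(X)))
    if (nrow(X) == 1L) agg <- matrix(agg, nrow = 1L)
  }
  if (segment && epsilon > 0) agg <- pmax(agg, epsilon)
  n <- nrow(X); h <- pmap@gridH; w <- pmap@gridW
  arr <- array(0, dim = c(n, h, w),
               dimnames = list(rownames(X), NULL, NULL))
  keys <- do.call(rbind, strsplit(names(groups), ",", fixed = TRUE))
  prow <- as.integer(keys[, 1]); pcol <- as.integer(keys[, 2])
  for (g in seq_along(groups)) {
    arr[cbind(seq_len(n), prow[g] + 1L, pcol[g] + 1L)] <- agg[, g]
  }
  methods::new("ImageStack", images = arr, foregroundMask = pmap@foregroundMask,
               epsilon = if (segment) epsilon else 0,
               scheme = "unspecified")
}

#' Support mask of one sample image
#'
#' The set of strictly positive pixels of sample `sampleIndex`. With the
#' segmentation offset, every sample's support equals the foreground mask;
#' without it, zero-inflated samples have strictly smaller supports that vary
#' from sample to sample.
#'
#' @param stack an [ImageStack-class].
#' @param sampleIndex integer index into the stack.
#' @return a logical `H x W` matrix.
#' @export
supportMask <- function(stack, sampleIndex) {
  stopifnot(methods::is(stack, "ImageStack"))
  n <- dim(stack@images)[1L]
  if (sampleIndex < 1L || sampleIndex > n) {
    stop(sprintf("sample index %d out of range [1, %d]", sampleIndex, n),
         call. = FALSE)
  }
  stack@images[sampleIndex, , ] > 0
}
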