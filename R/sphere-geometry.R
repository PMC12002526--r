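#' @include AllClasses.R
NULL

# ---- general-point Log/Exp maps in ambient coordinates (internal) ----------
# Used by the Fréchet-mean iteration; the pole-specialised maps below are the
# exported, (d-1)-coordinate versions.

# theta/sin(theta), stable near 0 via its Taylor series
.thetaOverSin <- function(th) {
  f <- th / sin(th)
  small <- th < 1e-6
  if (any(small)) f[small] <- 1 + th[small]^2 / 6 + 7 * th[small]^4 / 360
  f
}

# rows of X mapped into T_p (ambient d-vectors orthogonal to p)
.logRowsAt <- function(p, X) {
  ct <- .clamp(as.vector(X %*% p), -1, 1)
  th <- acos(ct)
  if (any(th > pi - 1e-8)) stop("point antipodal to the base point", call. = FALSE)
  .thetaOverSin(th) * (X - outer(ct, p))
}

.expAt <- function(p, v) {
  r <- sqrt(sum(v^2))
  if (r < 1e-14) return(p)
  out <- cos(r) * p + (sin(r) / r) * v
  out / sqrt(sum(out^2))
}

# ---------------------------------------------------------------------------

#' Geodesic (great-circle) distance between unit vectors
#'
#' The length of the shortest path on the sphere between `u` and `v`:
#' `acos` of their inner product, clamped to `[-1, 1]` for numerical safety.
#'
#' @param u,v numeric unit vectors of equal length.
#' @return a nonnegative angle in `[0, pi]`, in radians.
#' @examples
#' geodesicDistance(c(1, 0, 0), c(0, 1, 0))  # pi/2
#' @export
geodesicDistance <- function(u, v) {
  stopifnot(length(u) == length(v))
  .assertUnit(u, 1e-8, "u"); .assertUnit(v, 1e-8, "v")
  acos(.clamp(sum(u * v), -1, 1))
}

#' Fréchet (intrinsic) mean on the sphere
#'
#' The point minimising the sum of squared geodesic distances to the data.
#' Computed by the standard fixed-point iteration: Log-map all points at the
#' current estimate, average the tangent vectors, Exp-map the average, and
#' repeat until the update step is below `tol`. The iteration is initialised
#' at the normalised extrinsic (Euclidean) mean; for data confined to one
#' open hemisphere — always the case for square-root-transformed
#' compositions, which live in the nonnegative orthant — the iteration
#' converges to the unique minimiser.
#'
#' @param x a [SpherePoints-class] object (or a numeric matrix of unit rows).
#' @param tol convergence tolerance on the norm of the mean tangent update
#'   (radians); default `1e-10`.
#' @param maxIter maximum number of iterations; default 200. Non-convergence
#'   raises an error carrying the last iterate and step norm.
#' @param ... unused.
#' @return a unit vector of length `d`.
#' @examples
#' p <- rbind(c(sin(0.3), 0, cos(0.3)), c(-sin(0.3), 0, cos(0.3)))
#' frechetMean(p)  # the pole, by symmetry
#' @describeIn frechetMean intrinsic mean of points on the sphere.
#' @export
setMethod("frechetMean", "SpherePoints", function(x, tol = 1e-10, maxIter = 200, ...) {
  .frechetMeanMatrix(values(x), tol = tol, maxIter = maxIter)
})

#' @describeIn frechetMean method for a plain matrix of unit rows.
#' @export
setMethod("frechetMean", "matrix", function(x, tol = 1e-10, maxIter = 200, ...) {
  .frechetMeanMatrix(x, tol = tol, maxIter = maxIter)
})

.frechetMeanMatrix <- function(X, tol = 1e-10, maxIter = 200) {
  stopifnot(nrow(X) >= 1L)
  dev <- abs(sqrt(rowSums(X^2)) - 1)
  if (any(dev > 1e-8)) stop("input rows must be unit vectors", call. = FALSE)
  if (nrow(X) == 1L) return(as.vector(X[1L, ]))
  mu <- colMeans(X)
  nm <- sqrt(sum(mu^2))
  if (nm < 1e-12) stop("degenerate configuration: extrinsic mean is zero", call. = FALSE)
  mu <- mu / nm
  for (it in seq_len(maxIter)) {
    v <- colMeans(.logRowsAt(mu, X))
    stepNorm <- sqrt(sum(v^2))
    if (stepNorm < tol) return(mu)
    mu <- .expAt(mu, v)
  }
  cond <- simpleError(sprintf(
    "Fréchet mean did not converge in %d iterations (last step norm %.3g)",
    maxIter, stepNorm))
  cond$lastIterate <- mu
  cond$stepNorm <- stepNorm
  stop(cond)
}

#' Rotation sending a unit vector to the pole
#'
#' Returns the `d x d` special orthogonal matrix that rotates `mu` onto the
#' pole `(0, ..., 0, 1)` within the plane spanned by `mu` and the pole, and
#' acts as the identity on the orthogonal complement of that plane. This is
#' the reference-point alignment applied before the pole Log map.
#'
#' For large `d`, prefer the factored application used internally by
#' [tangentProjection()]; this function materialises the dense matrix.
#'
#' @param mu unit vector; must not be antipodal to the pole (the rotation
#'   plane would be undefined — impossible for nonnegative-orthant data).
#' @return an orthogonal matrix `R` with `R %*% mu` equal to the pole and
#'   `det(R) = 1`.
#' @export
rotationToPole <- function(mu) {
  .assertUnit(mu, 1e-8, "mu")
  d <- length(mu)
  ct <- mu[d]                               # <mu, pole>
  if (ct < -1 + 1e-12) {
    stop("mu is antipodal to the pole: rotation plane undefined", call. = FALSE)
  }
  R <- diag(d)
  if (ct > 1 - 1e-15) return(R)             # already at the pole
  pole <- c(rep(0, d - 1L), 1)
  v <- pole - ct * mu
  st <- sqrt(sum(v^2))                      # sin(theta)
  vh <- v / st
  R + st * (outer(vh, mu) - outer(mu, vh)) +
    (ct - 1) * (outer(mu, mu) + outer(vh, vh))
}

# apply the pole rotation for base point mu to rows of X without forming R:
# R x = x + (x.mu)(s*vh + (c-1)mu) + (x.vh)((c-1)vh - s*mu),  O(n d)
.applyPoleRotationRows <- function(mu, X) {
  d <- length(mu)
  ct <- mu[d]
  if (ct < -1 + 1e-12) stop("mu is antipodal to the pole", call. = FALSE)
  if (ct > 1 - 1e-15) return(X)
  pole <- c(rep(0, d - 1L), 1)
  v <- pole - ct * mu
  st <- sqrt(sum(v^2))
  vh <- v / st
  a1 <- as.vector(X %*% mu)
  a2 <- as.vector(X %*% vh)
  X + outer(a1, st * vh + (ct - 1) * mu) + outer(a2, (ct - 1) * vh - st * mu)
}

#' Log map at the pole
#'
#' Flattens a sphere point into the tangent space at the pole
#' `p = (0, ..., 0, 1)`:
#' `Log_p(x) = (theta / sin(theta)) * (x_1, ..., x_{d-1})` with
#' `theta = acos(x_d)`. The output has `d - 1` coordinates and norm equal to
#' the geodesic distance from the pole. At `theta = 0` the `0/0` limit is
#' taken by a series branch (`theta/sin(theta) -> 1`).
#'
#' @param x unit vector of length `d`, not antipodal to the pole.
#' @return numeric vector of length `d - 1`.
#' @examples
#' logMapPole(c(sin(0.4), 0, cos(0.4)))  # (0.4, 0)
#' @export
logMapPole <- function(x) {
  .assertUnit(x, 1e-8, "x")
  d <- length(x)
  head <- x[-d]
  # theta = acos(x_d), computed as atan2(|head|, x_d): identical in exact
  # arithmetic (|head| = sin(theta) for unit x) but well conditioned at the
  # pole, where acos loses ~sqrt(eps) accuracy
  sn <- sqrt(sum(head^2))
  th <- atan2(sn, x[d])
  if (th > pi - 1e-8) stop("x is antipodal to the pole", call. = FALSE)
  if (sn < 1e-12) return(rep(0, d - 1L))
  as.vector((th / sn) * head)
}

# vectorised pole Log map over rows; returns list(tangent, theta)
.logMapPoleRows <- function(X) {
  d <- ncol(X)
  head <- X[, -d, drop = FALSE]
  sn <- sqrt(rowSums(head^2))
  th <- atan2(sn, X[, d])
  if (any(th > pi - 1e-8)) stop("a point is antipodal to the pole", call. = FALSE)
  f <- ifelse(sn < 1e-12, 0, th / sn)   # head is ~0 wherever sn ~ 0
  list(tangent = f * head, theta = ifelse(sn < 1e-12, 0, th))
}

#' Exp map at the pole
#'
#' Inverse of [logMapPole()]: wraps a tangent vector `v` (length `d - 1`,
#' norm `r < pi`) back onto the sphere as
#' `(sin(r)/r * v, cos(r))`, with the series branch at `r = 0`.
#'
#' @param v numeric tangent vector with `norm(v) < pi`.
#' @return a unit vector of length `length(v) + 1`.
#' @examples
#' expMapPole(c(pi / 2, 0))  # (1, 0, 0)
#' @export
expMapPole <- function(v) {
  r <- sqrt(sum(v^2))
  if (r >= pi) stop("tangent vector norm must be < pi", call. = FALSE)
  if (r < 1e-6) {
    sc <- 1 - r^2 / 6 + r^4 / 120          # sin(r)/r
  } else {
    sc <- sin(r) / r
  }
  out <- c(sc * v, cos(r))
  out / sqrt(sum(out^2))
}

#' Project sphere points to the tangent space at their Fréchet mean
#'
#' Fits the whole tangent frame: computes the Fréchet mean of the points,
#' rotates the mean to the pole (applying the same rotation to every sample)
#' and applies the pole Log map row-wise. Per-sample geodesic distances from
#' the mean are recorded as `sampleAngles()`.
#'
#' The rotation is applied in factored rank-2 form, so the cost is
#' `O(n d)` and no `d x d` matrix is formed.
#'
#' @param points a [SpherePoints-class].
#' @param tol,maxIter passed to [frechetMean()].
#' @return a [TangentCoordinates-class] with `n x (d-1)` coordinates.
#' @seealso [projectPoints()] to reuse a fitted frame on new samples.
#' @export
tangentProjection <- function(points, tol = 1e-10, maxIter = 200) {
  stopifnot(methods::is(points, "SpherePoints"))
  X <- values(points)
  mu <- .frechetMeanMatrix(X, tol = tol, maxIter = maxIter)
  Y <- .applyPoleRotationRows(mu, X)
  lm <- .logMapPoleRows(Y)
  tang <- lm$tangent
  rownames(tang) <- rownames(X)
  colnames(tang) <- paste0("t", seq_len(ncol(tang)))
  methods::new("TangentCoordinates", values = tang, mu = mu, theta = lm$theta)
}

#' @describeIn projectPoints rotate and Log-map new sphere points with the
#'   frame (Fréchet mean + rotation) stored in a fitted projection. Used to
#'   map held-out samples with training-fold geometry only.
#' @export
setMethod("projectPoints", "TangentCoordinates", function(x, points, ...) {
  P <- if (methods::is(points, "SpherePoints")) values(points) else as.matrix(points)
  if (ncol(P) != length(x@mu)) stop("dimension mismatch with the fitted frame", call. = FALSE)
  Y <- .applyPoleRotationRows(x@mu, P)
  tang <- .logMapPoleRows(Y)$tangent
  rownames(tang) <- rownames(P)
  colnames(tang) <- paste0("t", seq_len(ncol(tang)))
  tang
})

#' Principal geodesic analysis (PCA in the tangent space)
#'
#' Centered PCA of the tangent coordinates by singular value decomposition.
#' With `k = "all"` (the default) no truncation is applied and all
#' `min(n - 1, d - 1)` components are retained; truncation is an option, not
#' the default, because the image-generation step consumes the full tangent
#' representation.
#'
#' @param tan a [TangentCoordinates-class].
#' @param k number of components, or `"all"`.
#' @return a [PGAResult-class].
#' @export
pga <- function(tan, k = "all") {
  stopifnot(methods::is(tan, "TangentCoordinates"))
  X <- values(tan)
  n <- nrow(X)
  if (n < 2L) stop("pga needs at least two samples", call. = FALSE)
  kmax <- min(n - 1L, ncol(X))
  if (identical(k, "all")) k <- kmax
  k <- as.integer(k)
  if (k < 1L || k > kmax) stop(sprintf("k must lie in [1, %d]", kmax), call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = k, nv = k)
  sc <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(sc) <- rownames(X)
  colnames(sc) <- paste0("PG", seq_len(k))
  load <- sv$v
  rownames(load) <- colnames(X)
  colnames(load) <- colnames(sc)
  methods::new("PGAResult", scores = sc, loadings = load,
               variances = sv$d[seq_len(k)]^2 / (n - 1L), k = k)
}
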