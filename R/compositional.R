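#' @include AllClasses.R
NULL

#' Close a count table to the simplex
#'
#' Divides every sample's counts by its total, producing relative abundances
#' that sum to one. Exact zeros are preserved exactly: no pseudocount and no
#' zero replacement is applied anywhere in this package — avoiding the
#' distortions of replacement is the point of the square-root route.
#'
#' @param table a [CountTable-class].
#' @return a [CompositionTable-class] with the same identifiers and order.
#' @examples
#' ct <- CountTable(matrix(c(2, 0, 3, 0, 5, 4), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' values(closure(ct))
#' @export
closure <- function(table) {
  stopifnot(methods::is(table, "CountTable"))
  x <- counts(table)
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop(sprintf("cannot close sample '%s': all counts are zero",
                 rownames(x)[which(rs <= 0)[1L]]), call. = FALSE)
  }
  methods::new("CompositionTable", values = x / rs)
}

#' Square-root transform: simplex to unit hypersphere
#'
#' Maps each composition elementwise to its square root. Because the parts
#' sum to one, the image has unit Euclidean norm, i.e. lies on the
#' nonnegative orthant of the unit hypersphere. Unlike log-ratio transforms
#' the map is defined at the boundary: exact zeros map to exact zeros.
#'
#' @param comp a [CompositionTable-class].
#' @return a [SpherePoints-class] with the same identifiers.
#' @examples
#' ct <- CountTable(matrix(c(1, 1, 2), 1, 3,
#'   dimnames = list("s1", c("a", "b", "c"))))
#' values(sqrtTransform(closure(ct)))  # rows have unit norm
#' @export
sqrtTransform <- function(comp) {
  stopifnot(methods::is(comp, "CompositionTable"))
  x <- values(comp)
  if (any(x < 0)) stop("negative composition entry", call. = FALSE)
  methods::new("SpherePoints", values = sqrt(x))
}

#' Boolean mask of exact zeros
#'
#' TRUE wherever the original count is exactly zero. Used to reason about
#' "true zeros" (zero-valued features on the image foreground) as opposed to
#' background pixels that correspond to no feature at all.
#'
#' @param table a [CountTable-class].
#' @return a logical matrix of the same shape and dimnames.
#' @export
zeroMask <- function(table) {
  stopifnot(methods::is(table, "CountTable"))
  counts(table) == 0
}
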