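test_that("geodesic distance behaves on constructed configurations", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); pole <- c(0, 0, 1)
  expect_equal(geodesicDistance(e1, e1), 0)
  expect_equal(geodesicDistance(e1, e2), pi / 2)
  expect_equal(geodesicDistance(pole, c(sin(0.3), 0, cos(0.3))), 0.3,
               tolerance = 1e-12)
  expect_error(geodesicDistance(c(1, 1, 0), e1), "unit norm")
})

test_that("Frechet mean: fixed point, symmetry, and grid-search oracle", {
  x <- c(0.6, 0.8, 0)
  expect_equal(frechetMean(matrix(x, 1, dimnames = list("a", NULL))), x)

  sym <- rbind(c(sin(0.4), 0, cos(0.4)), c(-sin(0.4), 0, cos(0.4)))
  expect_equal(frechetMean(sym), c(0, 0, 1), tolerance = 1e-9)

  # three points on the 2-sphere vs dense spherical grid search (0.002 rad)
  P <- values(randomSpherePoints(3, 3, seed = 21))
  mu <- frechetMean(P)
  muGrid <- gridSearchFrechetMean(P, resolution = 0.002)
  expect_lt(geodesicDistance(mu, muGrid / sqrt(sum(muGrid^2))), 0.005)
})

test_that("Frechet mean satisfies the first-order condition at tol", {
  sp <- randomSpherePoints(50, 10, seed = 5, conc = 0.7)
  mu <- frechetMean(sp, tol = 1e-10)
  V <- sphereInsight:::.logRowsAt(mu, values(sp))
  expect_lt(sqrt(sum(colMeans(V)^2)), 1e-10)
})

test_that("non-convergence error carries the last iterate", {
  sp <- randomSpherePoints(20, 5, seed = 2)
  err <- tryCatch(frechetMean(sp, tol = 1e-16, maxIter = 2), error = identity)
  expect_s3_class(err, "error")
  expect_true(is.numeric(err$lastIterate) && length(err$lastIterate) == 5)
  expect_true(is.finite(err$stepNorm))
})

test_that("rotation to the pole maps mu to the pole and is an isometry", {
  expect_equal(rotationToPole(c(0, 0, 1)), diag(3))
  expect_equal(rotationToPole(c(1, 0)) %*% c(1, 0), cbind(c(0, 1)),
               tolerance = 1e-14)
  expect_error(rotationToPole(c(0, 0, -1)), "antipodal")

  for (s in 1:100) {
    d <- 3 + (s %% 5)
    u <- randomUnitRows(3, d, seed = 300 + s)
    R <- rotationToPole(u[1, ])
    expect_lt(max(abs(crossprod(R) - diag(d))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_lt(max(abs(R %*% u[1, ] - c(rep(0, d - 1), 1))), 1e-10)
    expect_lt(abs(sum((R %*% u[2, ]) * (R %*% u[3, ])) - sum(u[2, ] * u[3, ])),
              1e-10)
  }
})

test_that("pole Log map matches the spec cases and the general formula", {
  d <- 6
  pole <- c(rep(0, d - 1), 1)
  expect_equal(logMapPole(pole), rep(0, d - 1))
  expect_equal(logMapPole(c(sin(0.4), 0, cos(0.4))), c(0.4, 0), tolerance = 1e-14)
  expect_error(logMapPole(c(0, 0, -1)), "antipodal")

  X <- randomUnitRows(200, d, seed = 31)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    th <- acos(max(-1, min(1, x[d])))
    general <- if (th < 1e-12) rep(0, d - 1) else
      ((th / sin(th)) * (x - cos(th) * pole))[seq_len(d - 1)]
    expect_equal(logMapPole(x), general, tolerance = 1e-12)
  }
})

test_that("Exp map inverts the Log map and hits the quarter great circle", {
  expect_equal(expMapPole(c(0, 0)), c(0, 0, 1))
  expect_equal(expMapPole(c(pi / 2, 0)), c(1, 0, 0), tolerance = 1e-14)
  expect_error(expMapPole(c(pi, 0.1)), "< pi")

  X <- randomUnitRows(1000, 5, seed = 77)
  worst <- 0
  for (i in seq_len(nrow(X))) {
    err <- max(abs(expMapPole(logMapPole(X[i, ])) - X[i, ]))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-10)
})

test_that("Log map norm equals geodesic distance from the pole", {
  X <- randomUnitRows(300, 8, seed = 13)
  pole <- c(rep(0, 7), 1)
  for (i in seq_len(nrow(X))) {
    expect_equal(sqrt(sum(logMapPole(X[i, ])^2)),
                 geodesicDistance(pole, X[i, ]), tolerance = 1e-12)
  }
})

test_that("tangent projection records a consistent frame", {
  sp <- randomSpherePoints(40, 12, seed = 9, conc = 0.8)
  tc <- tangentProjection(sp)
  mu <- frechetMean(tc)
  expect_equal(sqrt(sum(mu^2)), 1, tolerance = 1e-12)
  R <- rotation(tc)
  expect_lt(max(abs(crossprod(R) - diag(12))), 1e-10)
  expect_lt(max(abs(R %*% mu - c(rep(0, 11), 1))), 1e-10)
  # row norms equal geodesic distances to the mean
  d <- vapply(seq_len(40), function(i) geodesicDistance(mu, values(sp)[i, ]),
              numeric(1))
  expect_equal(unname(sqrt(rowSums(values(tc)^2))), d, tolerance = 1e-10)
  # the mean itself maps to the zero tangent vector
  expect_lt(max(abs(projectPoints(tc, matrix(mu, 1,
                                             dimnames = list("mu", NULL))))),
            1e-10)
})

test_that("rotation applied in factored form matches the dense matrix", {
  sp <- randomSpherePoints(15, 9, seed = 41)
  mu <- frechetMean(sp)
  dense <- values(sp) %*% t(rotationToPole(mu))
  fact <- sphereInsight:::.applyPoleRotationRows(mu, values(sp))
  expect_equal(fact, dense, tolerance = 1e-12)
})

test_that("tangent coordinates approach flat geometry for tight clusters", {
  # cluster with max angle < 0.05: pairwise tangent distances track geodesics
  base <- c(0.3, 0.5, sqrt(1 - 0.09 - 0.25))
  withr::with_seed(17, {
    pert <- matrix(stats::rnorm(20 * 3, sd = 0.01), 20, 3)
  })
  P <- t(apply(pert, 1, function(e) { v <- base + e; v / sqrt(sum(v^2)) }))
  dimnames(P) <- list(paste0("s", 1:20), paste0("t", 1:3))
  sp <- methods::new("SpherePoints", values = P)
  tc <- tangentProjection(sp)
  euclid <- as.matrix(dist(values(tc)))
  geo <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) geo[i, j] <- geodesicDistance(P[i, ], P[j, ])
  off <- upper.tri(geo)
  expect_lt(max(abs(euclid[off] - geo[off]) / pmax(geo[off], 1e-12)), 1e-3)
})

test_that("small-angle samples reduce to their leading coordinates", {
  # points within 1e-3 of the pole: tangent row ~ first d-1 coordinates, O(theta^3)
  withr::with_seed(23, {
    v <- matrix(stats::rnorm(10 * 3, sd = 3e-4), 10, 3)
  })
  P <- t(apply(v, 1, function(t3) expMapPole(t3)))
  dimnames(P) <- list(paste0("s", 1:10), paste0("t", 1:4))
  lm <- sphereInsight:::.logMapPoleRows(P)
  expect_lt(max(abs(lm$tangent - P[, 1:3])), 1e-9)
})

test_that("pga is an exact centered SVD decomposition of tangent variance", {
  sp <- randomSpherePoints(30, 10, seed = 6, conc = 0.6)
  tc <- tangentProjection(sp)
  res <- pga(tc, k = "all")
  expect_lte(res@k, min(29, 9))
  expect_lt(max(abs(crossprod(loadings(res)) - diag(res@k))), 1e-10)
  expect_false(is.unsorted(rev(variances(res))))
  totalVar <- sum(apply(values(tc), 2, stats::var))
  expect_equal(sum(variances(res)), totalVar, tolerance = 1e-10)
  expect_error(pga(tangentProjection(randomSpherePoints(1, 5, seed = 1))),
               "at least two")
})

test_that("pga collapses rank-1 tangent data onto a single component", {
  withr::with_seed(44, {
    t1 <- stats::runif(25, -0.2, 0.2)
  })
  p <- rep(0.5, 4)                       # interior orthant base point
  w <- c(1, -1, 1, -1) / 2               # unit tangent direction at p
  P <- t(vapply(t1, function(s) sphereInsight:::.expAt(p, s * w), numeric(4)))
  dimnames(P) <- list(paste0("s", 1:25), paste0("t", 1:4))
  tc <- tangentProjection(methods::new("SpherePoints", values = P))
  res <- pga(tc, k = "all")
  expect_lt(variances(res)[2] / variances(res)[1], 1e-12)
})
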