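# Fixtures are generated in code; nothing is read from disk.

options(sphereInsight.verbose = FALSE)

tinyCountTable <- function() {
  CountTable(matrix(c(2, 0, 3, 0, 5, 4), 2, 3,
                    dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
}

# random points on the nonnegative orthant of the sphere (Dirichlet + sqrt)
randomSpherePoints <- function(n, d, seed = 1, conc = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n * d, shape = conc), n, d)
  })
  p <- g / rowSums(g)
  dimnames(p) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(d)))
  methods::new("SpherePoints", values = sqrt(p))
}

# random unit vectors anywhere on the sphere except near the antipode of the pole
randomUnitRows <- function(n, d, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
  })
  x <- x / sqrt(rowSums(x^2))
  flip <- x[, d] < -0.95
  x[flip, ] <- -x[flip, , drop = FALSE]
  x
}

# class-mean-difference linear probe AUC on a train/test split
linearProbeAuc <- function(X, y, seed = 1, trainFrac = 0.7) {
  n <- nrow(X)
  idx <- withr::with_seed(seed, sample(n))
  tr <- idx[seq_len(round(trainFrac * n))]
  te <- setdiff(idx, tr)
  w <- colMeans(X[tr[y[tr] == 1], , drop = FALSE]) -
       colMeans(X[tr[y[tr] == 0], , drop = FALSE])
  computeAUC(as.vector(X[te, , drop = FALSE] %*% w), y[te])
}

# brute-force Frechet mean on the 2-sphere by dense spherical grid search
gridSearchFrechetMean <- function(P, resolution = 0.002) {
  th <- seq(0, pi / 2, by = resolution)
  ph <- seq(0, pi / 2, by = resolution)
  g <- expand.grid(th = th, ph = ph)
  C <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  D <- acos(pmin(pmax(C %*% t(P), -1), 1))
  C[which.min(rowSums(D^2)), ]
}

# minimum rectangle area over an even sweep of candidate angles
sweepMinRectArea <- function(P, nAngles = 3600) {
  angles <- seq(0, pi / 2, length.out = nAngles)
  best <- Inf
  for (a in angles) {
    xr <- P[, 1] * cos(-a) - P[, 2] * sin(-a)
    yr <- P[, 1] * sin(-a) + P[, 2] * cos(-a)
    area <- diff(range(xr)) * diff(range(yr))
    if (area < best) best <- area
  }
  best
}

# a tiny layout + pixel map for rendering tests: includes an all-zero sample
segmentationFixture <- function(nFeat = 30, nSamp = 8, grid = 8, seed = 5) {
  withr::with_seed(seed, {
    coords <- matrix(stats::runif(nFeat * 2), nFeat, 2,
                     dimnames = list(paste0("f", seq_len(nFeat)), c("x", "y")))
    vals <- matrix(stats::runif(nSamp * nFeat), nSamp, nFeat,
                   dimnames = list(paste0("s", seq_len(nSamp)), rownames(coords)))
  })
  vals[1, ] <- 0                        # an all-zero-feature sample
  vals[2, seq_len(nFeat %/% 2)] <- 0    # a partially zero sample
  rect <- minAreaRectangle(coords)
  pmap <- pixelAssignment(coords, rect$angle, grid, grid)
  list(coords = coords, values = vals, pmap = pmap)
}

# fast training configuration for pipeline-level tests
fastTrain <- function(seed = 1) {
  trainConfig(epochs = 10L, batchSize = 16L, seed = seed)
}
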