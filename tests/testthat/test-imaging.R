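test_that("PCA layout recovers planar feature geometry up to rigid motion", {
  # features constructed to lie on a 2-D affine plane in sample space
  withr::with_seed(55, {
    A <- matrix(stats::rnorm(40 * 2), 40, 2)           # feature plane coords
    B <- matrix(stats::rnorm(2 * 12), 2, 12)           # plane basis
    offset <- stats::rnorm(12)
  })
  G <- A %*% B + matrix(offset, 40, 12, byrow = TRUE)  # features x samples
  lay <- featureLayout(t(G), method = "pca", seed = 1)
  expect_equal(unname(as.matrix(dist(values(lay)))),
               unname(as.matrix(dist(G))), tolerance = 1e-8)
})

test_that("layouts are deterministic per seed for every method", {
  withr::with_seed(66, {
    X <- matrix(stats::rnorm(20 * 40), 20, 40)
  })
  for (m in c("pca", "kpca", "tsne")) {
    l1 <- featureLayout(X, method = m, seed = 7,
                        params = list(maxIter = 60L))
    l2 <- featureLayout(X, method = m, seed = 7,
                        params = list(maxIter = 60L))
    expect_identical(values(l1), values(l2))
  }
})

test_that("degenerate layouts are rejected", {
  expect_error(featureLayout(matrix(1:4, 2, 2), method = "pca"),
               "at least 3 features")
  expect_error(featureLayout(matrix(1, 5, 6), method = "pca"), "degenerate")
})

test_that("minimum-area rectangle handles squares, rotation and collinearity", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- minAreaRectangle(sq)
  expect_equal(r$area, 1, tolerance = 1e-12)
  expect_equal(r$angle %% (pi / 2), 0, tolerance = 1e-12)

  ang <- 30 * pi / 180
  Rm <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  r30 <- minAreaRectangle(sq %*% t(Rm))
  expect_equal(r30$area, 1, tolerance = 1e-10)
  expect_equal(r30$angle %% (pi / 2), ang, tolerance = 1e-10)

  seg <- cbind(seq(0, 1, length.out = 5), seq(0, 2, length.out = 5))
  rc <- minAreaRectangle(seg)
  expect_true(rc$collinear)
  expect_equal(rc$area, 0)
})

test_that("rotating calipers matches a 3600-angle sweep on random instances", {
  for (s in 1:20) {
    withr::with_seed(700 + s, {
      P <- matrix(stats::rnorm(50 * 2), 50, 2)
    })
    r <- minAreaRectangle(P)
    oracle <- sweepMinRectArea(P, nAngles = 3600)
    expect_lte(r$area, oracle * 1.001)
  }
})

test_that("pixel assignment maps rectangle corners to grid corners", {
  corners <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  rownames(corners) <- paste0("f", 1:4)
  pm <- pixelAssignment(corners, angle = 0, gridH = 10, gridW = 10)
  got <- pixelCoords(pm)
  expect_setequal(sprintf("%d,%d", got[, 1], got[, 2]),
                  c("9,0", "9,9", "0,9", "0,0"))
})

test_that("coincident features share a pixel in one collision group", {
  coords <- rbind(a = c(0, 0), b = c(1, 1), c = c(1, 1), d = c(0.5, 0.2))
  pm <- pixelAssignment(coords, angle = 0, gridH = 8, gridW = 8)
  groups <- collisionGroups(pm)
  sizes <- sort(lengths(groups), decreasing = TRUE)
  expect_identical(unname(sizes[1]), 2L)
  expect_identical(sort(unlist(groups, use.names = FALSE)), 1:4)
  expect_error(pixelAssignment(coords, 0, gridH = 1, gridW = 8), ">= 2")
})

test_that("foreground pixel count never exceeds the feature count", {
  for (s in 1:10) {
    withr::with_seed(900 + s, {
      P <- matrix(stats::runif(35 * 2), 35, 2)
    })
    pm <- pixelAssignment(P, angle = 0, gridH = 6, gridW = 6)
    expect_lte(sum(foregroundMask(pm)), 35)
    expect_identical(sum(foregroundMask(pm)), length(collisionGroups(pm)))
  }
})

test_that("independent normalization uses per-feature training statistics", {
  M <- rbind(train1 = c(2, 5, 1), train2 = c(6, 5, 3), test = c(4, 9, -1))
  norm <- normalizeValues(M, "independent", trainIdx = 1:2)
  expect_equal(unname(norm["test", 1]), 0.5)      # (4-2)/(6-2)
  expect_equal(unname(norm[, 2]), c(0, 0, 0))     # constant feature -> 0
  expect_equal(unname(norm["test", 3]), 0)        # clipped below
  expect_equal(unname(norm["train2", ]), c(1, 0, 1))
  expect_error(normalizeValues(M, "independent", trainIdx = integer(0)),
               "empty training")
})

test_that("topology-preserving normalization preserves cross-cell ordering", {
  for (s in 1:5) {
    withr::with_seed(40 + s, {
      M <- matrix(stats::rnorm(8 * 6, sd = 3), 8, 6)
    })
    norm <- normalizeValues(M, "topology_preserving")
    o1 <- order(as.vector(M))
    expect_true(all(diff(as.vector(norm)[o1]) >= 0))
    expect_true(all(norm >= 0 & norm <= 1))
  }
  # out-of-range test rows clip to [0, 1]
  M <- rbind(a = c(0, 1), b = c(0.5, 0.2), test = c(-5, 9))
  norm <- normalizeValues(M, "topology_preserving", trainIdx = 1:2)
  expect_equal(unname(norm["test", ]), c(0, 1))
})

test_that("collision values aggregate by arithmetic mean before the offset", {
  coords <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  pm <- pixelAssignment(coords, 0, 4, 4)
  vals <- matrix(c(0.2, 0.6, 1), 1, 3, dimnames = list("s1", rownames(coords)))
  st <- renderImages(vals, pm, segment = FALSE)
  im <- images(st)[1, , ]
  expect_true(any(abs(im - 0.4) < 1e-12))
})

test_that("the segmentation offset standardizes supports; omitting it does not", {
  fix <- segmentationFixture()
  seg <- renderImages(fix$values, fix$pmap, epsilon = 1 / 255, segment = TRUE)
  raw <- renderImages(fix$values, fix$pmap, epsilon = 1 / 255, segment = FALSE)

  n <- nrow(fix$values)
  supportsSeg <- unique(lapply(seq_len(n), function(i) supportMask(seg, i)))
  expect_length(supportsSeg, 1L)
  expect_identical(supportsSeg[[1]], foregroundMask(fix$pmap))

  supportsRaw <- unique(lapply(seq_len(n), function(i) supportMask(raw, i)))
  expect_gte(length(supportsRaw), 2L)
  # the all-zero sample's raw image is indistinguishable from background
  expect_identical(unname(images(raw)[1, , ]),
                   matrix(0, nrow(foregroundMask(fix$pmap)),
                          ncol(foregroundMask(fix$pmap))))
  # raw supports are contained in the foreground
  for (s in supportsRaw) expect_true(all(!s | foregroundMask(fix$pmap)))

  # every foreground pixel of every segmented image is at least epsilon
  fg <- foregroundMask(fix$pmap)
  expect_true(all(apply(images(seg), 1, function(im) all(im[fg] >= 1 / 255))))
  # and an all-zero sample renders as constant epsilon on the foreground
  expect_true(all(abs(images(seg)[1, , ][fg] - 1 / 255) < 1e-15))
})

test_that("epsilon outside [0, 1) and out-of-range values are rejected", {
  fix <- segmentationFixture()
  expect_error(renderImages(fix$values, fix$pmap, epsilon = 1), "epsilon")
  expect_error(renderImages(fix$values, fix$pmap, epsilon = -0.1), "epsilon")
  bad <- fix$values; bad[3, 1] <- 1.5
  expect_error(renderImages(bad, fix$pmap), "\\[0, 1\\]")
  expect_error(supportMask(renderImages(fix$values, fix$pmap), 99),
               "out of range")
})

test_that("rendering is bit-deterministic and train/test hygienic", {
  withr::with_seed(12, {
    X <- matrix(stats::runif(30 * 25), 30, 25)
  })
  run <- function(M) {
    lay <- featureLayout(M[1:20, ], method = "pca", seed = 3)
    rect <- minAreaRectangle(lay)
    pm <- pixelAssignment(lay, rect$angle, 12, 12)
    norm <- normalizeValues(M, "independent", trainIdx = 1:20)
    renderImages(norm, pm)
  }
  s1 <- run(X); s2 <- run(X)
  expect_identical(images(s1), images(s2))
  # perturbing test rows must leave the training-fitted layout and the
  # training rows' rendered images unchanged
  Y <- X
  withr::with_seed(99, {
    Y[21:30, ] <- matrix(stats::runif(10 * 25), 10, 25)
  })
  s3 <- run(Y)
  expect_identical(images(s1)[1:20, , ], images(s3)[1:20, , ])
})
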