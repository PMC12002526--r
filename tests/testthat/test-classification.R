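test_that("pair-counting AUC matches enumeration, extremes and tie handling", {
  expect_identical(computeAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_identical(computeAUC(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_identical(computeAUC(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(computeAUC(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    y <- rbinom(60, 1, 0.4)
    s <- stats::rnorm(60) + y
  })
  expect_equal(computeAUC(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing transforms", {
  for (i in 1:100) {
    withr::with_seed(1000 + i, {
      s <- stats::rnorm(30)
      y <- rbinom(30, 1, 0.5)
    })
    if (length(unique(y)) < 2) next
    a <- computeAUC(s, y)
    expect_equal(computeAUC(exp(2 * s) + 1, y), a, tolerance = 1e-12)
    expect_equal(computeAUC(rank(s), y), a, tolerance = 1e-12)
  }
})

test_that("AUC of negated scores complements to one without ties", {
  withr::with_seed(5, {
    s <- stats::rnorm(40)
    y <- rep(c(0, 1), 20)
  })
  expect_equal(computeAUC(s, y) + computeAUC(-s, y), 1, tolerance = 1e-12)
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(0, 1), each = 5)
  f <- stratifiedFolds(y, k = 5, seed = 2)
  expect_length(f, 5)
  expect_identical(sort(unlist(f)), 1:10)
  for (fold in f) expect_identical(as.integer(table(y[fold])), c(1L, 1L))
  expect_identical(f, stratifiedFolds(y, k = 5, seed = 2))
  expect_false(identical(f, stratifiedFolds(y, k = 5, seed = 3)))

  yib <- c(rep(0, 30), rep(1, 12))
  fib <- stratifiedFolds(yib, k = 4, seed = 1)
  props <- vapply(fib, function(ix) sum(yib[ix]), numeric(1))
  expect_true(all(props == 3))
  expect_error(stratifiedFolds(y, k = 1), "at least 2")
  expect_error(stratifiedFolds(y, k = 6), "minority")
})

test_that("log-uniform search draws evenly across magnitudes", {
  rs <- randomSearch(function(lr, wd) 0, nTrials = 10000, seed = 8)
  # the search's lr draws, binned on log10 into 8 bins, are uniform
  lg <- log10(rs$trials$learningRate)
  expect_true(all(lg >= -6 & lg <= -2))
  counts <- table(cut(lg, breaks = seq(-6, -2, length.out = 9)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("random search finds the optimum of a known objective", {
  rs <- randomSearch(function(lr, wd) -(log10(lr) + 4)^2, nTrials = 400, seed = 4)
  expect_lt(abs(log10(rs$best$learningRate) + 4), 0.2)
  one <- randomSearch(function(lr, wd) 1, nTrials = 1, seed = 9)
  expect_identical(nrow(one$trials), 1L)
  expect_identical(one$best$learningRate, one$trials$learningRate[1])
})

test_that("failed trials are logged and skipped, not fatal", {
  obj <- function(lr, wd) if (lr > 1e-4) stop("boom") else log10(lr)
  rs <- randomSearch(obj, nTrials = 50, seed = 6)
  expect_true(any(rs$trials$failed))
  expect_true(any(!rs$trials$failed))
  expect_lte(rs$best$learningRate, 1e-4)
})

test_that("training configuration enforces the canonical search ranges", {
  expect_error(trainConfig(learningRate = 0.5), "1e-6, 1e-2")
  expect_error(trainConfig(weightDecay = 1e-6), "1e-6, 1e-2")
  expect_error(trainConfig(epochs = 0), "positive")
  cfg <- trainConfig()
  expect_identical(cfg$architecture, "small_cnn")
})

test_that("the requested but unavailable deep architecture errors clearly", {
  cfg <- trainConfig(architecture = "resnet50")
  X <- array(stats::runif(4 * 16 * 16), c(4, 16, 16))
  expect_error(trainCNN(X, c(0, 1, 0, 1), cfg), "not available")
})

test_that("CNN backprop gradients match numerical differentiation", {
  withr::with_seed(77, {
    X <- array(stats::runif(6 * 12 * 12), c(6, 12, 12))
    y <- rep(c(0, 1), 3)
  })
  params <- sphereInsight:::.cnnInit(12, 12, filters = c(3L, 4L),
                                     head = "flatten", seed = 2)
  pass <- sphereInsight:::.cnnPass(params, X, y, grad = TRUE)
  h <- 1e-5
  for (nm in c("W1", "b1", "W2", "b2", "w3", "b3")) {
    idx <- withr::with_seed(match(nm, c("W1", "b1", "W2", "b2", "w3", "b3")),
                            sample(length(params[[nm]]), min(4, length(params[[nm]]))))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (sphereInsight:::.cnnPass(pp, X, y)$loss -
              sphereInsight:::.cnnPass(pm, X, y)$loss) / (2 * h)
      expect_equal(pass$grads[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("CNN gradients also check out with the global-pooling head", {
  withr::with_seed(78, {
    X <- array(stats::runif(4 * 12 * 12), c(4, 12, 12))
    y <- c(0, 1, 1, 0)
  })
  params <- sphereInsight:::.cnnInit(12, 12, filters = c(2L, 3L),
                                     head = "gap", seed = 3)
  pass <- sphereInsight:::.cnnPass(params, X, y, grad = TRUE)
  h <- 1e-5
  for (nm in c("W1", "W2", "w3")) {
    for (i in c(1L, length(params[[nm]]))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (sphereInsight:::.cnnPass(pp, X, y)$loss -
              sphereInsight:::.cnnPass(pm, X, y)$loss) / (2 * h)
      expect_equal(pass$grads[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("the small CNN learns a linearly separable image problem", {
  # class 1 lights up a fixed pixel block; class 0 a different one
  withr::with_seed(21, {
    n <- 60
    y <- rep(c(0, 1), n / 2)
    X <- array(stats::runif(n * 16 * 16, 0, 0.2), c(n, 16, 16))
    for (i in seq_len(n)) {
      if (y[i] == 1) X[i, 3:5, 3:5] <- X[i, 3:5, 3:5] + 0.7
      else X[i, 10:12, 10:12] <- X[i, 10:12, 10:12] + 0.7
    }
  })
  tr <- 1:40; te <- 41:60
  model <- trainCNN(X[tr, , ], y[tr], trainConfig(epochs = 15, seed = 5))
  expect_gte(computeAUC(predictCNN(model, X[te, , ]), y[te]), 0.95)
  # determinism: same config, same data, same scores
  model2 <- trainCNN(X[tr, , ], y[tr], trainConfig(epochs = 15, seed = 5))
  expect_identical(predictCNN(model, X[te, , ]), predictCNN(model2, X[te, , ]))
})

test_that("cross-validation refuses degenerate fold counts", {
  sim <- generateDataset(syntheticParams(nSamples = 12, nTaxa = 30,
                                         dirichletConcentration = 1,
                                         sequencingDepth = 500L, seed = 2))
  expect_error(crossValidate(sim$counts, sim$labels, k = 1), "at least 2")
})
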