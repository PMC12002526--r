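#' @include AllClasses.R cnn.R
NULL

#' Training configuration
#'
#' Validated list of CNN training hyperparameters. Learning rate must lie in
#' `[1e-6, 1e-2]` and weight decay in `(1e-6, 1e-2)` — the log-scale search
#' ranges used by [randomSearch()]. The optimizer is AdamW.
#'
#' Only the `small_cnn` architecture (two 3x3 conv blocks + pooling + linear
#' head) is implemented; it is sized for desk-scale grids on one CPU.
#'
#' @param architecture `"small_cnn"`.
#' @param learningRate AdamW learning rate.
#' @param weightDecay decoupled weight decay.
#' @param epochs,batchSize training schedule.
#' @param seed integer; controls initialisation and batch order.
#' @param filters integer pair: channels of the two conv blocks.
#' @param head `"flatten"` (default) or `"gap"`.
#' @return a named list of class `"TrainConfig"`.
#' @export
trainConfig <- function(architecture = "small_cnn", learningRate = 1e-3,
                        weightDecay = 1e-4, epochs = 30L, batchSize = 16L,
                        seed = 1L, filters = c(8L, 16L),
                        head = c("flatten", "gap")) {
  head <- match.arg(head)
  if (!architecture %in% c("small_cnn", "resnet50")) {
    stop("unknown architecture", call. = FALSE)
  }
  if (!is.numeric(learningRate) || learningRate < 1e-6 || learningRate > 1e-2) {
    stop("learningRate must lie in [1e-6, 1e-2]", call. = FALSE)
  }
  if (!is.numeric(weightDecay) || weightDecay <= 1e-6 || weightDecay >= 1e-2) {
    stop("weightDecay must lie in (1e-6, 1e-2)", call. = FALSE)
  }
  if (!.isCount(epochs) || !.isCount(batchSize)) {
    stop("epochs and batchSize must be positive integers", call. = FALSE)
  }
  structure(list(architecture = architecture,
                 learningRate = as.numeric(learningRate),
                 weightDecay = as.numeric(weightDecay),
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed), filters = as.integer(filters),
                 head = head),
            class = "TrainConfig")
}

#' Stratified k-fold partition
#'
#' Partitions all sample indices into `k` disjoint folds such that each
#' fold's class proportions are within one sample of the global proportions.
#' Deterministic for a fixed seed. With imbalanced cohorts (e.g. 24 cases vs
#' 67 controls) unstratified folds can lack positives entirely, which is why
#' stratification is the default reading of "k-fold" here.
#'
#' @param labels binary vector (0/1).
#' @param k number of folds, `2 <= k <= ` minority-class count.
#' @param seed integer seed.
#' @return list of `k` integer index vectors (the held-out sets).
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  minority <- min(table(factor(y, levels = c(0L, 1L))))
  if (k > minority) {
    stop(sprintf("k = %d exceeds the minority class count (%d)", k, minority),
         call. = FALSE)
  }
  folds <- vector("list", k)
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      ix <- sample(which(y == cls))
      fid <- rep_len(seq_len(k), length(ix))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ix[fid == f])
    }
  })
  lapply(folds, sort)
}

#' Area under the ROC curve by pair counting
#'
#' The Mann–Whitney form: the probability that a randomly chosen positive
#' sample is scored above a randomly chosen negative one, with ties counted
#' one half. Invariant under any strictly increasing transform of the scores.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels binary vector (0/1) of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' computeAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
computeAUC <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)                       # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# one fold of the leakage-safe image pipeline: fit geometry, layout and
# normalization on trainIdx only, render everything, train, score test rows
.foldPipeline <- function(sphere, y, trainIdx, testIdx, pipeline, train,
                          foldSeed) {
  if (length(unique(y[trainIdx])) < 2L) {
    stop("a training fold contains a single class", call. = FALSE)
  }
  ids <- rownames(values(sphere))
  sub <- methods::new("SpherePoints",
                      values = values(sphere)[trainIdx, , drop = FALSE])
  tc <- tangentProjection(sub)
  tangAll <- projectPoints(tc, sphere)
  layout <- featureLayout(tangAll[trainIdx, , drop = FALSE],
                          method = pipeline$layoutMethod, seed = foldSeed,
                          params = pipeline$layoutParams,
                          fittedOn = sprintf("fold-train-%d", foldSeed))
  rect <- minAreaRectangle(layout)
  pmap <- pixelAssignment(layout, rect$angle, pipeline$gridH, pipeline$gridW)

  renderFor <- function(scheme) {
    norm <- normalizeValues(tangAll, scheme = scheme, trainIdx = trainIdx)
    renderImages(norm, pmap, epsilon = pipeline$epsilon,
                 segment = pipeline$segment, aggregate = pipeline$aggregate)
  }
  scheme <- pipeline$normScheme
  if (identical(scheme, "select_by_validation")) {
    # inner split of the training fold: pick the scheme with the lowest
    # validation error (1 - AUC), per the layout algorithm's selection rule
    inner <- stratifiedFolds(y[trainIdx], k = min(4L, sum(y[trainIdx] == 1L),
                                                  sum(y[trainIdx] == 0L)),
                             seed = foldSeed)[[1L]]
    valIdx <- trainIdx[inner]
    fitIdx <- setdiff(trainIdx, valIdx)
    errs <- vapply(c("independent", "topology_preserving"), function(s) {
      st <- renderFor(s)
      cfg <- train; cfg$seed <- foldSeed
      m <- trainCNN(images(st)[fitIdx, , , drop = FALSE], y[fitIdx], cfg)
      1 - computeAUC(predictCNN(m, images(st)[valIdx, , , drop = FALSE]), y[valIdx])
    }, numeric(1))
    scheme <- names(which.min(errs))
  }
  stack <- renderFor(scheme)
  cfg <- train; cfg$seed <- foldSeed
  model <- trainCNN(images(stack)[trainIdx, , , drop = FALSE], y[trainIdx], cfg)
  scores <- predictCNN(model, images(stack)[testIdx, , , drop = FALSE])
  list(auc = computeAUC(scores, y[testIdx]), scheme = scheme,
       scores = stats::setNames(scores, ids[testIdx]))
}

#' Cross-validated image-pipeline classification
#'
#' Runs the full compositional-to-image pipeline with k-fold cross
#' validation. Per fold, *everything that is fit* — the Fréchet mean and
#' rotation of the tangent projection, the 2-D feature layout, the
#' minimum-area rectangle, the pixel map, and the normalization statistics —
#' is computed from that fold's training samples only; held-out samples are
#' projected and rendered with the training-fold frame. Held-out AUC is
#' reported per fold and averaged.
#'
#' @param table a [CountTable-class].
#' @param labels binary vector (0/1), one per sample, in table order.
#' @param k number of folds (>= 2).
#' @param seed master seed; fans out to folds, layout and training.
#' @param pipeline a [pipelineConfig()] list.
#' @param train a [trainConfig()] list.
#' @return a [CVReport-class].
#' @export
crossValidate <- function(table, labels, k = 10L, seed = 1L,
                          pipeline = pipelineConfig(), train = trainConfig()) {
  stopifnot(methods::is(table, "CountTable"))
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(counts(table)))
  sphere <- sqrtTransform(closure(table))
  folds <- stratifiedFolds(y, k = k, seed = seed)
  all <- seq_along(y)
  aucs <- numeric(length(folds))
  schemes <- character(length(folds))
  for (f in seq_along(folds)) {
    testIdx <- folds[[f]]
    trainIdx <- setdiff(all, testIdx)
    res <- .foldPipeline(sphere, y, trainIdx, testIdx, pipeline, train,
                         foldSeed = as.integer(seed) * 1000L + f)
    aucs[f] <- res$auc
    schemes[f] <- res$scheme
    siLog("INFO", sprintf("fold %d/%d: AUC %.3f (scheme %s)",
                          f, length(folds), res$auc, res$scheme))
  }
  methods::new("CVReport", foldAucs = aucs, folds = folds,
               configsEvaluated = 1L, bestConfig = unclass(train),
               seed = as.integer(seed),
               details = list(schemes = schemes, pipeline = pipeline))
}

#' Log-uniform random search over learning rate and weight decay
#'
#' Samples `nTrials` (learning rate, weight decay) pairs log-uniformly on the
#' given ranges — so sampled magnitudes are evenly distributed across decades
#' — evaluates `objective` for each, and returns the argmax together with the
#' full trial log. A trial whose objective is non-finite or errors is marked
#' failed and the search continues. Deterministic per seed.
#'
#' The optional `selection = "max"` mirrors the protocol of tuning many
#' trials and reporting the maximum objective seen; note that a max over
#' trials is an optimistically biased estimate of performance.
#'
#' @param objective function of `(learningRate, weightDecay)` returning a
#'   scalar to maximise (e.g. mean CV AUC).
#' @param lrRange,wdRange positive 2-vectors; defaults are the canonical
#'   search ranges `[1e-6, 1e-2]`.
#' @param nTrials number of samples (>= 1).
#' @param seed integer seed.
#' @return list with `best` (list with `learningRate`, `weightDecay`,
#'   `value`) and `trials` (data frame with one row per trial).
#' @export
randomSearch <- function(objective, lrRange = c(1e-6, 1e-2),
                         wdRange = c(1e-6, 1e-2), nTrials = 20L, seed = 1L) {
  stopifnot(all(lrRange > 0), all(wdRange > 0), nTrials >= 1L)
  draws <- withr::with_seed(as.integer(seed), {
    cbind(lr = 10^stats::runif(nTrials, log10(lrRange[1]), log10(lrRange[2])),
          wd = 10^stats::runif(nTrials, log10(wdRange[1]), log10(wdRange[2])))
  })
  vals <- rep(NA_real_, nTrials)
  failed <- logical(nTrials)
  for (i in seq_len(nTrials)) {
    v <- tryCatch(objective(draws[i, "lr"], draws[i, "wd"]),
                  error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      failed[i] <- TRUE
    } else {
      vals[i] <- v
    }
  }
  trials <- data.frame(trial = seq_len(nTrials), learningRate = draws[, "lr"],
                       weightDecay = draws[, "wd"], value = vals,
                       failed = failed)
  if (all(failed)) stop("every trial failed", call. = FALSE)
  bi <- which.max(vals)
  list(best = list(learningRate = unname(draws[bi, "lr"]),
                   weightDecay = unname(draws[bi, "wd"]), value = vals[bi]),
       trials = trials)
}
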