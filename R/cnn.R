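# Small convolutional network in base R: im2col convolutions, manual
# backprop, AdamW. Two 3x3 conv blocks (ReLU + 2x2 max pool after the first,
# 2x2 max pool after the second), then either a flatten+linear head (default;
# it keeps the pixel-location information that the DeepInsight layout
# encodes) or a global-average-pooling head ("gap").
#
# Sized for desk-scale grids (32x32) on one CPU; gradient-checked in the
# test suite against numerical differentiation.

.im2col <- function(A, kh, kw) {
  d <- dim(A); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oh <- H - kh + 1L; ow <- W - kw + 1L
  cols <- vector("list", kh * kw)
  p <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    p <- p + 1L
    blk <- A[, di + seq_len(oh), dj + seq_len(ow), , drop = FALSE]
    dim(blk) <- c(N * oh * ow, C)
    cols[[p]] <- blk
  }
  list(P = do.call(cbind, cols), oh = oh, ow = ow)
}

.col2im <- function(dP, inDim, kh, kw, oh, ow) {
  N <- inDim[1]; C <- inDim[4]
  dA <- array(0, inDim)
  p <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    p <- p + 1L
    blk <- dP[, (p - 1L) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(N, oh, ow, C)
    dA[, di + seq_len(oh), dj + seq_len(ow), ] <-
      dA[, di + seq_len(oh), dj + seq_len(ow), , drop = FALSE] + blk
  }
  dA
}

# weight array kh x kw x C x F  <->  (kh*kw*C) x F matrix matching .im2col
.wToMat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3, 1, 2, 4)), nrow = d[1] * d[2] * d[3])
}
.wFromMat <- function(M, kh, kw, C, F) {
  aperm(array(M, c(C, kh, kw, F)), c(2, 3, 1, 4))
}

.convF <- function(A, W, b) {
  d <- dim(W)
  ic <- .im2col(A, d[1], d[2])
  out <- ic$P %*% .wToMat(W)
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(dim(A)[1], ic$oh, ic$ow, d[4])
  list(out = out, P = ic$P, oh = ic$oh, ow = ic$ow, inDim = dim(A))
}

.convB <- function(cache, W, dOut) {
  d <- dim(W)
  dm <- matrix(dOut, nrow = dim(dOut)[1] * dim(dOut)[2] * dim(dOut)[3])
  dW <- .wFromMat(crossprod(cache$P, dm), d[1], d[2], d[3], d[4])
  db <- colSums(dm)
  dP <- tcrossprod(dm, .wToMat(W))
  dA <- .col2im(dP, cache$inDim, d[1], d[2], cache$oh, cache$ow)
  list(dA = dA, dW = dW, db = db)
}

.poolF <- function(A) {
  d <- dim(A); ph <- d[2] %/% 2L; pw <- d[3] %/% 2L
  i1 <- seq_len(ph) * 2L - 1L; j1 <- seq_len(pw) * 2L - 1L
  parts <- list(A[, i1, j1, , drop = FALSE],     A[, i1, j1 + 1L, , drop = FALSE],
                A[, i1 + 1L, j1, , drop = FALSE], A[, i1 + 1L, j1 + 1L, , drop = FALSE])
  M <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  list(M = M, parts = parts, i1 = i1, j1 = j1, inDim = d)
}

.poolB <- function(cache, dM) {
  dA <- array(0, cache$inDim)
  taken <- array(FALSE, dim(dM))
  offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (k in 1:4) {
    m <- (cache$parts[[k]] == cache$M) & !taken
    taken <- taken | m
    di <- offs[[k]][1]; dj <- offs[[k]][2]
    dA[, cache$i1 + di, cache$j1 + dj, ] <-
      dA[, cache$i1 + di, cache$j1 + dj, , drop = FALSE] + dM * m
  }
  dA
}

# forward (+ optional backward) pass; X: N x H x W array, y in {0,1} or NULL
.cnnPass <- function(params, X, y = NULL, grad = FALSE) {
  N <- dim(X)[1]
  A0 <- array(X, c(dim(X), 1L))
  c1 <- .convF(A0, params$W1, params$b1)
  r1 <- pmax(c1$out, 0)
  p1 <- .poolF(r1)
  c2 <- .convF(p1$M, params$W2, params$b2)
  r2 <- pmax(c2$out, 0)
  p2 <- .poolF(r2)
  if (identical(params$head, "gap")) {
    F2 <- apply(p2$M, c(1, 4), mean)
  } else {
    F2 <- matrix(p2$M, nrow = N)
  }
  z <- as.vector(F2 %*% params$w3 + params$b3)
  if (is.null(y)) return(list(logits = z))
  prob <- 1 / (1 + exp(-z))
  eps <- 1e-12
  loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  if (!grad) return(list(logits = z, loss = loss))

  dz <- (prob - y) / N
  dw3 <- as.vector(crossprod(F2, dz))
  db3 <- sum(dz)
  dF2 <- outer(dz, as.vector(params$w3))
  if (identical(params$head, "gap")) {
    d2 <- dim(p2$M)
    dP2 <- array(0, d2)
    sp <- d2[2] * d2[3]
    for (ch in seq_len(d2[4])) dP2[, , , ch] <- dF2[, ch] / sp
  } else {
    dP2 <- array(dF2, dim(p2$M))
  }
  dR2 <- .poolB(p2, dP2)
  dC2 <- dR2 * (c2$out > 0)
  b2g <- .convB(c2, params$W2, dC2)
  dP1 <- b2g$dA
  dR1 <- .poolB(p1, dP1)
  dC1 <- dR1 * (c1$out > 0)
  b1g <- .convB(c1, params$W1, dC1)
  list(logits = z, loss = loss,
       grads = list(W1 = b1g$dW, b1 = b1g$db, W2 = b2g$dW, b2 = b2g$db,
                    w3 = dw3, b3 = db3))
}

.cnnInit <- function(h, w, filters = c(8L, 16L), head = "flatten", seed = 1L) {
  k <- 3L
  oh1 <- h - k + 1L; ow1 <- w - k + 1L
  ph1 <- oh1 %/% 2L; pw1 <- ow1 %/% 2L
  oh2 <- ph1 - k + 1L; ow2 <- pw1 - k + 1L
  ph2 <- oh2 %/% 2L; pw2 <- ow2 %/% 2L
  if (ph2 < 1L || pw2 < 1L) {
    stop(sprintf("image %dx%d too small for the two conv/pool blocks", h, w),
         call. = FALSE)
  }
  nin <- if (identical(head, "gap")) filters[2] else ph2 * pw2 * filters[2]
  withr::with_seed(as.integer(seed), {
    params <- list(
      W1 = array(stats::rnorm(k * k * 1L * filters[1], sd = sqrt(2 / (k * k))),
                 c(k, k, 1L, filters[1])),
      b1 = rep(0, filters[1]),
      W2 = array(stats::rnorm(k * k * filters[1] * filters[2],
                              sd = sqrt(2 / (k * k * filters[1]))),
                 c(k, k, filters[1], filters[2])),
      b2 = rep(0, filters[2]),
      w3 = matrix(stats::rnorm(nin, sd = sqrt(1 / nin)), ncol = 1L),
      b3 = 0,
      head = head)
  })
  params
}

.adamwStep <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W1", "W2", "w3")
  for (nm in c("W1", "b1", "W2", "b2", "w3", "b3")) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    upd <- lr * mh / (sqrt(vh) + eps)
    if (nm %in% decayed) upd <- upd + lr * wd * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

#' Train the small CNN on an image stack
#'
#' Trains the package's two-block convolutional network with AdamW on binary
#' labels, minimising binary cross-entropy. Fully deterministic for a fixed
#' configuration seed.
#'
#' @param stack an [ImageStack-class] or plain `n x H x W` array in `[0, 1]`.
#' @param labels binary vector (0/1), length n.
#' @param config a [trainConfig()] list.
#' @return an opaque model object for [predictCNN()].
#' @export
trainCNN <- function(stack, labels, config = trainConfig()) {
  X <- if (methods::is(stack, "ImageStack")) images(stack) else stack
  y <- as.numeric(labels)
  n <- dim(X)[1]
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class", call. = FALSE)
  if (!identical(config$architecture, "small_cnn")) {
    stop(sprintf("architecture '%s' is not available; only 'small_cnn' is implemented",
                 config$architecture), call. = FALSE)
  }
  h <- dim(X)[2]; w <- dim(X)[3]
  params <- .cnnInit(h, w, filters = config$filters, head = config$head,
                     seed = config$seed)
  zeros <- lapply(params[c("W1", "b1", "W2", "b2", "w3", "b3")],
                  function(p) p * 0)
  state <- list(m = zeros, v = zeros)
  bs <- min(config$batchSize, n)
  t <- 0L
  withr::with_seed(as.integer(config$seed) + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1L, n)]
        if (length(ix) < 2L) next
        t <- t + 1L
        pass <- .cnnPass(params, X[ix, , , drop = FALSE], y[ix], grad = TRUE)
        st <- .adamwStep(params, pass$grads, state,
                         lr = config$learningRate, wd = config$weightDecay, t = t)
        params <- st$params; state <- st$state
      }
    }
  })
  structure(list(params = params, config = config, inputDim = c(h, w)),
            class = "sphereInsightCNN")
}

#' Predict scores from a trained small CNN
#'
#' @param model object returned by [trainCNN()].
#' @param stack an [ImageStack-class] or `n x H x W` array.
#' @return numeric vector of class-1 probabilities.
#' @export
predictCNN <- function(model, stack) {
  stopifnot(inherits(model, "sphereInsightCNN"))
  X <- if (methods::is(stack, "ImageStack")) images(stack) else stack
  if (!identical(dim(X)[2:3], as.integer(model$inputDim)) &&
      !identical(as.integer(dim(X)[2:3]), as.integer(model$inputDim))) {
    stop("image dimensions do not match the trained model", call. = FALSE)
  }
  n <- dim(X)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = 256L)) {
    ix <- start:min(start + 255L, n)
    z <- .cnnPass(model$params, X[ix, , , drop = FALSE])$logits
    out[ix] <- 1 / (1 + exp(-z))
  }
  out
}
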