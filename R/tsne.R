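# Exact (dense) t-SNE, used as one of the feature-layout embeddings.
# Standard formulation: perplexity-calibrated Gaussian input affinities,
# Student-t low-dimensional kernel, gradient descent with momentum and early
# exaggeration. Dense O(n^2) per iteration — intended for feature counts in
# the hundreds to low thousands, which is the regime of this package.

# per-point precision calibration by binary search on beta = 1/(2 sigma^2)
.tsnePerplexity <- function(D2, perplexity, tol = 1e-5, maxTries = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betaMin <- -Inf; betaMax <- Inf
    di <- D2[i, -i]
    for (tr in seq_len(maxTries)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < .Machine$double.xmin) sp <- .Machine$double.xmin
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < tol) break
      if (H > logU) { betaMin <- beta; beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2 }
      else          { betaMax <- beta; beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P
}

.tsneExact <- function(X, perplexity = 30, maxIter = 400L, seed = 1L,
                       eta = 100, momentum = c(0.5, 0.8), exaggeration = 4) {
  n <- nrow(X)
  if (n < 4L) stop("t-SNE needs at least 4 points", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)
  sumX <- rowSums(X^2)
  D2 <- pmax(outer(sumX, sumX, "+") - 2 * tcrossprod(X), 0)
  P <- .tsnePerplexity(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  })
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(maxIter)) {
    if (it == 101L) Pe <- P                         # stop early exaggeration
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250L) momentum[1] else momentum[2]
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
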