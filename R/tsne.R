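# Exact t-SNE to 2D for small point sets (the feature-distribution metric
# embeds at most a few hundred images).  Standard recipe: per-point
# perplexity calibration by bisection on the Gaussian bandwidth, symmetrized
# affinities, early exaggeration, momentum gradient descent on the
# Student-t low-dimensional affinities.

tsne_perplexity_p <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' Embed feature rows into 2D with t-SNE
#'
#' @param X numeric matrix (rows = items)
#' @param perplexity Gaussian neighbourhood size; default min(30, n/4)
#' @param seed recorded alongside results; the embedding itself is made
#'   deterministic by a PCA initialization, which also guarantees that
#'   duplicate input rows embed to identical coordinates
#' @param n_iter gradient-descent iterations
#' @return n x 2 matrix of embedded coordinates
#' @export
tsne_embed2d <- function(X, perplexity = NULL, seed = 1L, n_iter = 400L) {
  n <- nrow(X)
  if (n < 4L) stopf("need at least 4 points")
  perplexity <- perplexity %||% min(30, n / 4)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  P <- tsne_perplexity_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA init: deterministic, and duplicate rows start (and stay) identical,
  # so identical real/synthetic sets yield exactly coinciding point groups
  Xc <- sweep(X, 2L, colMeans(X))
  pc <- La.svd(Xc, nu = 2L, nv = 0L)
  Y <- pc$u %*% diag(pc$d[1:2], 2L)
  s1 <- stats::sd(Y[, 1])
  Y <- if (s1 > 0) Y / s1 * 1e-4 else matrix(0, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5; lr <- 100
  exag <- 12
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exag else P
    Gy <- tcrossprod(Y); sqy <- diag(Gy)
    num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * Gy)
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (it == 250) momentum <- 0.8
    inc <- momentum * inc - lr * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
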