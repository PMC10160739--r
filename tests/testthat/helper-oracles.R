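# Independent brute-force oracles used across the suite.  These are written
# from the definitions (loops, enumeration, quadrature), never by calling the
# implementation they check.

# dense full self-attention over all H*W tokens, plain loops
dense_attention_ref <- function(f, w) {
  d <- dim(f); H <- d[1]; W <- d[2]; C <- d[3]
  X <- matrix(0, H * W, C)
  for (i in seq_len(H)) for (j in seq_len(W))
    X[(i - 1) * W + j, ] <- f[i, j, ]
  M <- w$n_heads; dk <- w$d
  q <- X %*% w$wq; k <- X %*% w$wk; v <- X %*% w$wv
  heads <- matrix(0, H * W, C)
  for (m in seq_len(M)) {
    cols <- ((m - 1) * dk + 1):(m * dk)
    for (i in seq_len(H * W)) {
      s <- numeric(H * W)
      for (j in seq_len(H * W))
        s[j] <- sum(q[i, cols] * k[j, cols]) / sqrt(dk)
      a <- exp(s - max(s)); a <- a / sum(a)
      heads[i, cols] <- colSums(a * v[, cols, drop = FALSE])
    }
  }
  Y <- heads %*% w$wo
  out <- array(0, dim = c(H, W, C))
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j, ] <- Y[(i - 1) * W + j, ]
  out
}

# discretized 1-pixel forward chain: transition matrices on a value grid,
# exact Bayes posterior q(x_{t-1} | x_t, x0) by enumeration
discretized_bayes_posterior <- function(schedule, x0, t, grid) {
  ng <- length(grid)
  kern <- function(tt) {          # q(x_t | x_{t-1}) row-normalized on grid
    a <- sqrt(1 - schedule$betas[tt])
    sd <- sqrt(schedule$betas[tt])
    K <- outer(grid, grid, function(prev, nxt) dnorm(nxt, a * prev, sd))
    K / rowSums(K)
  }
  i0 <- which.min(abs(grid - x0))
  p_prev <- numeric(ng); p_prev[i0] <- 1        # delta at x0
  for (tt in seq_len(t - 1)) p_prev <- as.vector(p_prev %*% kern(tt))
  # p_prev = q(x_{t-1} | x0); posterior over x_{t-1} given observed x_t:
  Kt <- kern(t)
  function(xt_val) {
    lik <- dnorm(xt_val, sqrt(1 - schedule$betas[t]) * grid,
                 sqrt(schedule$betas[t]))
    w <- p_prev * lik
    w <- w / sum(w)
    c(mean = sum(grid * w), var = sum(grid^2 * w) - sum(grid * w)^2)
  }
}

# iterate the one-step forward kernel t times on a scalar pixel
iterate_forward_chain <- function(x0, t, schedule, n_draws) {
  x <- rep(x0, n_draws)
  for (tt in seq_len(t)) {
    a <- sqrt(1 - schedule$betas[tt])
    x <- a * x + sqrt(schedule$betas[tt]) * rnorm(n_draws)
  }
  x
}

# quadrature of a Gaussian density over an intensity bin
bin_prob_quadrature <- function(x0, mu, sigma2, delta, data_range) {
  s <- sqrt(sigma2)
  if (x0 <= data_range[1] + delta)
    stats::integrate(function(u) dnorm(u, mu, s), -Inf, x0 + delta,
                     rel.tol = 1e-10)$value
  else if (x0 >= data_range[2] - delta)
    stats::integrate(function(u) dnorm(u, mu, s), x0 - delta, Inf,
                     rel.tol = 1e-10)$value
  else
    stats::integrate(function(u) dnorm(u, mu, s), x0 - delta, x0 + delta,
                     rel.tol = 1e-10)$value
}

# naive 3x3 zero-padded convolution, plain loops (reference for the kernel)
conv3x3_ref <- function(x, w, b) {       # x: H x W x Cin, w: (9Cin) x Cout
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(w)
  out <- array(0, dim = c(H, W, Cout))
  offs <- expand.grid(dj = -1:1, di = -1:1)[, c(2, 1)]  # di-major like geom
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  offs <- offs[order(offs[, 1], offs[, 2]), ]
  for (i in seq_len(H)) for (j in seq_len(W)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (k in 1:9) {
      ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + sum(x[ii, jj, ] * w[((k - 1) * Cin + 1):(k * Cin), co])
    }
    out[i, j, co] <- acc
  }
  out
}

make_toy_model <- function(seed = 3, live_heads = TRUE) {
  m <- init_denoiser(network_config_toy(), seed = seed)
  if (live_heads) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed + 1000)
    for (nm in c("head.eps.w", "head.v.w"))
      m$params[[nm]] <- matrix(rnorm(length(m$params[[nm]]), 0, 0.1),
                               nrow = nrow(m$params[[nm]]))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  m
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)) / max(1e-12, max(abs(y))), tol)
}
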