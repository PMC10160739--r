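test_that("noise MSE matches a naive loop", {
  expect_equal(noise_mse_loss(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_equal(noise_mse_loss(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  set.seed(1)
  a <- array(rnorm(24), c(2, 3, 4)); b <- array(rnorm(24), c(2, 3, 4))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(noise_mse_loss(a, b), acc / 24)
  expect_error(noise_mse_loss(numeric(0), numeric(0)), "empty")
})

test_that("KL term vanishes at the perfect prediction and anchors at 0.5 nats", {
  sch <- noise_schedule(10, 0.02)
  x0 <- matrix(runif(9, -1, 1), 3)
  set.seed(2)
  eps <- matrix(rnorm(9), 3)
  t <- 6
  xt <- q_sample(x0, t, eps, sch)
  # perfect mean (true eps) and perfect variance (v = 0 -> beta_tilde)
  out <- denoiser_output(eps, matrix(-1e9, 3, 3))   # tanh -> -1 -> v = 0
  expect_lt(abs(vlb_term(x0, xt, t, out, sch)), 1e-10)
  # anchor: unit mean offset at unit variance must cost 0.5 nats per pixel.
  # Perturb eps so that mu_theta - mu = sqrt(beta_tilde) exactly.
  btl <- sch$posterior_variances[t]
  d_eps <- -sqrt(btl) * sqrt(sch$alphas[t]) * sqrt(1 - sch$alpha_bars[t]) /
    sch$betas[t]
  out2 <- denoiser_output(eps + d_eps, matrix(-1e9, 3, 3))
  expect_equal(vlb_term(x0, xt, t, out2, sch), 0.5, tolerance = 1e-8)
})

test_that("KL of N(0,1) against N(1,1) is 0.5 nats, confirmed by Monte Carlo", {
  p <- list(mean = 0, cov = matrix(1)); q <- list(mean = 1, cov = matrix(1))
  expect_equal(gaussian_kl(p, q), 0.5, tolerance = 1e-12)
  set.seed(3)
  x <- rnorm(1e5)
  mc <- mean(dnorm(x, 0, 1, log = TRUE) - dnorm(x, 1, 1, log = TRUE))
  expect_lt(abs(mc - 0.5) / 0.5, 0.02)
})

test_that("t = 1 discretized likelihood agrees with quadrature", {
  sch <- noise_schedule(10, 0.02)
  cfg <- loss_config()
  cases <- list(
    list(x0 = 0.1, mu = 0.12, s2 = 0.01),    # interior bin
    list(x0 = 0.0, mu = -0.3, s2 = 0.04),    # interior, off-center
    list(x0 = -1.0, mu = -0.9, s2 = 0.02),   # open lower edge
    list(x0 = 1.0, mu = 0.8, s2 = 0.05))     # open upper edge
  for (cs in cases) {
    ll <- swindiff:::discretized_gaussian_loglik(cs$x0, cs$mu, cs$s2,
                                                 cfg$delta, c(-1, 1))
    pq <- bin_prob_quadrature(cs$x0, cs$mu, sqrt(cs$s2)^2, cfg$delta, c(-1, 1))
    expect_lt(abs(exp(ll) - pq), 1e-4)
    expect_lt(abs(ll - log(pq)), 1e-4)
  }
  # the fast tanh approximation is close but NOT inside 1e-4 on open bins;
  # it is provided for parity and checked at its own accuracy
  ll_approx <- swindiff:::discretized_gaussian_loglik(0.1, 0.12, 0.01,
                                                      cfg$delta, c(-1, 1),
                                                      approx = TRUE)
  pq <- bin_prob_quadrature(0.1, 0.12, 0.01, cfg$delta, c(-1, 1))
  expect_lt(abs(exp(ll_approx) - pq), 5e-3)
})

test_that("vlb_term routes t = 1 through the discretized decoder", {
  sch <- noise_schedule(10, 0.02)
  x0 <- matrix(c(-1, -0.2, 0.3, 1), 2)
  set.seed(4)
  eps <- matrix(rnorm(4), 2)
  xt <- q_sample(x0, 1, eps, sch)
  out <- denoiser_output(eps, matrix(1e9, 2, 2))   # v = 1 -> sigma^2 = beta_1
  val <- vlb_term(x0, xt, 1, out, sch)
  mu <- mu_from_eps(xt, 1, eps, sch)
  s2 <- sigma_from_v(1, out$v, sch)
  ref <- -mean(mapply(function(x, m, s)
    log(bin_prob_quadrature(x, m, s, 1/256, c(-1, 1))), x0, mu, s2))
  expect_equal(val, ref, tolerance = 1e-4)
  expect_error(vlb_term(x0, xt, 0, out, sch), "out of range")
})

test_that("vlb_term is non-negative for t >= 2", {
  sch <- noise_schedule(20, 0.01)
  set.seed(5)
  for (rep in 1:20) {
    t <- sample(2:20, 1)
    x0 <- matrix(runif(4, -1, 1), 2)
    eps <- matrix(rnorm(4), 2)
    xt <- q_sample(x0, t, eps, sch)
    out <- denoiser_output(eps + matrix(rnorm(4, 0, 0.3), 2),
                           matrix(rnorm(4), 2))
    expect_gte(vlb_term(x0, xt, t, out, sch), 0)
  }
})

test_that("hybrid loss combines the two objectives with gamma = 0.01", {
  expect_equal(formals(loss_config)$gamma, 0.01)
  expect_equal(eval(formals(loss_config)$delta), 1 / 256)
  sch <- noise_schedule(10, 0.02)
  set.seed(6)
  x0 <- array(runif(8, -1, 1), c(2, 2, 2))
  eps <- array(rnorm(8), c(2, 2, 2))
  t <- c(4, 7)
  xt <- array(0, c(2, 2, 2))
  for (i in 1:2) xt[, , i] <- q_sample(x0[, , i], t[i], eps[, , i], sch)
  batch <- list(x0 = x0, xt = xt, eps = eps, t = t)
  out <- denoiser_output(eps, array(-1e9, c(2, 2, 2)))
  h <- hybrid_loss(batch, out, sch)
  expect_lt(abs(h$l_var), 1e-10)     # perfect prediction: vlb contributes 0
  expect_equal(h$loss, h$l_mean)
  # arithmetic: L = L_mean + gamma * L_var
  out2 <- denoiser_output(eps + 0.5, array(0.3, c(2, 2, 2)))
  h2 <- hybrid_loss(batch, out2, sch, loss_config(gamma = 0.01))
  expect_equal(h2$loss, h2$l_mean + 0.01 * h2$l_var)
  expect_equal(h2$l_mean, 0.25)
})

test_that("analytic loss gradients match finite differences", {
  sch <- noise_schedule(10, 0.02)
  set.seed(8)
  x0 <- array(runif(8, -1, 1), c(2, 2, 2))
  eps <- array(rnorm(8), c(2, 2, 2))
  t <- c(1, 5)                               # exercise both vlb branches
  xt <- array(0, c(2, 2, 2))
  for (i in 1:2) xt[, , i] <- q_sample(x0[, , i], t[i], eps[, , i], sch)
  batch <- list(x0 = x0, xt = xt, eps = eps, t = t)
  ep <- eps + array(rnorm(8, 0, 0.2), c(2, 2, 2))
  vr <- array(rnorm(8, 0, 0.5), c(2, 2, 2))
  gl <- swindiff:::hybrid_loss_grads(batch, denoiser_output(ep, vr), sch,
                                     loss_config())
  lossat <- function(ep_, vr_)
    hybrid_loss(batch, denoiser_output(ep_, vr_), sch, loss_config())$loss
  h <- 1e-6
  for (idx in c(1, 4, 6, 8)) {
    e2 <- ep; e2[idx] <- e2[idx] + h
    fd <- (lossat(e2, vr) - lossat(ep, vr)) / h
    # eps gradient: the VLB mean is detached, so only the MSE term counts
    expect_equal(gl$d_eps[idx], 2 * (ep[idx] - eps[idx]) / 8, tolerance = 1e-8)
    v2 <- vr; v2[idx] <- v2[idx] + h
    fdv <- (lossat(ep, v2) - lossat(ep, vr)) / h
    expect_equal(gl$d_vraw[idx], fdv, tolerance = 1e-4)
  }
})
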