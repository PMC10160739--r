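test_that("spaced chains pick the stated subsets and preserve marginals", {
  sch <- noise_schedule(4000, 5e-6)
  ch <- make_spaced_chain(sch, 500)
  expect_length(ch$S, 500)
  expect_false(any(duplicated(ch$S)))
  expect_true(all(diff(ch$S) > 0))
  expect_equal(ch$S[1], 1)
  expect_equal(ch$S[500], 4000)
  # worked example at T = 10, n = 5
  s10 <- noise_schedule(10, 0.02)
  expect_equal(make_spaced_chain(s10, 5)$S, c(1L, 3L, 5L, 8L, 10L))
  # effective alpha-bars equal the parent's at the selected steps
  expect_equal(ch$effective_alpha_bars, sch$alpha_bars[ch$S])
  # effective beta at sub-step 1 with S1 = 1 equals the parent beta_1
  expect_equal(ch$effective_betas[1], sch$betas[1])
  expect_error(make_spaced_chain(sch, 0), "out of range")
  expect_error(make_spaced_chain(sch, 4001), "out of range")
})

test_that("the identity sub-chain reproduces the parent quantities exactly", {
  sch <- noise_schedule(40, 1e-3)
  ch <- make_spaced_chain(sch, 40)
  expect_equal(ch$S, 1:40)
  expect_equal(ch$effective_betas, sch$betas, tolerance = 1e-12)
  expect_equal(ch$effective_alpha_bars, sch$alpha_bars)
  expect_equal(ch$effective_posterior_variances, sch$posterior_variances,
               tolerance = 1e-12)
})

test_that("reverse_step endpoints behave", {
  sch <- noise_schedule(10, 0.02)
  ch <- make_spaced_chain(sch, 10)
  set.seed(20)
  xs <- matrix(rnorm(16), 4)
  out <- denoiser_output(matrix(rnorm(16), 4), matrix(0, 4, 4))
  # zero noise leaves exactly the mean
  mu <- mu_from_eps(xs, 5, out$eps_pred, sch)
  expect_equal(reverse_step(xs, 5, out, ch, matrix(0, 4, 4)), mu)
  # v = 1: the stochastic term has sd sqrt(effective beta)
  out1 <- denoiser_output(out$eps_pred, matrix(1e9, 4, 4))
  noise <- matrix(1, 4, 4)
  step <- reverse_step(xs, 5, out1, ch, noise)
  expect_equal(step - mu, matrix(sqrt(ch$effective_betas[5]), 4, 4))
  # final sub-step drops the noise term entirely
  expect_equal(reverse_step(xs, 1, out, ch, matrix(100, 4, 4)),
               mu_from_eps(xs, 1, out$eps_pred, sch))
  expect_error(reverse_step(xs, 11, out, ch, noise), "out of chain")
})

test_that("spaced sampler with n_steps = T is bit-identical to a full-chain loop", {
  m <- make_toy_model(seed = 6)
  T_steps <- 6
  sch <- noise_schedule(T_steps, 0.03)
  ch <- make_spaced_chain(sch, T_steps)
  side <- 32; B <- 2
  got <- generate(m, ch, B, seed = 77, modality = "phantom", side = side)
  # independent full-chain sampler, same documented RNG order
  set.seed(77)
  x <- array(rnorm(side * side * B), c(side, side, B))
  for (t in T_steps:1) {
    out <- denoiser_forward(m, x, t)
    mu <- mu_from_eps(x, t, out$eps_pred, sch)
    if (t > 1) {
      btl <- max(sch$posterior_variances[t], 1e-20)
      s2 <- exp(out$v * log(sch$betas[t]) + (1 - out$v) * log(btl))
      x <- mu + sqrt(s2) * array(rnorm(side * side * B), c(side, side, B))
    } else x <- mu
  }
  x <- pmin(pmax(x, -1), 1)
  for (i in seq_len(B))
    expect_identical(got$images[[i]], x[, , i])
})

test_that("generation is seed-deterministic and respects the clip range", {
  m <- make_toy_model(seed = 6)
  sch <- noise_schedule(20, 0.005)
  ch <- make_spaced_chain(sch, 5)
  a <- generate(m, ch, 3, seed = 5, modality = "phantom", side = 32)
  b <- generate(m, ch, 3, seed = 5, modality = "phantom", side = 32)
  expect_identical(a$images, b$images)
  for (im in a$images) expect_true(all(im >= -1 & im <= 1))
  # CT clips to [0, 1]
  ct <- generate(m, ch, 2, seed = 5, modality = "ct", side = 32)
  for (im in ct$images) expect_true(all(im >= 0 & im <= 1))
})
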