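test_that("sinusoidal embedding follows the stated frequency rule", {
  e0 <- sinusoidal_embed(0, dim = 16)
  expect_equal(e0[1:8], rep(0, 8))
  expect_equal(e0[9:16], rep(1, 8))
  expect_error(sinusoidal_embed(1, dim = 7), "even")
  # component k (0-based) of the sin half is sin(t * max_period^(-2k/dim))
  dim <- 32; mp <- 1e6; t <- 137
  e <- sinusoidal_embed(t, dim, mp)
  for (k in c(0, 3, 11)) {
    expect_equal(e[k + 1], sin(t * mp^(-2 * k / dim)))
    expect_equal(e[dim / 2 + k + 1], cos(t * mp^(-2 * k / dim)))
  }
  # reference defaults: dim 128, max period 1e6
  expect_equal(eval(formals(sinusoidal_embed)$dim), 128L)
  expect_equal(formals(sinusoidal_embed)$max_period, 1e6)
})

test_that("denoiser outputs are image-shaped and finite for both depths", {
  m <- make_toy_model()
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  out <- denoiser_forward(m, x, c(3, 150))
  expect_equal(dim(out$eps_pred), dim(x))
  expect_equal(dim(out$v_raw), dim(x))
  expect_true(all(is.finite(out$eps_pred)))
  expect_true(all(is.finite(out$v)))
  expect_true(all(out$v >= 0 & out$v <= 1))
  # full depth plan: 2 conv + 4 swin down, 3 middle, mirrored; needs side 64
  cfg_full <- network_config(base_channels = 32, width_multiplier = 0.125,
                             window_size = 4, num_heads = 2,
                             time_embed_dim = 32, groupnorm_groups = 4,
                             depth = "full")
  expect_identical(cfg_full$plan,
                   list(enc_conv = 2L, enc_swin = 4L, middle = 3L))
  mf <- init_denoiser(cfg_full, seed = 2)
  xf <- matrix(rnorm(64 * 64), 64)
  of <- denoiser_forward(mf, xf, 17)
  expect_equal(dim(of$eps_pred), c(64, 64))
  expect_true(all(is.finite(of$eps_pred)))
  expect_error(denoiser_forward(m, matrix(0, 24, 24), 1), "incompatible")
})

test_that("timestep conditioning is live", {
  m <- make_toy_model(live_heads = TRUE)
  x <- matrix(rnorm(32 * 32), 32)
  o1 <- denoiser_forward(m, x, 2)
  o2 <- denoiser_forward(m, x, 180)
  expect_gt(max(abs(o1$eps_pred - o2$eps_pred)), 1e-8)
})

test_that("parameter count grows with the width multiplier", {
  counts <- vapply(c(0.25, 0.5, 0.75, 1), function(wm)
    count_params(init_denoiser(network_config(
      base_channels = 32, width_multiplier = wm, window_size = 4,
      num_heads = 2, time_embed_dim = 32, groupnorm_groups = 4,
      depth = "reduced"), seed = 1)), numeric(1))
  expect_true(all(diff(counts) > 0))
  # roughly quadratic: full model far larger than the quarter model
  expect_gt(counts[4] / counts[1], 8)
})

test_that("the tape conv kernel matches a naive loop convolution", {
  set.seed(13)
  ns <- asNamespace("swindiff")
  H <- 5; W <- 4; Cin <- 3; Cout <- 2
  x <- array(rnorm(H * W * Cin), c(H, W, Cin))
  w <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
  b <- rnorm(Cout)
  tp <- ns$tape_new()
  xr <- matrix(aperm(x, c(2, 1, 3)), H * W, Cin)
  g <- ns$conv_geom(1L, H, W)
  y <- ns$tp_value(tp, ns$tp_conv3x3(tp, ns$tp_input(tp, xr),
                                     ns$tp_input(tp, w), ns$tp_input(tp, b), g))
  ref <- conv3x3_ref(x, w, b)
  ref_flat <- matrix(aperm(ref, c(2, 1, 3)), H * W, Cout)
  expect_lt(max(abs(y - ref_flat)), 1e-12)
})

test_that("network gradients match central finite differences", {
  ns <- asNamespace("swindiff")
  m <- make_toy_model(seed = 3)
  set.seed(14)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  t <- c(3, 9)
  R1 <- matrix(rnorm(512), 512, 1); R2 <- matrix(rnorm(512), 512, 1)
  lossfn <- function(mm) {
    fw <- ns$denoiser_forward_tape(mm, x, t)
    sum(ns$tp_value(fw$tape, fw$eps_node) * R1) +
      sum(ns$tp_value(fw$tape, fw$v_node) * R2)
  }
  fw <- ns$denoiser_forward_tape(m, x, t)
  seeds <- list()
  seeds[[as.character(fw$eps_node)]] <- R1
  seeds[[as.character(fw$v_node)]] <- R2
  grads <- ns$tape_backward(fw$tape, seeds)
  picks <- sample(names(m$params), 16)
  for (nm in picks) {
    p <- m$params[[nm]]
    i <- sample(length(p), 1)
    h <- 1e-5 * max(1, abs(p[i]))
    mp <- m; mp$params[[nm]][i] <- p[i] + h
    mn <- m; mn$params[[nm]][i] <- p[i] - h
    fd <- (lossfn(mp) - lossfn(mn)) / (2 * h)
    an <- grads[[nm]][i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-5)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  m <- make_toy_model(seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "round-trip"))
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(attr(m2, "extra")$note, "round-trip")
  x <- matrix(rnorm(32 * 32), 32)
  o1 <- denoiser_forward(m, x, 8)
  o2 <- denoiser_forward(m2, x, 8)
  expect_identical(o1$eps_pred, o2$eps_pred)
  expect_identical(o1$v_raw, o2$v_raw)
})
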