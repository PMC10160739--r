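test_that("inception score hits its closed-form anchors", {
  K <- 5
  uni <- matrix(1 / K, 40, K)
  expect_equal(unname(inception_score(uni, 4)["mean"]), 1)
  onehot <- diag(K)[rep(seq_len(K), each = 8), ]
  is1 <- inception_score(onehot, 1)
  expect_equal(unname(is1["mean"]), K, tolerance = 1e-9)
  expect_equal(unname(is1["std"]), 0)
  # single split equals the no-split definition
  set.seed(40)
  p <- matrix(runif(60), 12, 5); p <- p / rowSums(p)
  marg <- colMeans(p)
  ref <- exp(mean(rowSums(p * log(p / rep(marg, each = 12)))))
  expect_equal(unname(inception_score(p, 1)["mean"]), ref)
  expect_error(inception_score(matrix(0, 3, 2)), "zero mass")
  expect_true(inception_score(p, 3)["mean"] >= 1 - 1e-12)
})

test_that("Frechet distance: identity, mean shift, and diagonal analytic case", {
  set.seed(41)
  a <- matrix(rnorm(400 * 4), 400, 4)
  expect_lt(fid(a, a), 1e-6)
  # far-apart standard normals: FID -> c^2 (identity covariances cancel)
  c_shift <- 3
  b <- matrix(rnorm(4000 * 4), 4000, 4)
  b2 <- matrix(rnorm(4000 * 4), 4000, 4); b2[, 1] <- b2[, 1] + c_shift
  expect_lt(abs(fid(b, b2) - c_shift^2) / c_shift^2, 0.05)
  # diagonal covariances: analytic Frechet distance
  s1 <- c(1, 4); s2 <- c(9, 1); mu2 <- c(2, -1)
  x1 <- cbind(rnorm(6000, 0, sqrt(s1[1])), rnorm(6000, 0, sqrt(s1[2])))
  x2 <- cbind(rnorm(6000, mu2[1], sqrt(s2[1])), rnorm(6000, mu2[2], sqrt(s2[2])))
  analytic <- sum(mu2^2) + sum(s1 + s2 - 2 * sqrt(s1 * s2))
  expect_lt(abs(fid(x1, x2) - analytic) / analytic, 0.1)
  # symmetry within numerical tolerance
  expect_equal(fid(x1, x2), fid(x2, x1), tolerance = 1e-8)
  expect_error(fid(x1, matrix(0, 5, 3)), "dimensions differ")
})

test_that("multivariate Gaussian KL matches Monte Carlo and is directional", {
  p <- list(mean = c(0, 0), cov = diag(c(1, 2)))
  q <- list(mean = c(1, 0), cov = diag(c(2, 2)))
  expect_equal(gaussian_kl(p, p), 0, tolerance = 1e-12)
  set.seed(42)
  x <- cbind(rnorm(1e5, 0, 1), rnorm(1e5, 0, sqrt(2)))
  logr <- (-0.5 * rowSums(x^2 / rep(c(1, 2), each = 1e5)) -
             0.5 * log(4 * pi^2 * 2)) -
    (-0.5 * ((x[, 1] - 1)^2 / 2 + x[, 2]^2 / 2) - 0.5 * log(4 * pi^2 * 4))
  expect_lt(abs(mean(logr) - gaussian_kl(p, q)) / gaussian_kl(p, q), 0.02)
  expect_false(isTRUE(all.equal(gaussian_kl(p, q), gaussian_kl(q, p))))
})

test_that("SSIM matches the reference implementation and its anchors", {
  set.seed(11)
  a <- matrix(runif(24 * 24, 0, 255), 24)
  b <- pmin(pmax(a + matrix(rnorm(24 * 24, 0, 12), 24), 0), 255)
  c_ <- matrix(runif(24 * 24, 0, 255), 24)
  # frozen from scikit-image structural_similarity (gaussian_weights = TRUE,
  # sigma = 1.5, use_sample_covariance = FALSE, data_range = 255)
  expect_equal(ssim(a, b), 0.9860024254, tolerance = 1e-8)
  expect_equal(ssim(a, c_), 0.0333039481, tolerance = 1e-8)
  expect_equal(ssim(a, a), 1.0)
  expect_true(abs(ssim(a, 255 - a)) <= 1)
})

test_that("nearest-SSIM flags duplicates and stays in range", {
  set.seed(43)
  imgs <- lapply(1:5, function(i) matrix(runif(32 * 32, -1, 1), 32))
  imgs[[6]] <- imgs[[2]]                    # exact duplicate pair
  s <- image_set(imgs, "phantom")
  ns_ <- nearest_ssim(s)
  expect_equal(ns_[2], 1.0)
  expect_equal(ns_[6], 1.0)
  expect_true(all(ns_ >= -1 & ns_ <= 1))
  expect_error(nearest_ssim(image_set(imgs[1], "phantom")), "at least 2")
})

test_that("diversity score is 0 on identical sets and positive under duplication", {
  set.seed(44)
  real <- generate_phantoms(phantom_config(n_images = 8, side = 32, seed = 8))
  expect_equal(diversity_score(real, real), 0, tolerance = 1e-10)
  synth <- real
  synth$images[[1]] <- synth$images[[2]]    # inject a duplicate
  expect_gt(diversity_score(real, synth), 0)
  # hand-built lists against the closed form
  expect_equal(swindiff:::gaussian_kl_1d(0.5, 0.04, 0.7, 0.09),
               0.5 * (log(0.09 / 0.04) + (0.04 + 0.04) / 0.09 - 1))
})

test_that("feature-distribution similarity separates clusters and is seeded", {
  cfg_a <- phantom_config(n_images = 12, side = 16, seed = 1,
                          intensity_levels = c(0.7, 0.9), background = -0.9)
  cfg_b <- phantom_config(n_images = 12, side = 16, seed = 2,
                          intensity_levels = c(0.7, 0.9), background = -0.9)
  cfg_c <- phantom_config(n_images = 12, side = 16, seed = 3,
                          intensity_levels = c(-0.5, -0.3), background = 0.6)
  a <- generate_phantoms(cfg_a); b <- generate_phantoms(cfg_b)
  c_ <- generate_phantoms(cfg_c)
  same <- fds(a, b, seed = 5)
  diff_ <- fds(a, c_, seed = 5)
  expect_gt(diff_, 1)
  expect_gt(diff_, same)
  expect_identical(fds(a, c_, seed = 5), diff_)   # rerun-stable
  expect_equal(fds(a, a, seed = 5), 0, tolerance = 1e-8)
})

test_that("extractors obey their contracts and feed a full report", {
  lab <- generate_phantoms(phantom_config(n_images = 48, side = 32, seed = 9),
                           with_labels = TRUE)
  pe <- extractor_toy_classifier(lab, seed = 2)
  probs <- pe$fn(lab)
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 48))
  fe <- extractor_random_projection(dim = 8, seed = 3)
  feats <- fe$fn(lab)
  expect_equal(dim(feats), c(48, 8))
  expect_identical(fe$fn(lab), feats)       # seeded projection is stable
  real <- generate_phantoms(phantom_config(n_images = 12, side = 32, seed = 10))
  synth <- generate_phantoms(phantom_config(n_images = 12, side = 32, seed = 11))
  rep_ <- metric_report(real, synth, fe, pe, seed = 4)
  expect_s3_class(rep_, "metric_report")
  expect_gte(rep_$fid, 0)
  expect_gte(rep_$fds, 0)
  expect_gte(rep_$ds, 0)
  expect_gte(rep_$is_mean, 1)
  expect_identical(rep_$extractor, "random-projection")
  expect_identical(rep_$kl_direction, "real_to_synth")
})
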