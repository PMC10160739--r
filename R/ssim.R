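# Structural similarity with the standard 11x11 Gaussian window (sigma 1.5),
# population covariances, computed on de-normalized 8-bit-equivalent
# intensities (data_range = 255).

gaussian_kernel_1d <- function(sigma = 1.5, radius = 5L) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian filter with reflect ("mirror-without-repeat") padding
gauss_filter2d <- function(img, sigma = 1.5, radius = 5L) {
  k <- gaussian_kernel_1d(sigma, radius)
  h <- nrow(img); w <- ncol(img)
  refl <- function(n) c((radius + 1):2, seq_len(n), (n - 1):(n - radius))
  p <- img[refl(h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(2 * radius + 1))
    out <- out + k[i] * p[i:(i + h - 1), , drop = FALSE]
  p <- out[, refl(w), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_len(2 * radius + 1))
    out2 <- out2 + k[i] * p[, i:(i + w - 1), drop = FALSE]
  out2
}

#' Structural similarity index between two images
#'
#' Gaussian-weighted SSIM (window 11, sigma 1.5, K1 = 0.01, K2 = 0.03),
#' population statistics, border of (win-1)/2 pixels cropped before
#' averaging.
#'
#' @param x,y numeric matrices on the same intensity scale
#' @param data_range dynamic range L of the data (255 for 8-bit-equivalent)
#' @return scalar SSIM in \[-1, 1\]
#' @export
ssim <- function(x, y, data_range = 255) {
  if (!identical(dim(x), dim(y))) stopf("images differ in shape")
  radius <- 5L
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  ux <- gauss_filter2d(x); uy <- gauss_filter2d(y)
  vx <- gauss_filter2d(x * x) - ux^2
  vy <- gauss_filter2d(y * y) - uy^2
  cxy <- gauss_filter2d(x * y) - ux * uy
  S <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  h <- nrow(x); w <- ncol(x)
  mean(S[(radius + 1):(h - radius), (radius + 1):(w - radius)])
}

# map normalized images to the 8-bit-equivalent scale used for SSIM
to_8bit_scale <- function(img, normalized_range) {
  (img - normalized_range[1]) / diff(normalized_range) * 255
}

#' Nearest-neighbour SSIM of every image in a set
#'
#' For each image, the maximum SSIM against every other image in the set
#' (self excluded).
#'
#' @param set an `image_set` with at least 2 images
#' @return numeric vector, one value per image
#' @export
nearest_ssim <- function(set) {
  n <- length(set$images)
  if (n < 2L) stopf("need at least 2 images")
  imgs <- lapply(set$images, to_8bit_scale, set$normalized_range)
  S <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- ssim(imgs[[i]], imgs[[j]])
    S[i, j] <- s; S[j, i] <- s
  }
  apply(S, 1L, max)
}
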