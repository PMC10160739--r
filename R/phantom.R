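#' Phantom generator configuration
#'
#' Anatomy-like toy images: a dark background with a handful of elliptical
#' "organs" at distinct tissue intensities plus Gaussian texture noise, all
#' in \[-1, 1\].  Defaults give 32x32 images with 1-3 ellipses, tissue levels
#' spread over the upper intensity range, and mild texture noise -- enough
#' structure for SSIM windows and feature extractors to latch onto.
#'
#' @param n_images number of images
#' @param side image side (power of two >= 16)
#' @param n_ellipses length-2 integer range of ellipses per image
#' @param intensity_levels tissue-class intensities in (-1, 1\]
#' @param noise_sigma texture noise standard deviation
#' @param background background intensity
#' @param seed RNG seed
#' @return a `phantom_config`
#' @export
phantom_config <- function(n_images = 64, side = 32, n_ellipses = c(1L, 3L),
                           intensity_levels = c(-0.2, 0.2, 0.6, 0.9),
                           noise_sigma = 0.05, background = -0.9, seed = 1L) {
  if (side < 16 || bitwAnd(side, side - 1L) != 0)
    stopf("side must be a power of two >= 16")
  structure(list(n_images = n_images, side = side,
                 n_ellipses = as.integer(n_ellipses),
                 intensity_levels = intensity_levels,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a seeded set of toy phantom images
#'
#' Fully determined by `cfg$seed`.  With `with_labels = TRUE` each image also
#' gets an integer label mask (0 = background, k = index of the tissue class
#' of the top-most ellipse covering the pixel), and the set carries a
#' per-image `class` vector (tissue class of the largest ellipse) used to
#' train the toy classifier extractor.
#'
#' @param cfg a `phantom_config`
#' @param with_labels also return label masks and per-image classes
#' @return an `image_set` (modality "phantom"); with labels, attributes
#'   `label_masks` (list of integer matrices) and `classes` (integer vector)
#' @export
generate_phantoms <- function(cfg = phantom_config(), with_labels = FALSE) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  side <- cfg$side
  xs <- matrix(rep(seq_len(side), each = side), side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), side)  # row index
  images <- vector("list", cfg$n_images)
  masks <- vector("list", cfg$n_images)
  classes <- integer(cfg$n_images)
  margin <- side / 8
  for (i in seq_len(cfg$n_images)) {
    img <- matrix(cfg$background, side, side)
    mask <- matrix(0L, side, side)
    k <- sample(seq(cfg$n_ellipses[1], cfg$n_ellipses[2]), 1)
    best_area <- -1
    for (e in seq_len(k)) {
      cls <- sample(seq_along(cfg$intensity_levels), 1)
      # centers and radii kept inside margins so shapes never clip the border
      a <- stats::runif(1, side / 10, side / 4)       # semi-axes (pixels)
      b <- stats::runif(1, side / 10, side / 4)
      cx <- stats::runif(1, margin + a, side - margin - a)
      cy <- stats::runif(1, margin + b, side - margin - b)
      th <- stats::runif(1, 0, pi)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(th) + dy * sin(th)
      w <- -dx * sin(th) + dy * cos(th)
      inside <- (u / a)^2 + (w / b)^2 <= 1
      img[inside] <- cfg$intensity_levels[cls]
      mask[inside] <- cls
      if (sum(inside) > best_area) { best_area <- sum(inside); classes[i] <- cls }
    }
    if (cfg$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(side^2, 0, cfg$noise_sigma), side)
    images[[i]] <- clip(img, -1, 1)
    masks[[i]] <- mask
  }
  set <- image_set(images, "phantom")
  if (with_labels) {
    attr(set, "label_masks") <- masks
    attr(set, "classes") <- classes
  }
  set
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
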