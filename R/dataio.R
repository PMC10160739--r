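# Modality conventions: fixed source intensity ranges and normalized target
# ranges.  X-rays map [0,255] -> [-1,1]; CT maps the Hounsfield-style window
# [-1024, 3012] -> [0,1]; MRI is min/max normalized per scan to [-1,1];
# phantoms are generated directly in [-1,1].

MODALITIES <- list(
  xray    = list(raw = c(0, 255),      norm = c(-1, 1), per_scan = FALSE),
  ct      = list(raw = c(-1024, 3012), norm = c(0, 1),  per_scan = FALSE),
  mri     = list(raw = NULL,           norm = c(-1, 1), per_scan = TRUE),
  phantom = list(raw = c(-1, 1),       norm = c(-1, 1), per_scan = FALSE)
)

modality_info <- function(modality) {
  m <- MODALITIES[[modality]]
  if (is.null(m)) stopf("unknown modality '%s' (use %s)", modality,
                        paste(names(MODALITIES), collapse = ", "))
  m
}

#' Normalize a raw image into its modality's range
#'
#' Affine map from the modality's source intensity range onto its normalized
#' target range.  X-ray and CT use fixed printed source ranges; MRI uses the
#' per-scan min/max (supply `raw_range` to override).
#'
#' @param image raw 2D numeric matrix
#' @param modality one of "xray", "mri", "ct", "phantom"
#' @param raw_range optional length-2 source range override
#' @return normalized matrix with attribute `raw_range`
#' @export
normalize_image <- function(image, modality, raw_range = NULL) {
  m <- modality_info(modality)
  rr <- raw_range %||% m$raw
  if (is.null(rr)) {                   # per-scan (MRI)
    rr <- range(image)
    if (diff(rr) == 0) stopf("constant %s scan: zero dynamic range", modality)
  }
  nr <- m$norm
  out <- (image - rr[1]) / (rr[2] - rr[1]) * (nr[2] - nr[1]) + nr[1]
  attr(out, "raw_range") <- rr
  out
}

#' Invert the modality normalization
#'
#' Values are first clipped to the normalized range, then the affine map is
#' inverted back to source intensities.
#'
#' @param image normalized matrix
#' @param modality one of "xray", "mri", "ct", "phantom"
#' @param raw_range source range (required for MRI)
#' @return raw-range matrix
#' @export
denormalize_image <- function(image, modality, raw_range = NULL) {
  m <- modality_info(modality)
  rr <- raw_range %||% m$raw %||% attr(image, "raw_range")
  if (is.null(rr)) stopf("raw_range required to denormalize %s", modality)
  nr <- m$norm
  x <- clip(image, nr[1], nr[2])
  out <- (x - nr[1]) / (nr[2] - nr[1]) * (rr[2] - rr[1]) + rr[1]
  attr(out, "raw_range") <- NULL
  out
}

#' A batch of normalized 2D images
#'
#' @param images list of 2D numeric matrices, all the same resolution,
#'   already normalized to the modality's range
#' @param modality one of "xray", "mri", "ct", "phantom"
#' @param raw_range source intensity range (per-set; MRI sets may carry
#'   per-image ranges in `attr(image, "raw_range")`)
#' @param pixel_spacing optional mm pair, carried as metadata only
#' @return an `image_set`
#' @export
image_set <- function(images, modality, raw_range = NULL,
                      pixel_spacing = NULL) {
  m <- modality_info(modality)
  if (length(images) == 0L) stopf("empty image set")
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) stopf("all images must share one resolution")
    if (any(im < m$norm[1] - 1e-9 | im > m$norm[2] + 1e-9))
      stopf("pixel outside normalized range [%g, %g]", m$norm[1], m$norm[2])
  }
  structure(list(images = images, modality = modality,
                 normalized_range = m$norm,
                 raw_range = raw_range %||% m$raw,
                 pixel_spacing = pixel_spacing),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<image_set> %d x (%d x %d) %s images in [%g, %g]\n",
              length(x$images), d[1], d[2], x$modality,
              x$normalized_range[1], x$normalized_range[2]))
  invisible(x)
}

# stack an image_set into an array [H, W, B]
set_to_array <- function(set) {
  d <- dim(set$images[[1]])
  array(unlist(set$images), dim = c(d[1], d[2], length(set$images)))
}

array_to_set <- function(a, modality, ...) {
  image_set(lapply(seq_len(dim(a)[3]), function(i) a[, , i]), modality, ...)
}

#' Conform image geometry to a square target
#'
#' `pad` centers the image inside a `target_side` square using edge-replicate
#' (boundary) padding; `resample` rescales bilinearly.
#'
#' @param image 2D numeric matrix
#' @param target_side side length of the square output
#' @param mode "pad" or "resample"
#' @return `target_side` x `target_side` matrix
#' @export
conform_geometry <- function(image, target_side, mode = c("pad", "resample")) {
  mode <- match.arg(mode)
  h <- nrow(image); w <- ncol(image)
  if (mode == "pad") {
    if (h > target_side || w > target_side)
      stopf("pad mode needs target_side >= both input sides (%d x %d vs %d)",
            h, w, target_side)
    if (h == target_side && w == target_side) return(image)
    top <- floor((target_side - h) / 2); bottom <- target_side - h - top
    left <- floor((target_side - w) / 2); right <- target_side - w - left
    ri <- c(rep(1L, top), seq_len(h), rep(h, bottom))
    ci <- c(rep(1L, left), seq_len(w), rep(w, right))
    image[ri, ci, drop = FALSE]
  } else {
    bilinear_resize(image, target_side, target_side)
  }
}

# bilinear resampling with half-pixel (align_corners = FALSE) convention
bilinear_resize <- function(image, out_h, out_w) {
  h <- nrow(image); w <- ncol(image)
  src <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    p <- clip(p, 0, n_in - 1)
    i0 <- floor(p); f <- p - i0
    list(i0 = i0 + 1, i1 = pmin(i0 + 2, n_in), f = f)
  }
  r <- src(out_h, h); c_ <- src(out_w, w)
  a <- image[r$i0, c_$i0, drop = FALSE] * (1 - r$f) +
       image[r$i1, c_$i0, drop = FALSE] * r$f
  b <- image[r$i0, c_$i1, drop = FALSE] * (1 - r$f) +
       image[r$i1, c_$i1, drop = FALSE] * r$f
  a * rep(1 - c_$f, each = out_h) + b * rep(c_$f, each = out_h)
}

#' Save an image set to a directory with a JSON manifest
#'
#' PNG files store intensities quantized to 8 bits over the normalized range;
#' NIfTI files store de-normalized float32 source intensities.
#'
#' @param set an `image_set`
#' @param dir output directory (created if missing)
#' @param format "png" or "nifti"
#' @return `dir`, invisibly
#' @export
save_image_set <- function(set, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nr <- set$normalized_range
  ext <- if (format == "png") "png" else "nii"
  files <- sprintf("img_%04d.%s", seq_along(set$images), ext)
  for (i in seq_along(set$images)) {
    p <- file.path(dir, files[i])
    if (format == "png") {
      v <- round((set$images[[i]] - nr[1]) / (nr[2] - nr[1]) * 255)
      write_png_gray(clip(v, 0, 255), p)
    } else {
      raw_img <- denormalize_image(set$images[[i]], set$modality,
                                   set$raw_range)
      write_nifti_2d(raw_img, p, set$pixel_spacing %||% c(1, 1))
    }
  }
  manifest <- list(modality = set$modality, format = format,
                   normalized_range = nr, raw_range = set$raw_range,
                   pixel_spacing = set$pixel_spacing, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load an image set saved by [save_image_set()]
#'
#' @param dir directory containing a `manifest.json`
#' @return an `image_set`
#' @export
load_image_set <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stopf("no manifest.json in %s", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  nr <- as.numeric(man$normalized_range)
  images <- lapply(man$files, function(f) {
    p <- file.path(dir, f)
    if (man$format == "png") {
      v <- read_png_gray(p)
      v / 255 * (nr[2] - nr[1]) + nr[1]
    } else {
      raw_img <- read_nifti_2d(p)
      out <- normalize_image(raw_img, man$modality,
                             raw_range = as.numeric(man$raw_range))
      attr(out, "raw_range") <- NULL
      attr(out, "pixel_spacing") <- NULL
      clip(out, nr[1], nr[2])
    }
  })
  image_set(images, man$modality,
            raw_range = if (!is.null(man$raw_range)) as.numeric(man$raw_range),
            pixel_spacing = if (!is.null(man$pixel_spacing))
              as.numeric(man$pixel_spacing))
}
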