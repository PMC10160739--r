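#' Feature and probability extractors
#'
#' Metrics are computed on pluggable extractors: a named transform from an
#' image set to feature rows (for the Frechet distance) or class-probability
#' rows (for the Inception score).  Bundled extractors work fully offline: a
#' seeded random projection and a toy softmax classifier trained on labelled
#' phantoms.  A pretrained classifier (the usual ImageNet Inception) can be
#' plugged in through [extractor_from_function()].
#'
#' @param dim projected feature dimension
#' @param seed seed for the Gaussian projection
#' @return an `extractor` (list with `name`, `type`, `fn`)
#' @export
extractor_random_projection <- function(dim = 16L, seed = 1L) {
  force(dim); force(seed)
  structure(list(
    name = "random-projection", type = "feature",
    fn = function(set) {
      X <- t(apply(set_to_array(set), 3L, identity))
      npix <- ncol(X)
      old <- get_rng_state(); on.exit(restore_rng_state(old))
      set.seed(seed)
      P <- matrix(stats::rnorm(npix * dim), npix, dim) / sqrt(npix)
      unname(X %*% P)
    }), class = "extractor")
}

#' @rdname extractor_random_projection
#' @param train_set labelled phantom set from
#'   `generate_phantoms(..., with_labels = TRUE)`
#' @param epochs,lr training settings of the softmax regression
#' @export
extractor_toy_classifier <- function(train_set, epochs = 300L, lr = 0.5,
                                     seed = 1L) {
  classes <- attr(train_set, "classes")
  if (is.null(classes)) stopf("train_set must carry per-image classes")
  K <- max(classes)
  feat <- function(set) {
    a <- set_to_array(set)
    # 8x8 average-pooled pixels as inputs
    side <- dim(a)[1]
    f <- side %/% 8L
    X <- t(apply(a, 3L, function(m) {
      as.vector(bilinear_resize(m, 8L, 8L))
    }))
    cbind(1, X)
  }
  X <- feat(train_set)
  Yd <- diag(K)[classes, , drop = FALSE]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(ncol(X) * K, 0, 0.01), ncol(X), K)
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    Z <- X %*% W
    Z <- Z - apply(Z, 1L, max)
    Pr <- exp(Z); Pr <- Pr / rowSums(Pr)
    W <- W - lr * (crossprod(X, Pr - Yd) / n + 1e-4 * W)
  }
  structure(list(
    name = "toy-classifier", type = "prob",
    fn = function(set) {
      Z <- feat(set) %*% W
      Z <- Z - apply(Z, 1L, max)
      Pr <- exp(Z)
      unname(Pr / rowSums(Pr))
    }), class = "extractor")
}

#' @rdname extractor_random_projection
#' @param fn function mapping an `image_set` to a numeric row matrix
#' @param name provenance label (e.g. "pretrained-inception")
#' @param type "feature" or "prob"
#' @export
extractor_from_function <- function(fn, name, type = c("feature", "prob")) {
  structure(list(name = name, type = match.arg(type), fn = fn),
            class = "extractor")
}

#' Inception score from class-probability rows
#'
#' Per split, exp(mean KL(row || split marginal)); reported as mean and
#' standard deviation over splits.
#'
#' @param probs matrix of probability rows (non-negative, rows sum to 1)
#' @param n_splits number of splits (default 10)
#' @return c(mean, std)
#' @export
inception_score <- function(probs, n_splits = 10L) {
  if (any(rowSums(probs) < 1e-9)) stopf("probability rows with zero mass")
  probs <- probs / rowSums(probs)
  n <- nrow(probs)
  if (n_splits < 1L || n_splits > n) stopf("n_splits out of range")
  bounds <- floor(linspace(0, n, n_splits + 1L))
  vals <- vapply(seq_len(n_splits), function(s) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    p <- probs[rows, , drop = FALSE]
    marg <- colMeans(p)
    kl <- rowSums(p * (log(pmax(p, 1e-12)) -
                         rep(log(pmax(marg, 1e-12)), each = nrow(p))))
    exp(mean(kl))
  }, numeric(1))
  c(mean = mean(vals), std = if (n_splits > 1L) stats::sd(vals) else 0)
}

#' Fit a Gaussian summary to feature rows
#'
#' @param feats feature row matrix (>= 2 rows)
#' @param ridge diagonal regularization added to the covariance
#' @return list with `mean` and symmetric positive semi-definite `cov`
#' @export
gaussian_fit <- function(feats, ridge = 1e-6) {
  if (nrow(feats) < 2L) stopf("need >= 2 rows to fit a covariance")
  mu <- colMeans(feats)
  S <- stats::cov(feats)
  S <- (S + t(S)) / 2 + ridge * diag(ncol(feats))
  list(mean = mu, cov = S)
}

# symmetric PSD matrix square root via eigen-decomposition, tiny negative
# eigenvalues clipped
sqrtm_psd <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two feature sets
#'
#' ||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^(1/2)) on Gaussians fitted
#' to each set.
#'
#' @param feats_a,feats_b feature row matrices of equal dimension
#' @return scalar >= 0
#' @export
fid <- function(feats_a, feats_b) {
  if (ncol(feats_a) != ncol(feats_b)) stopf("feature dimensions differ")
  ga <- gaussian_fit(feats_a); gb <- gaussian_fit(feats_b)
  sa_half <- sqrtm_psd(ga$cov)
  cross <- sqrtm_psd(sa_half %*% gb$cov %*% sa_half)
  d <- sum((ga$mean - gb$mean)^2) +
    sum(diag(ga$cov)) + sum(diag(gb$cov)) - 2 * sum(diag(cross))
  max(d, 0)
}

#' Closed-form KL divergence between multivariate Gaussians
#'
#' KL( N(mu_p, S_p) || N(mu_q, S_q) ), in nats.
#'
#' @param p,q Gaussian summaries from [gaussian_fit()] (lists with `mean`,
#'   `cov`)
#' @return scalar >= 0
#' @export
gaussian_kl <- function(p, q) {
  k <- length(p$mean)
  ch <- tryCatch(chol(q$cov), error = function(e)
    stopf("q covariance singular even after ridge"))
  qi <- chol2inv(ch)
  dmu <- q$mean - p$mean
  ld_q <- 2 * sum(log(diag(ch)))
  ld_p <- as.numeric(determinant(p$cov, logarithm = TRUE)$modulus)
  0.5 * (sum(qi * p$cov) + drop(t(dmu) %*% qi %*% dmu) - k + ld_q - ld_p)
}

#' Feature-distribution similarity (2D-embedding Gaussian KL)
#'
#' Embeds the pooled real + synthetic images into 2D with t-SNE (one shared
#' embedding, fixed seed), splits the points back into their groups, fits a
#' 2D Gaussian to each, and reports the KL divergence between the fits
#' (direction `real` || `synth` by default).
#'
#' @param real,synth `image_set`s (>= 3 images each)
#' @param seed embedding seed
#' @param direction "real_to_synth" or "synth_to_real"
#' @return scalar >= 0 (0 when the two groups coincide)
#' @export
fds <- function(real, synth, seed = 1L,
                direction = c("real_to_synth", "synth_to_real")) {
  direction <- match.arg(direction)
  n_r <- length(real$images); n_s <- length(synth$images)
  if (n_r < 3L || n_s < 3L) stopf("groups too small to fit a covariance")
  X <- rbind(t(apply(set_to_array(real), 3L, identity)),
             t(apply(set_to_array(synth), 3L, identity)))
  # a multiset has one location per distinct point: embed unique rows and
  # map duplicates onto their representative, so identical real/synthetic
  # sets yield exactly coinciding groups (and KL exactly 0)
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  uid <- match(key, key)
  uniq <- sort(unique(uid))
  Yu <- tsne_embed2d(X[uniq, , drop = FALSE], seed = seed)
  Y <- Yu[match(uid, uniq), , drop = FALSE]
  gr <- gaussian_fit(Y[seq_len(n_r), , drop = FALSE])
  gs <- gaussian_fit(Y[n_r + seq_len(n_s), , drop = FALSE])
  if (direction == "real_to_synth") gaussian_kl(gr, gs)
  else gaussian_kl(gs, gr)
}

#' Diversity score (nearest-SSIM distribution KL)
#'
#' Computes each set's nearest-SSIM values, fits a 1D Gaussian to each list
#' (variance floored at 1e-8), and reports the closed-form KL
#' (`real` || `synth` by default).
#'
#' @param real,synth `image_set`s (>= 3 images each)
#' @param direction "real_to_synth" or "synth_to_real"
#' @return scalar >= 0
#' @export
diversity_score <- function(real, synth,
                            direction = c("real_to_synth", "synth_to_real")) {
  direction <- match.arg(direction)
  if (length(real$images) < 3L || length(synth$images) < 3L)
    stopf("need >= 3 images per set")
  a <- nearest_ssim(real); b <- nearest_ssim(synth)
  va <- max(stats::var(a), 1e-8); vb <- max(stats::var(b), 1e-8)
  if (direction == "real_to_synth")
    gaussian_kl_1d(mean(a), va, mean(b), vb)
  else gaussian_kl_1d(mean(b), vb, mean(a), va)
}

#' Full metric report for a real/synthetic pair of image sets
#'
#' @param real,synth `image_set`s
#' @param feature_extractor extractor with type "feature" (for FID)
#' @param prob_extractor optional extractor with type "prob" (for IS of the
#'   synthetic set); IS is NA when absent
#' @param seed embedding seed for FDS
#' @param n_splits Inception-score splits
#' @param direction KL direction for FDS and DS
#' @return a `metric_report` list: `is_mean`, `is_std`, `fid`, `fds`, `ds`,
#'   `n_real`, `n_synth`, `extractor`, `embedding_seed`, `kl_direction`
#' @export
metric_report <- function(real, synth, feature_extractor,
                          prob_extractor = NULL, seed = 1L, n_splits = 10L,
                          direction = "real_to_synth") {
  is_val <- c(NA_real_, NA_real_)
  if (!is.null(prob_extractor)) {
    probs <- prob_extractor$fn(synth)
    is_val <- inception_score(probs, min(n_splits, nrow(probs)))
  }
  fid_val <- fid(feature_extractor$fn(real), feature_extractor$fn(synth))
  fds_val <- fds(real, synth, seed = seed, direction = direction)
  ds_val <- diversity_score(real, synth, direction = direction)
  structure(list(is_mean = unname(is_val[1]), is_std = unname(is_val[2]),
                 fid = fid_val, fds = fds_val, ds = ds_val,
                 n_real = length(real$images), n_synth = length(synth$images),
                 extractor = feature_extractor$name, embedding_seed = seed,
                 kl_direction = direction),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> n_real = %d, n_synth = %d (%s)\n",
                     "  IS  (up):   %s\n  FID (down): %.4f\n",
                     "  FDS (down): %.4f\n  DS  (down): %.4f\n"),
              x$n_real, x$n_synth, x$extractor,
              if (is.na(x$is_mean)) "NA"
              else sprintf("%.3f +/- %.3f", x$is_mean, x$is_std),
              x$fid, x$fds, x$ds))
  invisible(x)
}
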