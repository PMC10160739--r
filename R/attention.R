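#' Multi-head attention weights
#'
#' Per-head query/key/value projections and a shared output projection.  The
#' per-head matrices are the column blocks of C x C matrices `wq`, `wk`,
#' `wv`; `wo` maps the concatenated heads back to C channels.
#'
#' @param C channel count
#' @param n_heads number of heads M (must divide C); the per-head key
#'   dimension d = C / M is used in the 1/sqrt(d) scaling
#' @param seed RNG seed for the Gaussian init
#' @return an `attention_weights` list
#' @export
attention_weights <- function(C, n_heads = 4L, seed = 1L) {
  if (C %% n_heads != 0) stopf("n_heads must divide C")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  structure(list(wq = init_lin(C, C), wk = init_lin(C, C),
                 wv = init_lin(C, C), wo = init_lin(C, C),
                 n_heads = as.integer(n_heads), d = C %/% n_heads),
            class = "attention_weights")
}

#' Partition a feature map into non-overlapping l x l windows
#'
#' @param f H x W x C array
#' @param l window side (must divide H and W)
#' @param shifted cyclically shift the map by (l/2, l/2) before partitioning
#' @return list of l^2 x C token matrices, row-major within each window
#' @export
window_partition <- function(f, l, shifted = FALSE) {
  d <- dim(f); H <- d[1]; W <- d[2]; C <- d[3]
  if (H %% l != 0 || W %% l != 0)
    stopf("H = %d, W = %d not divisible by window size l = %d", H, W, l)
  flat <- matrix(aperm(f, c(2, 1, 3)), nrow = H * W, ncol = C) # row-major rows
  win <- window_geom(1L, H, W, l, shifted)
  lapply(seq_len(ncol(win)), function(g) flat[win[, g], , drop = FALSE])
}

#' Merge windows back into a feature map (inverse of [window_partition()])
#'
#' @param windows list of l^2 x C matrices
#' @param H,W feature map size
#' @param l window side
#' @param shifted undo the cyclic shift
#' @return H x W x C array
#' @export
window_merge <- function(windows, H, W, l, shifted = FALSE) {
  C <- ncol(windows[[1]])
  win <- window_geom(1L, H, W, l, shifted)
  flat <- matrix(0, H * W, C)
  for (g in seq_along(windows)) flat[win[, g], ] <- windows[[g]]
  aperm(array(flat, dim = c(W, H, C)), c(2, 1, 3))
}

#' Windowed multi-head self-attention
#'
#' Partitions the feature map into non-overlapping l x l windows (cyclically
#' shifted by (l/2, l/2) for the shifted variant), runs multi-head softmax
#' self-attention over the l^2 tokens of each window with 1/sqrt(d) scaling,
#' applies the output projection, and merges the windows back.  No attention
#' masking is applied across wrapped edges.  The refinement fully-connected
#' layer that follows each attention pass in the network is a separate
#' parameter and is not part of this primitive.
#'
#' @param f H x W x C array
#' @param w an `attention_weights`
#' @param l window side
#' @param shifted use the shifted-window variant
#' @return H x W x C array
#' @export
window_mhsa <- function(f, w, l, shifted = FALSE) {
  d <- dim(f); H <- d[1]; W <- d[2]; C <- d[3]
  wins <- window_partition(f, l, shifted)
  M <- w$n_heads; dk <- w$d
  out <- lapply(wins, function(x) {
    q <- x %*% w$wq; k <- x %*% w$wk; v <- x %*% w$wv
    heads <- matrix(0, nrow(x), C)
    for (m in seq_len(M)) {
      cols <- ((m - 1L) * dk + 1L):(m * dk)
      s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dk)
      s <- s - apply(s, 1L, max)
      a <- exp(s); a <- a / rowSums(a)
      heads[, cols] <- a %*% v[, cols, drop = FALSE]
    }
    heads %*% w$wo
  })
  window_merge(out, H, W, l, shifted)
}
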