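# A small reverse-mode tape. Feature maps are stored as (B*H*W) x C matrices
# with rows ordered image-major, then row-major within each image
# (row index = (b-1)*H*W + (i-1)*W + j). Each op appends a node holding the
# value plus a backward closure mapping the output gradient to parent
# gradients.  Running forward without ever calling tape_backward() is plain
# inference.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 2048L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, value, parents = integer(), backward = NULL,
                    param = NULL, cache = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", tp$n))
  tp$nodes[[tp$n]] <- list(value = value, parents = parents,
                           backward = backward, param = param, cache = cache)
  tp$n
}

# NB: force id before touching tp$nodes -- a lazily evaluated id expression
# may itself append a node to the tape (e.g. tp_input(...) inlined at a call
# site), and `tp$nodes[[id]]` would otherwise index a stale copy of the list.
tp_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

tp_input <- function(tp, value) tp_node(tp, value)
tp_param <- function(tp, value, name) tp_node(tp, value, param = name)

# run reverse pass from seed gradients (named list: node id -> gradient);
# returns named list of parameter gradients
tape_backward <- function(tp, seeds) {
  grads <- vector("list", tp$n)
  for (nm in names(seeds)) grads[[as.integer(nm)]] <- seeds[[nm]]
  for (id in tp$n:1) {
    g <- grads[[id]]
    node <- tp$nodes[[id]]
    if (is.null(g) || is.null(node$backward)) next
    contrib <- node$backward(g, node)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(contrib[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) contrib[[k]]
                    else grads[[p]] + contrib[[k]]
    }
  }
  out <- list()
  for (id in seq_len(tp$n)) {
    p <- tp$nodes[[id]]$param
    if (!is.null(p)) out[[p]] <- grads[[id]] %||%
        array(0, dim = dim(tp$nodes[[id]]$value) %||%
                length(tp$nodes[[id]]$value))
  }
  out
}

## ---- elementwise and linear ops ----

tp_add <- function(tp, a, b) {
  tp_node(tp, tp_value(tp, a) + tp_value(tp, b), c(a, b),
          function(g, node) list(g, g))
}

tp_silu <- function(tp, a) {
  x <- tp_value(tp, a)
  s <- 1 / (1 + exp(-x))
  tp_node(tp, x * s, a,
          function(g, node) {
            cc <- node$cache
            list(g * (cc$s * (1 + cc$x * (1 - cc$s))))
          },
          cache = list(x = x, s = s))
}

tp_matmul <- function(tp, a, b) {
  av <- tp_value(tp, a); bv <- tp_value(tp, b)
  tp_node(tp, av %*% bv, c(a, b),
          function(g, node) {
            cc <- node$cache
            list(g %*% t(cc$b), crossprod(cc$a, g))
          },
          cache = list(a = av, b = bv))
}

# add a length-C bias row-broadcast over all rows
tp_add_bias <- function(tp, a, bias) {
  av <- tp_value(tp, a); bv <- tp_value(tp, bias)
  tp_node(tp, sweep(av, 2L, bv, "+"), c(a, bias),
          function(g, node) list(g, colSums(g)))
}

tp_linear <- function(tp, x, w, b = NULL) {
  y <- tp_matmul(tp, x, w)
  if (!is.null(b)) y <- tp_add_bias(tp, y, b)
  y
}

tp_concat_cols <- function(tp, a, b) {
  av <- tp_value(tp, a); bv <- tp_value(tp, b)
  ca <- ncol(av)
  tp_node(tp, cbind(av, bv), c(a, b),
          function(g, node) {
            cc <- node$cache
            list(g[, seq_len(cc$ca), drop = FALSE],
                 g[, -seq_len(cc$ca), drop = FALSE])
          },
          cache = list(ca = ca))
}

## ---- geometry caches ----

.geom_cache <- new.env(parent = emptyenv())

# row indices of 3x3 neighbourhoods with a phantom zero row (index N+1) for
# out-of-bounds offsets, plus per-row image ids, for a (B, H, W) layout
conv_geom <- function(B, H, W) {
  key <- paste("conv", B, H, W, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  N <- B * H * W
  ii <- rep(rep(seq_len(H), each = W), times = B)
  jj <- rep(rep(seq_len(W), times = H), times = B)
  bb <- rep(seq_len(B), each = H * W)
  idx <- vector("list", 9L)
  k <- 0L
  for (di in -1:1) for (dj in -1:1) {
    k <- k + 1L
    ri <- ii + di; cj <- jj + dj
    ok <- ri >= 1 & ri <= H & cj >= 1 & cj <= W
    id <- (bb - 1L) * H * W + (ri - 1L) * W + cj
    id[!ok] <- N + 1L
    idx[[k]] <- id
  }
  idxmat <- matrix(0L, N, 9L)
  for (k in 1:9) idxmat[, k] <- as.integer(idx[[k]])
  g <- list(B = B, H = H, W = W, N = N, idx = idx, idxmat = idxmat, img = bb)
  .geom_cache[[key]] <- g
  g
}

# windowed row grouping for attention: matrix (l*l) x n_windows of row indices;
# shifted variant cyclically shifts the map by (l/2, l/2) before partitioning
window_geom <- function(B, H, W, l, shifted) {
  key <- paste("win", B, H, W, l, shifted, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  s <- if (shifted) l %/% 2L else 0L
  rows <- matrix(0L, nrow = l * l,
                 ncol = B * (H %/% l) * (W %/% l))
  col <- 0L
  for (b in seq_len(B)) for (wi in seq_len(H %/% l)) for (wj in seq_len(W %/% l)) {
    col <- col + 1L
    r0 <- (wi - 1L) * l; c0 <- (wj - 1L) * l
    cell <- 0L
    for (i in seq_len(l)) for (j in seq_len(l)) {
      cell <- cell + 1L
      # cyclic shift: window coordinates map to original rows/cols shifted by s
      ri <- ((r0 + i - 1L + s) %% H) + 1L
      cj <- ((c0 + j - 1L + s) %% W) + 1L
      rows[cell, col] <- (b - 1L) * H * W + (ri - 1L) * W + cj
    }
  }
  .geom_cache[[key]] <- rows
  rows
}

# bilinear up / 2x2-average down resampling as sparse row maps:
# out[n, ] = sum_p w[[p]][n] * in[src[[p]][n], ]
resize_geom <- function(B, H, W, mode) {
  key <- paste("rs", B, H, W, mode, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  if (mode == "down") {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    ii <- rep(rep(seq_len(H2), each = W2), times = B)
    jj <- rep(rep(seq_len(W2), times = H2), times = B)
    bb <- rep(seq_len(B), each = H2 * W2)
    base <- function(di, dj) (bb - 1L) * H * W + (2L * ii - 2L + di) * W +
      (2L * jj - 1L + dj)
    src <- list(base(0L, 0L), base(0L, 1L), base(1L, 0L), base(1L, 1L))
    n <- length(src[[1]])
    w <- rep(list(rep(0.25, n)), 4L)
    out <- list(src = src, w = w, H = H2, W = W2, N_in = B * H * W,
                injective = TRUE)
  } else {
    H2 <- H * 2L; W2 <- W * 2L
    ii <- rep(rep(seq_len(H2), each = W2), times = B)
    jj <- rep(rep(seq_len(W2), times = H2), times = B)
    bb <- rep(seq_len(B), each = H2 * W2)
    coord <- function(p, n_in) {        # half-pixel mapping, clamped
      x <- (p - 0.5) / 2 - 0.5
      x <- clip(x, 0, n_in - 1)
      i0 <- floor(x)
      list(i0 = i0 + 1, i1 = pmin(i0 + 2, n_in), f = x - i0)
    }
    ry <- coord(ii, H); rx <- coord(jj, W)
    at <- function(r, c) (bb - 1L) * H * W + (r - 1L) * W + c
    src <- list(at(ry$i0, rx$i0), at(ry$i0, rx$i1),
                at(ry$i1, rx$i0), at(ry$i1, rx$i1))
    w <- list((1 - ry$f) * (1 - rx$f), (1 - ry$f) * rx$f,
              ry$f * (1 - rx$f), ry$f * rx$f)
    out <- list(src = src, w = w, H = H2, W = W2, N_in = B * H * W,
                injective = FALSE)
  }
  .geom_cache[[key]] <- out
  out
}

## ---- structured ops ----

tp_conv3x3 <- function(tp, x, w, b, geom) {
  xv <- tp_value(tp, x)
  wv <- tp_value(tp, w)
  y <- cpp_conv3x3_fw(xv, geom$idxmat, wv, tp_value(tp, b))
  tp_node(tp, y, c(x, w, b),
          function(g, node) {
            cc <- node$cache
            r <- cpp_conv3x3_bw(cc$xv, g, cc$geom$idxmat, cc$wv)
            list(r$dx, r$dw, as.vector(r$db))
          },
          cache = list(xv = xv, wv = wv, geom = geom))
}

tp_groupnorm <- function(tp, x, gamma, beta, geom, groups, eps = 1e-5) {
  xv <- tp_value(tp, x)
  C <- ncol(xv)
  if (C %% groups != 0) stopf("groupnorm: %d channels not divisible by %d groups",
                              C, groups)
  gv <- tp_value(tp, gamma)
  fw <- cpp_groupnorm_fw(xv, geom$B, groups, gv, tp_value(tp, beta), eps)
  tp_node(tp, fw$y, c(x, gamma, beta),
          function(g, node) {
            cc <- node$cache
            r <- cpp_groupnorm_bw(g, cc$xhat, cc$inv_sd, cc$gv, cc$B, cc$groups)
            list(r$dx, as.vector(r$dgamma), as.vector(r$dbeta))
          },
          cache = list(xhat = fw$xhat, inv_sd = fw$inv_sd, gv = gv,
                       B = geom$B, groups = groups))
}

# broadcast-add a per-image embedding row (B x C) over all pixels
tp_add_time <- function(tp, x, temb, geom) {
  xv <- tp_value(tp, x); tv <- tp_value(tp, temb)
  tp_node(tp, xv + tv[geom$img, , drop = FALSE], c(x, temb),
          function(g, node) {
            cc <- node$cache
            list(g, rowsum(g, cc$img, reorder = TRUE))
          },
          cache = list(img = geom$img))
}

tp_resize <- function(tp, x, rs) {
  xv <- tp_value(tp, x)
  y <- rs$w[[1]] * xv[rs$src[[1]], , drop = FALSE]
  for (p in 2:4) y <- y + rs$w[[p]] * xv[rs$src[[p]], , drop = FALSE]
  tp_node(tp, y, x,
          function(g, node) {
            cc <- node$cache
            dX <- matrix(0, cc$rs$N_in, ncol(g))
            for (p in 1:4) {
              tmp <- cc$rs$w[[p]] * g
              if (cc$rs$injective) {
                id <- cc$rs$src[[p]]
                dX[id, ] <- dX[id, ] + tmp
              } else {
                acc <- rowsum(tmp, cc$rs$src[[p]], reorder = FALSE)
                ids <- as.integer(rownames(acc))
                dX[ids, ] <- dX[ids, ] + acc
              }
            }
            list(dX)
          },
          cache = list(rs = rs))
}

# multi-head softmax self-attention within precomputed windows.
# q, k, v: (N x C) nodes; win: (l^2 x n_win) row-index matrix
tp_window_attn <- function(tp, q, k, v, win, n_heads) {
  qv <- tp_value(tp, q); kv <- tp_value(tp, k); vv <- tp_value(tp, v)
  C <- ncol(qv)
  if (C %% n_heads != 0) stopf("channels %d not divisible by %d heads", C, n_heads)
  fw <- cpp_window_attn_fw(qv, kv, vv, win, n_heads)
  tp_node(tp, fw$y, c(q, k, v),
          function(gr, node) {
            cc <- node$cache
            r <- cpp_window_attn_bw(gr, cc$qv, cc$kv, cc$vv, cc$win,
                                    cc$n_heads, cc$A)
            list(r$dq, r$dk, r$dv)
          },
          cache = list(qv = qv, kv = kv, vv = vv, win = win,
                       n_heads = n_heads, A = fw$A))
}

## ---- array <-> row-matrix layout helpers ----

# array [H, W, B] (or matrix H x W) -> (B*H*W) x 1 matrix, row-major per image
img_to_rows <- function(a) {
  if (is.matrix(a)) return(matrix(as.vector(t(a)), ncol = 1L))
  matrix(as.vector(aperm(a, c(2L, 1L, 3L))), ncol = 1L)
}

# (B*H*W) x 1 matrix -> array [H, W, B]
rows_to_img <- function(m, H, W, B) {
  aperm(array(as.vector(m), dim = c(W, H, B)), c(2L, 1L, 3L))
}
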