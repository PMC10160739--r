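#' Denoiser network configuration
#'
#' A U-shaped encoder-decoder that maps (noisy image, timestep) to a noise
#' estimate and a raw variance-interpolation output.  The full depth plan is
#' 2 convolutional down-blocks, 4 Swin-transformer down-blocks, 3 middle Swin
#' blocks, then 4 Swin up-blocks and 2 convolutional up-blocks; the reduced
#' plan (for small test images) is 2 conv-down + 2 swin-down, 1 middle,
#' mirrored.  Channel widths start at `round(base_channels *
#' width_multiplier)` at the stem, double at each down-sampling stage, and cap
#' at 8x the stem width; the decoder mirrors the encoder.  Shortcut
#' connections concatenate encoder features into the matching decoder stage.
#'
#' @param base_channels width of the first convolutional stage before the
#'   multiplier (default 128 for the full plan)
#' @param width_multiplier scales every stage's channel count, in (0, 1];
#'   the 25/50/75/100 percent ablation knob
#' @param window_size attention window side l (clamped to the feature side at
#'   each stage)
#' @param num_heads attention heads M
#' @param time_embed_dim sinusoidal timestep embedding width (default 128)
#' @param time_embed_max_period largest sinusoid period (default 1e6)
#' @param groupnorm_groups group-normalization groups (default 32; must
#'   divide every stage width)
#' @param depth "full" or "reduced"
#' @return a `network_config`
#' @export
network_config <- function(base_channels = 128L, width_multiplier = 1,
                           window_size = 8L, num_heads = 4L,
                           time_embed_dim = 128L,
                           time_embed_max_period = 1e6,
                           groupnorm_groups = 32L,
                           depth = c("full", "reduced")) {
  depth <- match.arg(depth)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stopf("width_multiplier must be in (0, 1]")
  stem <- as.integer(round(base_channels * width_multiplier))
  if (stem < 1L) stopf("stem width rounds to zero")
  plan <- if (depth == "full")
    list(enc_conv = 2L, enc_swin = 4L, middle = 3L)
  else list(enc_conv = 2L, enc_swin = 2L, middle = 1L)
  nstage <- plan$enc_conv + plan$enc_swin
  ch <- stem * pmin(2^(0:nstage), 8L)         # ch[1] = stem, cap 8x
  for (c_ in ch) if (c_ %% groupnorm_groups != 0 && c_ > groupnorm_groups)
    stopf("groupnorm_groups = %d does not divide stage width %d",
          groupnorm_groups, c_)
  if (any(ch %% groupnorm_groups != 0))
    stopf("groupnorm_groups = %d must divide every stage width (%s)",
          groupnorm_groups, paste(ch, collapse = ", "))
  structure(list(base_channels = as.integer(base_channels),
                 width_multiplier = width_multiplier,
                 window_size = as.integer(window_size),
                 num_heads = as.integer(num_heads),
                 time_embed_dim = as.integer(time_embed_dim),
                 time_embed_max_period = time_embed_max_period,
                 groupnorm_groups = as.integer(groupnorm_groups),
                 depth = depth, plan = plan, channels = ch),
            class = "network_config")
}

#' A compact preset for <= 64 px test images
#'
#' Reduced depth, narrow channels, small attention windows and 4
#' group-normalization groups, sized so desk-scale CPU training is feasible.
#'
#' @param width_multiplier width knob, default 0.125 (4 stem channels)
#' @return a `network_config`
#' @export
network_config_toy <- function(width_multiplier = 0.125) {
  network_config(base_channels = 32L, width_multiplier = width_multiplier,
                 window_size = 4L, num_heads = 2L, time_embed_dim = 32L,
                 groupnorm_groups = 4L, depth = "reduced")
}

#' Sinusoidal timestep embedding
#'
#' First half sine, second half cosine, at geometrically spaced frequencies
#' from 1 down to 1/max_period: component k (0-based) of the sine half is
#' sin(t * max_period^(-2k/dim)).
#'
#' @param t timestep (scalar or vector, >= 0)
#' @param dim embedding dimension (even)
#' @param max_period largest period
#' @return a length-`dim` vector, or a `length(t)` x `dim` matrix
#' @export
sinusoidal_embed <- function(t, dim = 128L, max_period = 1e6) {
  if (dim %% 2L != 0L) stopf("embedding dim must be even")
  if (any(t < 0)) stopf("t must be >= 0")
  half <- dim %/% 2L
  freqs <- max_period^(-2 * (seq_len(half) - 1) / dim)
  arg <- outer(t, freqs)
  out <- cbind(sin(arg), cos(arg))
  if (length(t) == 1L) drop(out) else out
}

## ---- parameter initialization ----

init_conv <- function(shape9, cin, cout, scale = 1) {
  matrix(stats::rnorm(9 * cin * cout, 0, scale * sqrt(2 / (9 * cin))),
         nrow = 9 * cin, ncol = cout)
}
init_lin <- function(cin, cout, scale = 1) {
  matrix(stats::rnorm(cin * cout, 0, scale / sqrt(cin)), cin, cout)
}

# deterministic parameter naming: <path>.<layer>.<w|b|gamma|beta>
add_conv <- function(P, name, cin, cout, zero = FALSE) {
  P[[paste0(name, ".w")]] <- if (zero) matrix(0, 9 * cin, cout)
                             else init_conv(NULL, cin, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}
add_lin <- function(P, name, cin, cout, zero = FALSE) {
  P[[paste0(name, ".w")]] <- if (zero) matrix(0, cin, cout)
                             else init_lin(cin, cout)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}
add_gn <- function(P, name, c_) {
  P[[paste0(name, ".gamma")]] <- rep(1, c_)
  P[[paste0(name, ".beta")]] <- numeric(c_)
  P
}

add_conv_section <- function(P, name, cin, cout, tdim) {
  P <- add_gn(P, paste0(name, ".gn0"), cin)
  P <- add_conv(P, paste0(name, ".conv0"), cin, cout)
  P <- add_lin(P, paste0(name, ".time"), tdim, cout)
  P <- add_gn(P, paste0(name, ".gn1"), cout)
  P <- add_conv(P, paste0(name, ".conv1"), cout, cout)
  P <- add_gn(P, paste0(name, ".gn2"), cout)
  P <- add_conv(P, paste0(name, ".conv2"), cout, cout)
  P
}

add_swin_section <- function(P, name, cin, cout, tdim) {
  P <- add_gn(P, paste0(name, ".gn0"), cin)
  P <- add_conv(P, paste0(name, ".conv0"), cin, cout)
  P <- add_lin(P, paste0(name, ".time"), tdim, cout)
  for (att in c("wa", "swa")) {
    P <- add_gn(P, paste0(name, ".", att, ".gn"), cout)
    for (pr in c("q", "k", "v", "o"))
      P <- add_lin(P, paste0(name, ".", att, ".", pr), cout, cout)
    P <- add_lin(P, paste0(name, ".", att, ".fc"), cout, cout)
  }
  P
}

block_names <- function(cfg) {
  plan <- cfg$plan
  enc <- c(sprintf("enc.conv%d", seq_len(plan$enc_conv)),
           sprintf("enc.swin%d", seq_len(plan$enc_swin)))
  mid <- sprintf("mid%d", seq_len(plan$middle))
  dec <- c(sprintf("dec.swin%d", rev(seq_len(plan$enc_swin))),
           sprintf("dec.conv%d", rev(seq_len(plan$enc_conv))))
  list(enc = enc, mid = mid, dec = dec)
}

#' Initialize a denoiser model
#'
#' Builds the flat named-parameter list for a configuration; fully seeded.
#' All layers (including the two output heads) use fan-in-scaled Gaussian
#' init; zero-initializing the heads -- a convention from very long GPU
#' training runs -- blocks every trunk gradient until the head grows and is
#' a poor fit for short CPU runs (see the methods vignette).
#'
#' @param cfg a `network_config`
#' @param seed RNG seed
#' @return a `denoiser_model` list with `params` (named list) and `cfg`
#' @export
init_denoiser <- function(cfg, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  plan <- cfg$plan
  ch <- cfg$channels                     # ch[s+1] = width of stage s
  tdim <- cfg$time_embed_dim
  P <- list()
  P <- add_lin(P, "temb.fc1", tdim, tdim)
  P <- add_lin(P, "temb.fc2", tdim, tdim)
  P <- add_conv(P, "stem", 1L, ch[1])
  nstage <- plan$enc_conv + plan$enc_swin
  nm <- block_names(cfg)
  for (s in seq_len(nstage)) {           # encoder blocks, downsample in last section
    base <- nm$enc[s]
    is_conv <- s <= plan$enc_conv
    nsec <- if (is_conv) 3L else 2L
    for (sec in seq_len(nsec)) {
      cin <- if (sec == 1L) ch[s] else ch[s + 1]
      addf <- if (is_conv) add_conv_section else add_swin_section
      P <- addf(P, sprintf("%s.s%d", base, sec), cin, ch[s + 1], tdim)
    }
  }
  for (m in seq_len(plan$middle))
    for (sec in 1:2)
      P <- add_swin_section(P, sprintf("%s.s%d", nm$mid[m], sec),
                            ch[nstage + 1], ch[nstage + 1], tdim)
  for (k in seq_len(nstage)) {           # decoder blocks, upsample in last section
    s <- nstage - k + 1L                 # mirrored stage index
    base <- nm$dec[k]
    is_conv <- s <= plan$enc_conv
    nsec <- if (is_conv) 3L else 2L
    for (sec in seq_len(nsec)) {
      cin <- if (sec == 1L) 2L * ch[s + 1] else ch[s + 1]
      cout <- if (sec == nsec) ch[s] else ch[s + 1]
      addf <- if (is_conv) add_conv_section else add_swin_section
      P <- addf(P, sprintf("%s.s%d", base, sec), cin, cout, tdim)
    }
  }
  P <- add_gn(P, "head.gn", 2L * ch[1])
  P <- add_conv(P, "head.eps", 2L * ch[1], 1L)
  P <- add_gn(P, "head_v.gn", 2L * ch[1])
  P <- add_conv(P, "head.v", 2L * ch[1], 1L)
  structure(list(params = P, cfg = cfg), class = "denoiser_model")
}

#' @export
print.denoiser_model <- function(x, ...) {
  cat(sprintf("<denoiser_model> depth = %s, stem = %d ch, %d tensors, %s parameters\n",
              x$cfg$depth, x$cfg$channels[1], length(x$params),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of parameters in a model
#' @param model a `denoiser_model`
#' @return integer count
#' @export
count_params <- function(model) sum(vapply(model$params, length, numeric(1)))

## ---- forward pass ----

# registry mapping parameter names to tape node ids, created per forward
param_nodes <- function(tp, params) {
  ids <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, tp_param(tp, params[[nm]], nm), ids)
  function(nm) get(nm, ids)
}

fw_conv_section <- function(tp, pid, x, temb, name, geom, resize = NULL) {
  if (!is.null(resize)) {
    x <- tp_resize(tp, x, resize$rs)
    geom <- resize$geom
  }
  h <- tp_groupnorm(tp, x, pid(paste0(name, ".gn0.gamma")),
                    pid(paste0(name, ".gn0.beta")), geom, attr(geom, "groups"))
  h <- tp_silu(tp, h)
  h0 <- tp_conv3x3(tp, h, pid(paste0(name, ".conv0.w")),
                   pid(paste0(name, ".conv0.b")), geom)
  tproj <- tp_linear(tp, temb, pid(paste0(name, ".time.w")),
                     pid(paste0(name, ".time.b")))
  h <- tp_add_time(tp, h0, tproj, geom)
  h <- tp_groupnorm(tp, h, pid(paste0(name, ".gn1.gamma")),
                    pid(paste0(name, ".gn1.beta")), geom, attr(geom, "groups"))
  h <- tp_silu(tp, h)
  h <- tp_conv3x3(tp, h, pid(paste0(name, ".conv1.w")),
                  pid(paste0(name, ".conv1.b")), geom)
  h <- tp_groupnorm(tp, h, pid(paste0(name, ".gn2.gamma")),
                    pid(paste0(name, ".gn2.beta")), geom, attr(geom, "groups"))
  h <- tp_silu(tp, h)
  h <- tp_conv3x3(tp, h, pid(paste0(name, ".conv2.w")),
                  pid(paste0(name, ".conv2.b")), geom)
  list(out = tp_add(tp, h, h0), geom = geom)   # residual: early conv -> output
}

fw_attention <- function(tp, pid, x, name, geom, l, n_heads, shifted) {
  g <- tp_groupnorm(tp, x, pid(paste0(name, ".gn.gamma")),
                    pid(paste0(name, ".gn.beta")), geom, attr(geom, "groups"))
  q <- tp_linear(tp, g, pid(paste0(name, ".q.w")), pid(paste0(name, ".q.b")))
  k <- tp_linear(tp, g, pid(paste0(name, ".k.w")), pid(paste0(name, ".k.b")))
  v <- tp_linear(tp, g, pid(paste0(name, ".v.w")), pid(paste0(name, ".v.b")))
  win <- window_geom(geom$B, geom$H, geom$W, l, shifted)
  a <- tp_window_attn(tp, q, k, v, win, n_heads)
  a <- tp_linear(tp, a, pid(paste0(name, ".o.w")), pid(paste0(name, ".o.b")))
  a <- tp_linear(tp, a, pid(paste0(name, ".fc.w")), pid(paste0(name, ".fc.b")))
  tp_add(tp, x, a)                             # residual around attention
}

fw_swin_section <- function(tp, pid, x, temb, name, geom, l, n_heads,
                            resize = NULL) {
  if (!is.null(resize)) {
    x <- tp_resize(tp, x, resize$rs)
    geom <- resize$geom
  }
  l_eff <- min(l, geom$H, geom$W)
  h <- tp_groupnorm(tp, x, pid(paste0(name, ".gn0.gamma")),
                    pid(paste0(name, ".gn0.beta")), geom, attr(geom, "groups"))
  h <- tp_silu(tp, h)
  h0 <- tp_conv3x3(tp, h, pid(paste0(name, ".conv0.w")),
                   pid(paste0(name, ".conv0.b")), geom)
  tproj <- tp_linear(tp, temb, pid(paste0(name, ".time.w")),
                     pid(paste0(name, ".time.b")))
  h <- tp_add_time(tp, h0, tproj, geom)
  h <- fw_attention(tp, pid, h, paste0(name, ".wa"), geom, l_eff, n_heads,
                    shifted = FALSE)
  h <- fw_attention(tp, pid, h, paste0(name, ".swa"), geom, l_eff, n_heads,
                    shifted = TRUE)
  list(out = h, geom = geom)
}

mk_geom <- function(B, H, W, groups) {
  g <- conv_geom(B, H, W)
  attr(g, "groups") <- groups
  g
}

# Full forward pass on the tape.  x: array [H, W, B] (or matrix for B = 1);
# t: integer vector length B.  Returns node ids of the two heads plus tape.
denoiser_forward_tape <- function(model, x, t) {
  cfg <- model$cfg
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  H <- dim(x)[1]; W <- dim(x)[2]; B <- dim(x)[3]
  if (H != W) stopf("input must be square, got %d x %d", H, W)
  plan <- cfg$plan
  nstage <- plan$enc_conv + plan$enc_swin
  if (H %% 2^nstage != 0)
    stopf("side %d incompatible with %d down-sampling stages", H, nstage)
  if (length(t) == 1L) t <- rep(t, B)
  tp <- tape_new()
  pid <- param_nodes(tp, model$params)
  groups <- cfg$groupnorm_groups
  nm <- block_names(cfg)

  temb0 <- tp_input(tp, sinusoidal_embed(t, cfg$time_embed_dim,
                                         cfg$time_embed_max_period))
  temb <- tp_linear(tp, temb0, pid("temb.fc1.w"), pid("temb.fc1.b"))
  temb <- tp_silu(tp, temb)
  temb <- tp_linear(tp, temb, pid("temb.fc2.w"), pid("temb.fc2.b"))

  geom <- mk_geom(B, H, W, groups)
  h <- tp_conv3x3(tp, tp_input(tp, img_to_rows(x)), pid("stem.w"),
                  pid("stem.b"), geom)
  stem_out <- h
  skips <- list(); skip_geoms <- list()
  for (s in seq_len(nstage)) {                 # encoder
    base <- nm$enc[s]
    is_conv <- s <= plan$enc_conv
    nsec <- if (is_conv) 3L else 2L
    for (sec in seq_len(nsec)) {
      rsz <- NULL
      if (sec == nsec) {                       # downsample in last section
        rs <- resize_geom(B, geom$H, geom$W, "down")
        rsz <- list(rs = rs, geom = mk_geom(B, rs$H, rs$W, groups))
      }
      name <- sprintf("%s.s%d", base, sec)
      res <- if (is_conv)
        fw_conv_section(tp, pid, h, temb, name, geom, rsz)
      else fw_swin_section(tp, pid, h, temb, name, geom, cfg$window_size,
                           cfg$num_heads, rsz)
      h <- res$out; geom <- res$geom
    }
    skips[[s]] <- h; skip_geoms[[s]] <- geom
  }
  for (m in seq_len(plan$middle))
    for (sec in 1:2) {
      res <- fw_swin_section(tp, pid, h, temb,
                             sprintf("%s.s%d", nm$mid[m], sec), geom,
                             cfg$window_size, cfg$num_heads)
      h <- res$out
    }
  for (k in seq_len(nstage)) {                 # decoder
    s <- nstage - k + 1L
    base <- nm$dec[k]
    is_conv <- s <= plan$enc_conv
    nsec <- if (is_conv) 3L else 2L
    h <- tp_concat_cols(tp, h, skips[[s]])     # shortcut connection
    for (sec in seq_len(nsec)) {
      rsz <- NULL
      if (sec == nsec) {                       # upsample in last section
        rs <- resize_geom(B, geom$H, geom$W, "up")
        rsz <- list(rs = rs, geom = mk_geom(B, rs$H, rs$W, groups))
      }
      name <- sprintf("%s.s%d", base, sec)
      res <- if (is_conv)
        fw_conv_section(tp, pid, h, temb, name, geom, rsz)
      else fw_swin_section(tp, pid, h, temb, name, geom, cfg$window_size,
                           cfg$num_heads, rsz)
      h <- res$out; geom <- res$geom
    }
  }
  h <- tp_concat_cols(tp, h, stem_out)
  he <- tp_groupnorm(tp, h, pid("head.gn.gamma"), pid("head.gn.beta"),
                     geom, groups)
  he <- tp_silu(tp, he)
  eps_node <- tp_conv3x3(tp, he, pid("head.eps.w"), pid("head.eps.b"), geom)
  hv <- tp_groupnorm(tp, h, pid("head_v.gn.gamma"), pid("head_v.gn.beta"),
                     geom, groups)
  hv <- tp_silu(tp, hv)
  v_node <- tp_conv3x3(tp, hv, pid("head.v.w"), pid("head.v.b"), geom)
  list(tape = tp, eps_node = eps_node, v_node = v_node,
       H = H, W = W, B = B)
}

#' Run the denoiser
#'
#' @param model a `denoiser_model`
#' @param x noisy image: H x W matrix or \[H, W, B\] array (side divisible by
#'   2^(number of down-sampling stages))
#' @param t timestep(s): scalar or length-B vector in 1..T
#' @return a `denoiser_output` whose elements have the shape of `x`
#' @export
denoiser_forward <- function(model, x, t) {
  was_mat <- is.matrix(x)
  fw <- denoiser_forward_tape(model, x, t)
  eps <- rows_to_img(tp_value(fw$tape, fw$eps_node), fw$H, fw$W, fw$B)
  vr <- rows_to_img(tp_value(fw$tape, fw$v_node), fw$H, fw$W, fw$B)
  if (was_mat) { eps <- eps[, , 1]; vr <- vr[, , 1] }
  denoiser_output(eps, vr)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a flat named-parameter archive with the network (and
#' optionally training) configuration embedded; parameter naming is
#' deterministic so checkpoints round-trip bit-exactly.
#'
#' @param model a `denoiser_model`
#' @param path file path (.rds)
#' @param extra optional list stored alongside (training config, schedule)
#' @return `load_checkpoint` returns the `denoiser_model` with attribute
#'   `extra`
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(params = model$params, cfg = unclass(model$cfg),
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- structure(list(params = obj$params,
                          cfg = structure(obj$cfg, class = "network_config")),
                     class = "denoiser_model")
  attr(model, "extra") <- obj$extra
  model
}
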