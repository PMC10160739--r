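#' Training configuration
#'
#' Defaults reproduce the reference settings: AdamW with learning rate 2e-5
#' and weight decay 1e-4, 250 epochs, batch size 8, a T = 4000 linear
#' schedule of slope 5e-6, and hybrid-loss weight gamma = 0.01.
#'
#' @param learning_rate AdamW step size
#' @param weight_decay decoupled weight decay
#' @param epochs passes over the dataset
#' @param batch_size images per optimization step
#' @param T_steps diffusion steps of the training schedule
#' @param slope linear schedule slope
#' @param gamma hybrid-loss weight on the variance term; `gamma = 0`
#'   degrades training to pure noise-MSE (the VLB term is skipped)
#' @param seed run seed (initialization, shuffling, timesteps, noise)
#' @param checkpoint_interval steps between periodic checkpoints (0 = none)
#' @param ema_decay exponential-moving-average decay for a shadow copy of the
#'   weights; NULL (default) disables EMA
#' @param max_steps optional cap on total optimization steps
#' @param grad_clip global-norm gradient clip (default 1.0)
#' @return a `train_config`
#' @export
train_config <- function(learning_rate = 2e-5, weight_decay = 1e-4,
                         epochs = 250L, batch_size = 8L,
                         T_steps = 4000L, slope = 5e-6, gamma = 0.01,
                         seed = 1L, checkpoint_interval = 0L,
                         ema_decay = NULL, max_steps = NULL,
                         grad_clip = 1.0) {
  if (learning_rate <= 0 || weight_decay < 0 || batch_size < 1)
    stopf("rates must be positive")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 T_steps = as.integer(T_steps), slope = slope, gamma = gamma,
                 seed = as.integer(seed),
                 checkpoint_interval = as.integer(checkpoint_interval),
                 ema_decay = ema_decay, max_steps = max_steps,
                 grad_clip = grad_clip),
            class = "train_config")
}

adamw_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       step = 0L)
}

adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

# one optimization step: sample t and eps, corrupt, forward, analytic head
# gradients, backprop, AdamW update.  Returns updated model/state + losses.
train_step <- function(model, opt, batch_x0, schedule, cfg, lcfg) {
  B <- dim(batch_x0)[3]
  H <- dim(batch_x0)[1]; W <- dim(batch_x0)[2]
  t <- sample.int(schedule$T, B, replace = TRUE)
  eps <- array(stats::rnorm(length(batch_x0)), dim = dim(batch_x0))
  xt <- array(0, dim = dim(batch_x0))
  for (i in seq_len(B))
    xt[, , i] <- q_sample(batch_x0[, , i], t[i], eps[, , i], schedule)
  fw <- denoiser_forward_tape(model, xt, t)
  eps_pred <- rows_to_img(tp_value(fw$tape, fw$eps_node), H, W, B)
  v_raw <- rows_to_img(tp_value(fw$tape, fw$v_node), H, W, B)
  out <- denoiser_output(eps_pred, v_raw)
  batch <- list(x0 = batch_x0, xt = xt, eps = eps, t = t)
  if (cfg$gamma > 0) {
    gl <- hybrid_loss_grads(batch, out, schedule, lcfg)
  } else {        # pure noise-MSE training: VLB skipped entirely
    l_mean <- noise_mse_loss(eps, eps_pred)
    gl <- list(loss = l_mean, l_mean = l_mean, l_var = NA_real_,
               d_eps = 2 * (eps_pred - eps) / length(eps),
               d_vraw = array(0, dim = dim(v_raw)))
  }
  seeds <- list()
  seeds[[as.character(fw$eps_node)]] <- img_to_rows(gl$d_eps)
  seeds[[as.character(fw$v_node)]] <- img_to_rows(gl$d_vraw)
  grads <- tape_backward(fw$tape, seeds)
  grads <- clip_global_norm(grads, cfg$grad_clip)
  upd <- adamw_step(model$params, grads, opt, cfg$learning_rate,
                    cfg$weight_decay)
  list(params = upd$params, state = upd$state,
       loss = gl$loss, l_mean = gl$l_mean, l_var = gl$l_var)
}

#' Train the denoiser
#'
#' Optimizes the hybrid objective with AdamW.  Per step, a batch is drawn in
#' seeded shuffled order, each image gets a uniform timestep in 1..T and
#' fresh Gaussian noise, and gradients are clipped at global norm
#' `grad_clip`.  Fully deterministic for a fixed seed.
#'
#' @param dataset an `image_set`, normalized to its modality's range
#' @param net_cfg a `network_config`
#' @param train_cfg a `train_config`
#' @param out_dir optional directory for periodic checkpoints and the loss
#'   trace CSV
#' @return a list: `model` (final `denoiser_model`), `schedule`, `trace`
#'   (data.frame step, epoch, l_mean, l_var, loss), `train_cfg`
#' @export
train <- function(dataset, net_cfg, train_cfg = train_config(),
                  out_dir = NULL) {
  if (length(dataset$images) == 0L) stopf("empty dataset")
  schedule <- noise_schedule(train_cfg$T_steps, train_cfg$slope)
  lcfg <- loss_config(gamma = max(train_cfg$gamma, 1e-12),
                      data_range = dataset$normalized_range)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(train_cfg$seed)
  model <- init_denoiser(net_cfg, seed = derive_seed(train_cfg$seed, "init"))
  opt <- adamw_state(model$params)
  ema <- if (!is.null(train_cfg$ema_decay)) model$params else NULL
  xall <- set_to_array(dataset)
  n <- dim(xall)[3]
  if (n < train_cfg$batch_size)
    stopf("dataset smaller than one batch (%d < %d)", n, train_cfg$batch_size)
  step <- 0L
  rows <- list()
  done <- !is.null(train_cfg$max_steps) && train_cfg$max_steps == 0L
  for (epoch in if (done) integer() else seq_len(train_cfg$epochs)) {
    perm <- sample.int(n)
    nb <- n %/% train_cfg$batch_size
    for (b in seq_len(nb)) {
      ids <- perm[((b - 1) * train_cfg$batch_size + 1):(b * train_cfg$batch_size)]
      res <- train_step(model, opt, xall[, , ids, drop = FALSE], schedule,
                        train_cfg, lcfg)
      model$params <- res$params
      opt <- res$state
      step <- step + 1L
      if (!is.finite(res$loss))
        stopf("NaN/Inf loss at step %d (l_mean = %g, l_var = %g): aborting",
              step, res$l_mean, res$l_var)
      if (!is.null(ema)) {
        d <- train_cfg$ema_decay
        for (nm in names(ema))
          ema[[nm]] <- d * ema[[nm]] + (1 - d) * model$params[[nm]]
      }
      rows[[step]] <- c(step = step, epoch = epoch, l_mean = res$l_mean,
                        l_var = res$l_var, loss = res$loss)
      if (!is.null(out_dir) && train_cfg$checkpoint_interval > 0L &&
          step %% train_cfg$checkpoint_interval == 0L)
        save_checkpoint(model, file.path(out_dir, sprintf("ckpt_%06d.rds", step)),
                        extra = list(train_cfg = unclass(train_cfg), step = step))
      if (!is.null(train_cfg$max_steps) && step >= train_cfg$max_steps) {
        done <- TRUE; break
      }
    }
    if (done) break
  }
  trace <- as.data.frame(do.call(rbind, rows))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trace, file.path(out_dir, "loss_trace.csv"),
                     row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "ckpt_final.rds"),
                    extra = list(train_cfg = unclass(train_cfg), step = step))
  }
  out <- list(model = model, schedule = schedule, trace = trace,
              train_cfg = train_cfg)
  if (!is.null(ema))
    out$ema_model <- structure(list(params = ema, cfg = net_cfg),
                               class = "denoiser_model")
  out
}
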