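#' Loss configuration
#'
#' @param gamma weight on the variational (variance) loss; default 0.01
#' @param delta half-width of one pixel-intensity bin for the discretized
#'   Gaussian decoder; default 1/256 (8-bit data mapped to a width-2 range)
#' @param data_range the normalized intensity range the decoder discretizes;
#'   images normalized to \[-1, 1\] (x-ray/MRI/phantom) use the default,
#'   CT normalized to \[0, 1\] should pass `c(0, 1)`
#' @param cdf_approx use the fast tanh approximation of the Gaussian CDF
#'   instead of the exact CDF (default FALSE; see the methods vignette)
#' @return a `loss_config` list
#' @export
loss_config <- function(gamma = 0.01, delta = 1/256,
                        data_range = c(-1, 1), cdf_approx = FALSE) {
  if (gamma <= 0) stopf("gamma must be > 0")
  if (delta <= 0) stopf("delta must be > 0")
  structure(list(gamma = gamma, delta = delta, data_range = data_range,
                 cdf_approx = cdf_approx), class = "loss_config")
}

#' Gaussian CDF, exact or fast tanh approximation
#'
#' The approximation is 0.5 * (1 + tanh(sqrt(2/pi) (z + 0.044715 z^3))),
#' accurate to ~2e-4 in probability.
#'
#' @param z standardized argument
#' @param approx logical; use the tanh approximation
#' @return CDF values
#' @export
gaussian_cdf <- function(z, approx = FALSE) {
  if (!approx) return(stats::pnorm(z))
  0.5 * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
}

# derivative of gaussian_cdf w.r.t. z (density, exact or approximated)
gaussian_cdf_deriv <- function(z, approx = FALSE) {
  if (!approx) return(stats::dnorm(z))
  u <- sqrt(2 / pi) * (z + 0.044715 * z^3)
  0.5 * (1 - tanh(u)^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * z^2)
}

#' Package network outputs into a DenoiserOutput
#'
#' Maps the raw second head through a bounded activation,
#' v = (tanh(v_raw) + 1) / 2, so the variance-interpolation coefficient always
#' lies in \[0, 1\].
#'
#' @param eps_pred image-shaped noise estimate
#' @param v_raw image-shaped raw network output for the variance head
#' @return a `denoiser_output` list with `eps_pred`, `v_raw`, `v`
#' @export
denoiser_output <- function(eps_pred, v_raw) {
  if (length(eps_pred) != length(v_raw))
    stopf("eps_pred and v_raw shapes differ")
  structure(list(eps_pred = eps_pred, v_raw = v_raw,
                 v = (tanh(v_raw) + 1) / 2),
            class = "denoiser_output")
}

#' Mean-squared noise-prediction loss
#'
#' Mean over all pixels, images and timesteps of (eps - eps_pred)^2.
#'
#' @param eps_true true injected noise
#' @param eps_pred predicted noise, same shape
#' @return scalar loss
#' @export
noise_mse_loss <- function(eps_true, eps_pred) {
  if (length(eps_true) == 0L) stopf("empty batch")
  if (length(eps_true) != length(eps_pred)) stopf("shapes differ")
  mean((eps_true - eps_pred)^2)
}

# log-likelihood of x under a per-pixel Gaussian discretized into bins of
# width 2*delta on data_range, edge bins open-ended; returns per-pixel values
discretized_gaussian_loglik <- function(x, mu, sigma2, delta, data_range,
                                        approx = FALSE) {
  sigma <- sqrt(sigma2)
  zp <- (x - mu + delta) / sigma
  zm <- (x - mu - delta) / sigma
  cp <- gaussian_cdf(zp, approx)
  cm <- gaussian_cdf(zm, approx)
  p <- cp - cm
  lo_edge <- x <= data_range[1] + delta
  hi_edge <- x >= data_range[2] - delta
  p[lo_edge] <- cp[lo_edge]
  p[hi_edge] <- (1 - cm)[hi_edge]
  log(pmax(p, 1e-12))
}

# closed-form KL( N(m1, s1) || N(m2, s2) ), elementwise, in nats
gaussian_kl_1d <- function(m1, s1, m2, s2) {
  0.5 * (log(s2 / s1) + (s1 + (m1 - m2)^2) / s2 - 1)
}

#' One variational-lower-bound term
#'
#' For t >= 2 this is the closed-form KL between the true Bayes posterior
#' q(X_{t-1} | X_t, X_0) = N(mu, beta_tilde_t) and the model's reverse kernel
#' N(mu_theta, Sigma_theta), averaged over pixels.  For t = 1 it is the
#' negative log-likelihood of x0 under the discretized Gaussian decoder.
#' During optimization the means inside this term are detached so the VLB
#' trains the variance head only; the returned value is unaffected.
#'
#' @param x0 clean image
#' @param xt noisy image at step t
#' @param t timestep (>= 1)
#' @param out a `denoiser_output`
#' @param schedule a `noise_schedule`
#' @param cfg a `loss_config`
#' @return scalar, nats per pixel
#' @export
vlb_term <- function(x0, xt, t, out, schedule, cfg = loss_config()) {
  t <- check_t(t, schedule)
  mu_theta <- mu_from_eps(xt, t, out$eps_pred, schedule)
  sigma_theta <- sigma_from_v(t, out$v, schedule)
  if (t == 1L) {
    return(mean(-discretized_gaussian_loglik(
      x0, mu_theta, sigma_theta, cfg$delta, cfg$data_range, cfg$cdf_approx)))
  }
  post <- posterior_params(xt, x0, t, schedule)
  mean(gaussian_kl_1d(post$mean, post$variance, mu_theta, sigma_theta))
}

#' Hybrid training objective
#'
#' L = L_mean + gamma * L_var where L_mean is the noise MSE and L_var the
#' batch-mean VLB term.
#'
#' @param batch list with `x0`, `xt`, `eps` (arrays whose last dimension
#'   indexes images) and integer vector `t` (one timestep per image)
#' @param out a `denoiser_output` for the whole batch
#' @param schedule a `noise_schedule`
#' @param cfg a `loss_config`
#' @return list with `loss`, `l_mean`, `l_var`
#' @export
hybrid_loss <- function(batch, out, schedule, cfg = loss_config()) {
  l_mean <- noise_mse_loss(batch$eps, out$eps_pred)
  B <- length(batch$t)
  sl <- slice_last_dim
  vlb <- vapply(seq_len(B), function(i) {
    oi <- structure(list(eps_pred = sl(out$eps_pred, i),
                         v_raw = sl(out$v_raw, i), v = sl(out$v, i)),
                    class = "denoiser_output")
    vlb_term(sl(batch$x0, i), sl(batch$xt, i), batch$t[i], oi, schedule, cfg)
  }, numeric(1))
  l_var <- mean(vlb)
  list(loss = l_mean + cfg$gamma * l_var, l_mean = l_mean, l_var = l_var)
}

# index i of the last dimension of a 2- or 3-d array, dropping it
slice_last_dim <- function(a, i) {
  d <- dim(a)
  if (is.null(d) || length(d) == 2L) return(if (is.null(d)) a[i] else a[, i])
  a[, , i]
}

# Analytic gradients of the hybrid loss w.r.t. the network's two raw heads.
# Means are detached inside the VLB so d(eps_pred) comes from L_mean only and
# d(v_raw) from the variance path only.  Returns per-element gradient arrays
# matching the head shapes plus the loss components.
hybrid_loss_grads <- function(batch, out, schedule, cfg = loss_config()) {
  parts <- hybrid_loss(batch, out, schedule, cfg)
  n_tot <- length(batch$eps)
  d_eps <- 2 * (out$eps_pred - batch$eps) / n_tot
  d_vraw <- array(0, dim = dim(out$v_raw) %||% length(out$v_raw))
  B <- length(batch$t)
  npix <- n_tot / B
  sl <- slice_last_dim
  for (i in seq_len(B)) {
    t <- batch$t[i]
    v_raw_i <- sl(out$v_raw, i)
    v_i <- sl(out$v, i)
    sig <- sigma_from_v(t, v_i, schedule)
    bt <- schedule$betas[t]
    btl <- max(schedule$posterior_variances[t], POSTVAR_FLOOR)
    mu_theta <- mu_from_eps(sl(batch$xt, i), t, sl(out$eps_pred, i), schedule)
    if (t == 1L) {
      x0 <- sl(batch$x0, i)
      s <- sqrt(sig)
      zp <- (x0 - mu_theta + cfg$delta) / s
      zm <- (x0 - mu_theta - cfg$delta) / s
      cp <- gaussian_cdf(zp, cfg$cdf_approx)
      cm <- gaussian_cdf(zm, cfg$cdf_approx)
      dp <- gaussian_cdf_deriv(zp, cfg$cdf_approx)
      dm <- gaussian_cdf_deriv(zm, cfg$cdf_approx)
      p <- cp - cm
      dpds <- (dm * zm - dp * zp) / s        # d p / d sigma (interior bins)
      lo <- x0 <= cfg$data_range[1] + cfg$delta
      hi <- x0 >= cfg$data_range[2] - cfg$delta
      p[lo] <- cp[lo];        dpds[lo] <- (-dp * zp / s)[lo]
      p[hi] <- (1 - cm)[hi];  dpds[hi] <- (dm * zm / s)[hi]
      dnll_dsig2 <- -(1 / pmax(p, 1e-12)) * dpds / (2 * s)
      d_kl_dsig2 <- dnll_dsig2
    } else {
      post <- posterior_params(sl(batch$xt, i), sl(batch$x0, i), t, schedule)
      d_kl_dsig2 <- 0.5 * (1 / sig -
        (post$variance + (post$mean - mu_theta)^2) / sig^2)
    }
    dsig2_dv <- sig * (log(bt) - log(btl))
    dv_dvraw <- 0.5 * (1 - tanh(v_raw_i)^2)
    g <- cfg$gamma * d_kl_dsig2 * dsig2_dv * dv_dvraw / (npix * B)
    if (length(dim(d_vraw)) == 3L) d_vraw[, , i] <- g else d_vraw[, i] <- g
  }
  list(loss = parts$loss, l_mean = parts$l_mean, l_var = parts$l_var,
       d_eps = d_eps, d_vraw = d_vraw)
}
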