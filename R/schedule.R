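#' Linear variance schedule for forward diffusion
#'
#' Builds all per-timestep quantities of a T-step forward diffusion chain with
#' linearly increasing per-step variance beta_t = slope * t.  Alongside the
#' betas it stores alpha_t = 1 - beta_t, the cumulative products
#' alpha_bar_t = prod_{i<=t} alpha_i (with the convention alpha_bar_0 = 1),
#' and the Bayes posterior variances
#' beta_tilde_t = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t.
#'
#' The reference configuration uses T = 4000 and slope = 5e-6, giving
#' beta_1 = 5e-6 and beta_T = 0.02.
#'
#' @param T_steps number of diffusion steps (>= 1)
#' @param slope slope of the linear schedule; `slope * T_steps` must be < 1 so
#'   every beta stays inside (0, 1)
#' @return an object of class `noise_schedule`: a list with elements `T`,
#'   `slope`, `betas`, `alphas`, `alpha_bars`, `posterior_variances`
#' @examples
#' sch <- noise_schedule(4000, 5e-6)
#' sch$betas[4000]   # 0.02
#' @export
noise_schedule <- function(T_steps, slope) {
  if (!is.numeric(T_steps) || length(T_steps) != 1L || T_steps < 1 ||
      T_steps != floor(T_steps))
    stopf("T_steps must be a positive integer, got %s", format(T_steps))
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stopf("slope must be a positive real")
  if (slope * T_steps >= 1)
    stopf("slope * T = %g >= 1: beta_T would leave (0,1)", slope * T_steps)
  t <- seq_len(T_steps)
  betas <- slope * t
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  alpha_bar_prev <- c(1, alpha_bars[-T_steps])      # alpha_bar_0 = 1
  post_var <- (1 - alpha_bar_prev) / (1 - alpha_bars) * betas
  structure(
    list(T = as.integer(T_steps), slope = slope, betas = betas,
         alphas = alphas, alpha_bars = alpha_bars,
         posterior_variances = post_var),
    class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> T = %d, slope = %g, beta in [%g, %g]\n",
              x$T, x$slope, x$betas[1], x$betas[x$T]))
  invisible(x)
}

check_t <- function(t, schedule, min_t = 1L) {
  if (!is.numeric(t) || length(t) != 1L || t != floor(t) ||
      t < min_t || t > schedule$T)
    stopf("timestep t = %s out of range [%d, %d]", format(t), min_t, schedule$T)
  as.integer(t)
}

#' Schedule (de)serialization
#'
#' Schedules are always rebuilt from their two defining numbers, never
#' persisted as arrays.  `write_schedule_config` writes a flat `key: value`
#' text file with keys `T` and `slope`; `read_schedule_config` rebuilds the
#' schedule from such a file (YAML-subset or JSON).
#'
#' @param schedule a `noise_schedule`
#' @param path file path
#' @return `read_schedule_config` returns a `noise_schedule`
#' @export
write_schedule_config <- function(schedule, path) {
  write_flat_yaml(list(T = schedule$T, slope = schedule$slope), path)
  invisible(path)
}

#' @rdname write_schedule_config
#' @export
read_schedule_config <- function(path) {
  cfg <- read_config_file(path)
  noise_schedule(as.numeric(cfg$T), as.numeric(cfg$slope))
}

#' Corrupt an image to timestep t in closed form
#'
#' Draws from the forward marginal q(X_t | X_0):
#' X_t = sqrt(alpha_bar_t) X_0 + sqrt(1 - alpha_bar_t) eps.
#'
#' @param x0 clean image (any numeric array)
#' @param t timestep in 1..T
#' @param eps standard-normal noise, same shape as `x0`
#' @param schedule a `noise_schedule`
#' @return the noisy image, same shape as `x0`
#' @export
q_sample <- function(x0, t, eps, schedule) {
  t <- check_t(t, schedule)
  if (length(x0) != length(eps))
    stopf("x0 and eps shapes differ (%d vs %d values)", length(x0), length(eps))
  ab <- schedule$alpha_bars[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Bayes posterior of the forward chain
#'
#' The conditional q(X_{t-1} | X_t, X_0) of a Gaussian forward chain is itself
#' Gaussian with
#' mean = sqrt(alpha_bar_{t-1}) beta_t / (1 - alpha_bar_t) * x0 +
#'        sqrt(alpha_t) (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * xt
#' and scalar variance beta_tilde_t.  At t = 1 the posterior collapses to a
#' point mass at x0 (variance 0).
#'
#' @param xt noisy image at step t
#' @param x0 clean image
#' @param t timestep in 1..T
#' @param schedule a `noise_schedule`
#' @return list with elements `mean` (image) and `variance` (scalar)
#' @export
posterior_params <- function(xt, x0, t, schedule) {
  t <- check_t(t, schedule)
  if (length(xt) != length(x0)) stopf("xt and x0 shapes differ")
  ab_t <- schedule$alpha_bars[t]
  ab_prev <- if (t == 1L) 1 else schedule$alpha_bars[t - 1L]
  coef_x0 <- sqrt(ab_prev) * schedule$betas[t] / (1 - ab_t)
  coef_xt <- sqrt(schedule$alphas[t]) * (1 - ab_prev) / (1 - ab_t)
  list(mean = coef_x0 * x0 + coef_xt * xt,
       variance = schedule$posterior_variances[t])
}

#' Reverse-process mean from a noise estimate
#'
#' Substituting the noise parameterization into the posterior mean gives
#' mu_theta = (xt - beta_t / sqrt(1 - alpha_bar_t) * eps_pred) / sqrt(alpha_t).
#' Note the cumulative product alpha_bar_t under the square root.
#'
#' @param xt noisy image at step t
#' @param t timestep in 1..T
#' @param eps_pred predicted noise, same shape as `xt`
#' @param schedule a `noise_schedule`
#' @return the reverse-process mean, same shape as `xt`
#' @export
mu_from_eps <- function(xt, t, eps_pred, schedule) {
  t <- check_t(t, schedule)
  if (length(xt) != length(eps_pred)) stopf("xt and eps_pred shapes differ")
  ab <- schedule$alpha_bars[t]
  (xt - schedule$betas[t] / sqrt(1 - ab) * eps_pred) / sqrt(schedule$alphas[t])
}

# beta_tilde floored away from zero so log-interpolation stays defined at t = 1
POSTVAR_FLOOR <- 1e-20

#' Learned reverse-process variance from the interpolation coefficient
#'
#' The network's second head predicts a per-pixel coefficient v in [0, 1]; the
#' reverse variance is the log-linear interpolation
#' Sigma_theta = exp(v log beta_t + (1 - v) log beta_tilde_t).
#' beta_tilde_1 = 0 is floored at 1e-20 so the logarithm stays defined.
#'
#' @param t timestep in 1..T
#' @param v interpolation coefficient(s) in [0, 1] (image-shaped or scalar)
#' @param schedule a `noise_schedule`
#' @return variance, same shape as `v`
#' @export
sigma_from_v <- function(t, v, schedule) {
  t <- check_t(t, schedule)
  if (any(v < 0 | v > 1)) stopf("v must lie in [0, 1] elementwise")
  bt <- schedule$betas[t]
  btl <- max(schedule$posterior_variances[t], POSTVAR_FLOOR)
  exp(v * log(bt) + (1 - v) * log(btl))
}
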