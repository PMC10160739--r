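#' Build a spaced sub-chain for fast sampling
#'
#' Picks `n_steps` evenly spaced timesteps S from 1..T (deduplicated,
#' preserving order) and recomputes per-sub-step quantities from ratios of
#' the parent chain's cumulative alpha so the sub-chain's marginals match the
#' parent chain: effective beta at sub-step j is
#' 1 - alpha_bar(S_j) / alpha_bar(S_{j-1}) with alpha_bar(S_0) = 1.
#'
#' @param schedule a `noise_schedule`
#' @param n_steps number of sub-steps (1..T); the reference configuration
#'   spaces 500 steps over T = 4000
#' @return a `spaced_chain` with `S`, `effective_betas`,
#'   `effective_alphas`, `effective_alpha_bars`,
#'   `effective_posterior_variances`
#' @export
make_spaced_chain <- function(schedule, n_steps) {
  if (n_steps < 1 || n_steps > schedule$T)
    stopf("n_steps = %d out of range [1, %d]", n_steps, schedule$T)
  raw <- linspace(1, schedule$T, n_steps)
  S <- unique(as.integer(ceiling(raw - 0.5)))    # round half down; see vignette
  ab <- schedule$alpha_bars[S]
  ab_prev <- c(1, ab[-length(ab)])
  # effective alpha over the gap (S_{j-1}, S_j] as the product of parent
  # alphas: equal to the alpha_bar ratio, but bit-exact on the identity
  # sub-chain (the ratio of cumulative products differs in the last ulp)
  S_prev <- c(0L, S[-length(S)])
  gap1 <- (S - S_prev) == 1L
  eff_alpha <- vapply(seq_along(S), function(j)
    prod(schedule$alphas[(S_prev[j] + 1L):S[j]]), numeric(1))
  eff_beta <- 1 - eff_alpha
  # single-step gaps reduce to the parent step exactly: take the parent's
  # beta/alpha in their canonical form so the identity sub-chain is
  # bit-identical to the full chain
  eff_alpha[gap1] <- schedule$alphas[S[gap1]]
  eff_beta[gap1] <- schedule$betas[S[gap1]]
  eff_post <- (1 - ab_prev) / (1 - ab) * eff_beta
  structure(list(S = S, T = schedule$T,
                 effective_betas = eff_beta,
                 effective_alphas = eff_alpha,
                 effective_alpha_bars = ab,
                 effective_posterior_variances = eff_post),
            class = "spaced_chain")
}

#' @export
print.spaced_chain <- function(x, ...) {
  cat(sprintf("<spaced_chain> %d of %d steps (S = %d ... %d)\n",
              length(x$S), x$T, x$S[1], x$S[length(x$S)]))
  invisible(x)
}

# mean / variance of the reverse kernel at sub-step j, from a denoiser output
reverse_kernel <- function(xs, j, out, chain) {
  if (j < 1 || j > length(chain$S)) stopf("sub-step %d out of chain", j)
  ab <- chain$effective_alpha_bars[j]
  beta <- chain$effective_betas[j]
  alpha <- chain$effective_alphas[j]
  mu <- (xs - beta / sqrt(1 - ab) * out$eps_pred) / sqrt(alpha)
  btl <- max(chain$effective_posterior_variances[j], POSTVAR_FLOOR)
  sigma2 <- exp(out$v * log(beta) + (1 - out$v) * log(btl))
  list(mean = mu, variance = sigma2)
}

#' One reverse-diffusion step on a spaced chain
#'
#' X_{j-1} = mu_theta + sqrt(Sigma_theta) * noise, where mu_theta comes from
#' the noise estimate via the sub-chain's effective quantities and
#' Sigma_theta from the learned interpolation coefficient.  At the final
#' sub-step (j = 1) the noise term is dropped.
#'
#' @param xs current image(s)
#' @param j sub-step index (position in `chain$S`, counting from 1)
#' @param out a `denoiser_output` for (xs, S_j)
#' @param chain a `spaced_chain`
#' @param noise standard-normal draw, same shape as `xs` (ignored at j = 1)
#' @return the less-noisy image(s)
#' @export
reverse_step <- function(xs, j, out, chain, noise) {
  kern <- reverse_kernel(xs, j, out, chain)
  if (j == 1L) return(kern$mean)
  kern$mean + sqrt(kern$variance) * noise
}

#' Generate synthetic images by reverse diffusion
#'
#' Draws `n_images` standard-normal images, runs the full reverse recursion
#' over the spaced chain (feeding the original timestep S_j to the network so
#' timestep embeddings match training), and clips the outputs to the
#' modality's normalized range.  All randomness flows from one generator
#' seeded with `seed`: first the initial noise images, then the per-step
#' noise in reverse-chain order.
#'
#' @param model a `denoiser_model`
#' @param chain a `spaced_chain` built from the model's training schedule
#' @param n_images number of images
#' @param seed RNG seed
#' @param modality output modality tag (sets the clip range)
#' @param side image side length
#' @param trace if TRUE, also return mean absolute intensity per sub-step
#' @return an `image_set`; with `trace`, attribute `trace` holds the drift
#' @export
generate <- function(model, chain, n_images, seed = 1L, modality = "phantom",
                     side = 32L, trace = FALSE) {
  m <- modality_info(modality)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  B <- n_images
  x <- array(stats::rnorm(side * side * B), dim = c(side, side, B))
  nj <- length(chain$S)
  drift <- numeric(nj)
  for (j in nj:1) {
    out <- denoiser_forward(model, x, chain$S[j])
    noise <- if (j > 1L)
      array(stats::rnorm(side * side * B), dim = c(side, side, B))
    else array(0, dim = c(side, side, B))
    x <- reverse_step(x, j, out, chain, noise)
    drift[j] <- mean(abs(x))
  }
  x <- clip(x, m$norm[1], m$norm[2])
  set <- array_to_set(x, modality)
  if (trace) attr(set, "trace") <- drift
  set
}
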