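# The DDPM mathematical core: cosine noise schedule, closed-form forward
# noising, the velocity (v) parameterization and its inversion, the ancestral
# reverse step with fixed posterior variance, partial-noise reconstruction and
# the v-space training objective. Everything here is agnostic to what network
# produces the predictions: a "denoiser" is any function(x, t, conditions)
# returning a predicted velocity of the same shape as x.

#' Cosine noise schedule
#'
#' Builds the variance schedule with
#' \eqn{\bar\alpha_t = f(t)/f(0)}, \eqn{f(t) = \cos^2(((t/T + s)/(1+s)) \pi/2)},
#' and per-step \eqn{\beta_t = \min(1 - \bar\alpha_t/\bar\alpha_{t-1}, clip)}.
#' All downstream quantities (\eqn{\alpha_t}, cumulative \eqn{\bar\alpha_t},
#' posterior variances \eqn{\tilde\beta_t}) are recomputed from the clipped
#' betas, so the stored schedule is self-consistent.
#'
#' @param T_steps Total number of diffusion steps (1000 at full scale).
#' @param s Small offset preventing vanishing betas near t = 0 (default 0.008).
#' @param clip Upper bound on each beta (default 0.999).
#' @return Object of class `diffusion_schedule`: list with `T`, `betas`,
#'   `alphas`, `alpha_bars` (with `alpha_bars[t]` = \eqn{\bar\alpha_t}; the
#'   convention \eqn{\bar\alpha_0 = 1} is stored in `alpha_bar0`),
#'   and `posterior_vars`.
#' @export
cosine_schedule <- function(T_steps = 1000L, s = 0.008, clip = 0.999) {
  if (length(T_steps) != 1L || is.na(T_steps) || T_steps < 1)
    stop("'T_steps' must be a positive integer")
  T_steps <- as.integer(T_steps)
  f <- function(t) cos(((t / T_steps + s) / (1 + s)) * pi / 2)^2
  ab_raw <- f(0:T_steps) / f(0)
  betas <- pmin(1 - ab_raw[-1] / ab_raw[-(T_steps + 1)], clip)
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  ab_prev <- c(1, alpha_bars[-T_steps])
  posterior_vars <- betas * (1 - ab_prev) / (1 - alpha_bars)
  structure(list(
    T = T_steps, s = s, clip = clip,
    betas = betas, alphas = alphas,
    alpha_bar0 = 1, alpha_bars = alpha_bars,
    posterior_vars = posterior_vars
  ), class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf(
    "Cosine diffusion schedule: T = %d, s = %.3f, alpha_bar[T] = %.3g\n",
    x$T, x$s, x$alpha_bars[x$T]))
  invisible(x)
}

check_t <- function(t, sched) {
  if (length(t) != 1L || is.na(t) || t < 1 || t > sched$T || t != floor(t))
    stop(sprintf("'t' must be an integer in 1..%d", sched$T))
  as.integer(t)
}

# alpha_bar with the t = 0 convention
abar <- function(sched, t) if (t == 0) 1 else sched$alpha_bars[t]

#' Forward noising (closed-form marginal)
#'
#' Returns \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1-\bar\alpha_t} \epsilon}.
#' @param x0 Clean state (matrix, vertices x channels).
#' @param t Step in `1..T`.
#' @param eps Standard-normal draw of the same shape as `x0`.
#' @param sched A `diffusion_schedule`.
#' @export
q_sample <- function(x0, t, eps, sched) {
  t <- check_t(t, sched)
  if (!all(dim2(x0) == dim2(eps))) stop("'x0' and 'eps' shapes differ")
  ab <- abar(sched, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Velocity target of the v-parameterization
#'
#' \eqn{v = \sqrt{\bar\alpha_t}\,\epsilon - \sqrt{1-\bar\alpha_t}\,x_0}: the
#' exact rotation of (x0, eps) that the denoiser is trained to predict.
#' @inheritParams q_sample
#' @export
v_target <- function(x0, eps, t, sched) {
  t <- check_t(t, sched)
  if (!all(dim2(x0) == dim2(eps))) stop("'x0' and 'eps' shapes differ")
  ab <- abar(sched, t)
  sqrt(ab) * eps - sqrt(1 - ab) * x0
}

#' Invert the v-parameterization
#'
#' Recovers the implied clean state and noise from a noisy state and a
#' predicted velocity:
#' \eqn{\hat x_0 = \sqrt{\bar\alpha_t} x_t - \sqrt{1-\bar\alpha_t} v},
#' \eqn{\hat\epsilon = \sqrt{1-\bar\alpha_t} x_t + \sqrt{\bar\alpha_t} v}.
#' @param xt Noisy state at step `t`.
#' @param v Predicted velocity, same shape.
#' @inheritParams q_sample
#' @return List with `x0_hat` and `eps_hat`.
#' @export
x0_eps_from_v <- function(xt, v, t, sched) {
  t <- check_t(t, sched)
  if (!all(dim2(xt) == dim2(v))) stop("'xt' and 'v' shapes differ")
  ab <- abar(sched, t)
  list(x0_hat = sqrt(ab) * xt - sqrt(1 - ab) * v,
       eps_hat = sqrt(1 - ab) * xt + sqrt(ab) * v)
}

#' One ancestral reverse step
#'
#' Converts the predicted velocity to \eqn{\hat x_0} (optionally clipped),
#' forms the forward-posterior mean
#' \eqn{\mu = \frac{\sqrt{\bar\alpha_{t-1}}\beta_t}{1-\bar\alpha_t}\hat x_0 +
#'      \frac{\sqrt{\alpha_t}(1-\bar\alpha_{t-1})}{1-\bar\alpha_t} x_t}
#' and adds \eqn{\sqrt{\tilde\beta_t} z} noise for `t > 1`; the final step
#' `t = 1` is deterministic. The reverse variance is the fixed posterior
#' variance (not learned).
#'
#' @param xt State at step `t`.
#' @param v_hat Predicted velocity at `t` (same shape as `xt`).
#' @param t Step in `1..T`.
#' @param sched A `diffusion_schedule`.
#' @param z Optional standard-normal draw (same shape); drawn from the current
#'   RNG when `NULL` and `t > 1`.
#' @param clip_x0 Symmetric clipping bound on \eqn{\hat x_0} in standardized
#'   units (default 6); `Inf` disables clipping.
#' @return State at step `t - 1`.
#' @export
p_sample_step <- function(xt, v_hat, t, sched, z = NULL, clip_x0 = 6) {
  t <- check_t(t, sched)
  est <- x0_eps_from_v(xt, v_hat, t, sched)
  x0_hat <- pmin(pmax(est$x0_hat, -clip_x0), clip_x0)
  ab_t <- abar(sched, t)
  ab_prev <- abar(sched, t - 1)
  beta_t <- sched$betas[t]
  alpha_t <- sched$alphas[t]
  mu <- (sqrt(ab_prev) * beta_t / (1 - ab_t)) * x0_hat +
        (sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t)) * xt
  if (t > 1L) {
    if (is.null(z)) z <- matrix(rnorm(length(xt)), nrow(as.matrix(xt)))
    mu <- mu + sqrt(sched$posterior_vars[t]) * z
  }
  mu
}

#' Full reverse chain from a starting step
#'
#' Iterates [p_sample_step()] from `t_start` down to 1.
#' @param x_start State at `t_start` (e.g. pure noise at `t_start = T`).
#' @param t_start First step of the chain.
#' @param denoiser `function(x, t, conditions)` returning a predicted velocity.
#' @param conditions Conditioning payload passed through to the denoiser.
#' @inheritParams p_sample_step
#' @export
reverse_chain <- function(x_start, t_start, denoiser, conditions = NULL,
                          sched, clip_x0 = 6) {
  x <- x_start
  for (t in seq(t_start, 1L)) {
    v_hat <- denoiser(x, t, conditions)
    x <- p_sample_step(x, v_hat, t, sched, clip_x0 = clip_x0)
  }
  x
}

#' Pseudo-healthy partial-noise reconstruction
#'
#' Noises an observed map to step `t_start` with the closed-form forward
#' marginal and denoises it back to `t = 0` under the (healthy-trained)
#' reverse dynamics, holding the conditions fixed throughout; repeated
#' independently `n` times to produce a personalized reference set. With
#' `t_start = 0` the observation is returned unchanged (`n` copies).
#'
#' @param x0_obs Observed state (vertices x channels).
#' @param t_start Steps of noise to add before denoising (500 of 1000 at full
#'   scale; `T/2` at desk scale).
#' @param denoiser `function(x, t, conditions)` returning a predicted velocity.
#' @param conditions Conditioning payload (mask, age, sex) held fixed.
#' @param n Number of independent reconstructions.
#' @param sched A `diffusion_schedule`.
#' @param seed Optional integer; when given, the whole set of reconstructions
#'   is a deterministic function of it (caller RNG untouched).
#' @param clip_x0 Clipping bound passed to [p_sample_step()].
#' @return List of `n` reconstructed states.
#' @export
partial_reconstruct <- function(x0_obs, t_start = 500L, denoiser,
                                conditions = NULL, n = 10L, sched,
                                seed = NULL, clip_x0 = 6) {
  if (t_start < 0 || t_start > sched$T)
    stop(sprintf("'t_start' must be in 0..%d", sched$T))
  run <- function() {
    lapply(seq_len(n), function(i) {
      if (t_start == 0L) return(x0_obs)
      eps <- matrix(rnorm(length(x0_obs)), nrow(as.matrix(x0_obs)))
      x <- q_sample(x0_obs, t_start, eps, sched)
      reverse_chain(x, t_start, denoiser, conditions, sched, clip_x0)
    })
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' v-space training objective (Monte-Carlo estimate)
#'
#' For each item of a batch, draws `t` uniform on `1..T` and fresh standard
#' normal noise, forms the noisy state and the velocity target, and returns
#' the mean squared error between the denoiser's prediction and the target.
#'
#' @param x0_batch List of clean states (each vertices x channels).
#' @param conditions List of per-item conditioning payloads (or `NULL`).
#' @param denoiser `function(x, t, conditions)` returning predicted velocity.
#' @param sched A `diffusion_schedule`.
#' @param seed Optional integer for a deterministic estimate.
#' @return Scalar loss.
#' @export
diffusion_loss <- function(x0_batch, conditions = NULL, denoiser, sched,
                           seed = NULL) {
  if (length(x0_batch) == 0) stop("empty batch")
  run <- function() {
    per <- vapply(seq_along(x0_batch), function(i) {
      x0 <- x0_batch[[i]]
      t <- sample.int(sched$T, 1)
      eps <- matrix(rnorm(length(x0)), nrow(as.matrix(x0)))
      xt <- q_sample(x0, t, eps, sched)
      v <- v_target(x0, eps, t, sched)
      v_hat <- denoiser(xt, t, if (is.null(conditions)) NULL else conditions[[i]])
      mean((v_hat - v)^2)
    }, numeric(1))
    mean(per)
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}
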