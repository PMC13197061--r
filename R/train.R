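# Training loop for the spherical denoiser: Adam with optional cosine
# annealing on the v-space Monte-Carlo objective. One optimization step draws
# a mini-batch of subjects, a uniform time step and fresh noise per item,
# runs the tracked forward pass and backpropagates through the tape.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of per-subject matrices into a block batch.
stack_blocks <- function(xs) do.call(rbind, xs)

# Encode a 0/1 gyral/sulcal mask as a -1/+1 channel.
encode_mask <- function(mask) matrix(2 * as.numeric(mask) - 1, ncol = 1)

#' Train the denoiser on a set of clean maps
#'
#' @param params Initial parameter list (see [init_denoiser_params()]).
#' @param config A `denoiser_config`.
#' @param data List with one element per subject: `x0` (V x C standardized
#'   features), `mask` (encoded mask channels or `NULL`), `age` (years/100),
#'   `sex` (0/1).
#' @param sched A `diffusion_schedule`.
#' @param steps Number of optimization steps.
#' @param batch_size Subjects per step.
#' @param lr Peak Adam learning rate.
#' @param lr_anneal Cosine-anneal the rate to ~0 over `steps` (default TRUE).
#' @param seed Integer; the whole run is deterministic given it.
#' @param verbose Print the running loss every `report_every` steps.
#' @param report_every Reporting stride.
#' @return List with trained `params` and the per-step `loss` history.
#' @export
train_denoiser <- function(params, config, data, sched, steps = 2000L,
                           batch_size = 8L, lr = 2e-3, lr_anneal = TRUE,
                           seed = 1L, verbose = FALSE, report_every = 200L) {
  geom <- denoiser_geometry(config)
  n <- length(data)
  state <- adam_state(params)
  losses <- numeric(steps)
  with_seed_(seed, {
    for (step in seq_len(steps)) {
      ids <- sample.int(n, min(batch_size, n))
      b <- length(ids)
      t_vec <- sample.int(sched$T, b, replace = TRUE)
      xt_list <- vector("list", b); vt_list <- vector("list", b)
      for (i in seq_len(b)) {
        x0 <- data[[ids[i]]]$x0
        eps <- matrix(rnorm(length(x0)), nrow(x0))
        xt_list[[i]] <- q_sample(x0, t_vec[i], eps, sched)
        vt_list[[i]] <- v_target(x0, eps, t_vec[i], sched)
      }
      xt <- stack_blocks(xt_list)
      vt <- stack_blocks(vt_list)
      mask <- if (config$mask_channels > 0)
        stack_blocks(lapply(data[ids], `[[`, "mask")) else NULL
      age <- vapply(data[ids], `[[`, 0, "age")
      sex <- vapply(data[ids], `[[`, 0, "sex")

      tape <- ad_tape()
      pn <- lapply(params, function(p) ad_param(tape, p))
      v_hat <- denoiser_forward(pn, config, geom, xt, t_vec, age, sex, mask)
      loss <- ad_mean(ad_pow(ad_sub(v_hat, vt), 2))
      ad_backward(loss)
      grads <- lapply(pn, ad_grad)
      losses[step] <- ad_value(loss)[1]

      lr_t <- if (lr_anneal) lr * 0.5 * (1 + cos(pi * (step - 1) / steps)) else lr
      upd <- adam_step(params, grads, state, lr_t)
      params <- upd$params
      state <- upd$state
      if (verbose && step %% report_every == 0)
        message(sprintf("step %d  loss %.4f", step,
                        mean(losses[max(1, step - report_every + 1):step])))
    }
  })
  list(params = params, loss = losses)
}

# Inference closure: function(x, t, cond) -> predicted velocity, where cond
# is list(age, sex, mask) with vectors/blocks matching the stacked batch in x.
make_denoiser_fn <- function(params, config, geom) {
  force(params); force(config); force(geom)
  function(x, t, cond) {
    denoiser_forward(params, config, geom, x, t,
                     age = cond$age, sex = cond$sex, mask = cond$mask)
  }
}
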