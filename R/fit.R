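# The user-facing model: surface_ddpm() fits an anatomy-conditioned spherical
# diffusion model to a cohort of cortical feature maps and returns a classed
# object with the usual verbs. simulate() draws fresh maps from pure noise;
# predict() produces pseudo-healthy partial-noise reconstructions, the
# personalized reference sets that normative scoring consumes.

#' Fit an anatomy-conditioned spherical diffusion model
#'
#' Trains a conditional DDPM with v-parameterization on the feature maps of a
#' (healthy) training cohort. Channels are standardized to mean 0, sd 1 over
#' the cohort and the statistics stored for test-time reuse; the gyral/sulcal
#' mask is concatenated to the input as a -1/+1 channel (when
#' `condition_mask`), and age (scaled by 1/100) and sex modulate every
#' residual block through the shared time embedding.
#'
#' @param cohort A `cortex_cohort` (see [make_cohort()] or [read_cohort()]).
#' @param channels Feature channels to model (default cortical thickness and
#'   the shape-index analog).
#' @param condition_mask Concatenate the anatomical mask channel (TRUE for
#'   the anatomy-guided model; FALSE gives the unconditional ablation, which
#'   still carries age and sex).
#' @param T_steps Diffusion steps of the cosine schedule (250 at desk scale;
#'   1000 at full scale).
#' @param hidden_dims UNet widths per level (128/256/512 at full scale;
#'   the smaller desk-scale default trains on one CPU in minutes).
#' @param n_levels UNet depth.
#' @param time_embed_dim Shared embedding width.
#' @param steps,batch_size,lr,lr_anneal Training-loop controls (Adam; cosine
#'   annealing of the rate by default).
#' @param clip_x0 Clipping bound on the implied clean state during sampling.
#' @param seed Integer; initialization and training are deterministic given it.
#' @param verbose Report the running loss during training.
#' @return Object of class `surface_ddpm`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(cohort_spec(n_subjects = 20, seed = 7))
#' fit <- surface_ddpm(cohort, steps = 50, verbose = FALSE)
#' print(fit)
#' }
#' @export
surface_ddpm <- function(cohort, channels = c("ct", "si"),
                         condition_mask = TRUE,
                         T_steps = 250L,
                         hidden_dims = c(16L, 32L, 64L),
                         n_levels = 3L,
                         time_embed_dim = 64L,
                         steps = 2000L, batch_size = 8L,
                         lr = 2e-3, lr_anneal = TRUE,
                         clip_x0 = 6, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cohort, "cortex_cohort"))
  order <- cohort$spec$order %||% order_from_vertex_count(nrow(cohort$ico$vertices))
  std <- standardize_channels(cohort)
  stats <- attr(std, "channel_stats")
  data <- lapply(std$subjects, function(s) list(
    x0 = s$features[, channels, drop = FALSE],
    mask = if (condition_mask) encode_mask(s$mask) else NULL,
    age = s$age / 100,
    sex = s$sex
  ))
  config <- denoiser_config(
    base_order = order,
    feature_channels = length(channels),
    mask_channels = if (condition_mask) 1L else 0L,
    n_levels = n_levels,
    hidden_dims = hidden_dims,
    time_embed_dim = time_embed_dim
  )
  sched <- cosine_schedule(T_steps)
  params <- init_denoiser_params(config, seed = seed)
  run <- train_denoiser(params, config, data, sched, steps = steps,
                        batch_size = batch_size, lr = lr,
                        lr_anneal = lr_anneal, seed = seed, verbose = verbose)
  structure(list(
    params = run$params,
    config = config,
    geom = denoiser_geometry(config),
    sched = sched,
    channel_stats = stats,
    channels = channels,
    condition_mask = condition_mask,
    clip_x0 = clip_x0,
    loss_history = run$loss,
    training = list(steps = steps, batch_size = batch_size, lr = lr,
                    lr_anneal = lr_anneal, seed = seed,
                    n_subjects = length(data)),
    parcellation = cohort$parcellation,
    ico = cohort$ico
  ), class = "surface_ddpm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_params <- function(params) sum(vapply(params, length, integer(1)))

#' @export
print.surface_ddpm <- function(x, ...) {
  cat("Anatomy-conditioned spherical diffusion model\n")
  cat(sprintf("  order %d sphere (%d vertices), channels: %s%s\n",
              x$config$base_order, nrow(x$ico$vertices),
              paste(x$channels, collapse = ", "),
              if (x$condition_mask) " + gyral/sulcal mask" else " (no mask)"))
  cat(sprintf("  UNet widths [%s], %s parameters; T = %d cosine schedule\n",
              paste(x$config$hidden_dims, collapse = ", "),
              format(n_params(x$params), big.mark = ","), x$sched$T))
  tail_n <- min(100, length(x$loss_history))
  cat(sprintf("  trained %d steps on %d subjects; final loss %.4f (mean of last %d)\n",
              x$training$steps, x$training$n_subjects,
              mean(utils::tail(x$loss_history, tail_n)), tail_n))
  invisible(x)
}

#' @export
summary.surface_ddpm <- function(object, ...) {
  print(object)
  l <- object$loss_history
  q <- stats::quantile(utils::tail(l, max(1, length(l) %/% 4)))
  cat("  last-quarter loss quartiles:\n")
  print(round(q, 4))
  invisible(object)
}

#' @export
coef.surface_ddpm <- function(object, ...) object$params

#' @export
plot.surface_ddpm <- function(x, ...) {
  l <- x$loss_history
  graphics::plot(l, type = "l", col = "grey60", xlab = "optimization step",
                 ylab = "v-space loss", main = "Training loss", ...)
  if (length(l) >= 20) {
    k <- max(10, length(l) %/% 50)
    sm <- stats::filter(l, rep(1 / k, k), sides = 1)
    graphics::lines(sm, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

# Conditions for a block-stacked batch of subjects (each possibly repeated).
stack_conditions <- function(fit, subjects, each = 1L) {
  rep_items <- rep(seq_along(subjects), each = each)
  list(
    age = vapply(subjects[rep_items], `[[`, 0, "age") / 100,
    sex = vapply(subjects[rep_items], `[[`, 0, "sex"),
    mask = if (fit$condition_mask)
      stack_blocks(lapply(subjects[rep_items], function(s) encode_mask(s$mask)))
    else NULL
  )
}

#' Draw new subjects from the fitted model
#'
#' Runs the full reverse chain from pure noise, conditioned on the mask, age
#' and sex of the supplied subjects (their feature maps are ignored).
#'
#' @param object A fitted `surface_ddpm`.
#' @param nsim Draws per conditioning subject.
#' @param seed Integer seed (the simulation is deterministic given it).
#' @param subjects List of `cortex_subject` supplying the conditions; defaults
#'   to a single average condition (age 70, sex 0, first training mask absent
#'   models require `condition_mask = FALSE`).
#' @param ... Unused.
#' @return List (one element per subject) of lists of `nsim` feature maps in
#'   original units.
#' @export
simulate.surface_ddpm <- function(object, nsim = 1, seed = NULL,
                                  subjects, ...) {
  V <- nrow(object$ico$vertices)
  C <- object$config$feature_channels
  B <- length(subjects) * nsim
  cond <- stack_conditions(object, subjects, each = nsim)
  dn <- make_denoiser_fn(object$params, object$config, object$geom)
  run <- function() {
    x <- matrix(rnorm(B * V * C), B * V, C)
    out <- reverse_chain(x, object$sched$T, dn, cond, object$sched,
                         clip_x0 = object$clip_x0)
    split_destandardize(object, out, length(subjects), nsim, V)
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' Pseudo-healthy partial-noise reconstruction of observed subjects
#'
#' For each subject, noises the observed (standardized) feature map `t_start`
#' steps forward and denoises it back under the healthy-trained dynamics with
#' the subject's own mask, age and sex held fixed, independently `n` times.
#' The result is the personalized reference set of Eq.-style normative
#' scoring (see [abnormal_scores()]).
#'
#' @param object A fitted `surface_ddpm`.
#' @param newdata List of `cortex_subject` (or a `cortex_cohort`).
#' @param t_start Noising depth; default half the schedule (the full-scale
#'   analog is 500 of 1000 steps).
#' @param n Reconstructions per subject (reference-set size, default 10).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List per subject of `n` reconstructed feature maps (original
#'   units, V x channels).
#' @export
predict.surface_ddpm <- function(object, newdata, t_start = NULL, n = 10L,
                                 seed = NULL, ...) {
  subjects <- if (inherits(newdata, "cortex_cohort")) newdata$subjects else newdata
  if (is.null(t_start)) t_start <- object$sched$T %/% 2L
  V <- nrow(object$ico$vertices)
  cond <- stack_conditions(object, subjects, each = n)
  dn <- make_denoiser_fn(object$params, object$config, object$geom)
  # each subject's map repeated n times (block-stacked)
  x0 <- stack_blocks(lapply(subjects, function(s) {
    std <- apply_channel_stats(
      s$features[, object$channels, drop = FALSE], object$channel_stats)
    do.call(rbind, rep(list(std), n))
  }))
  run <- function() {
    out <- partial_reconstruct(x0, t_start, dn, cond, n = 1L,
                               sched = object$sched, clip_x0 = object$clip_x0)[[1]]
    split_destandardize(object, out, length(subjects), n, V)
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

# Split a stacked (n_subj * n * V) x C matrix back into per-subject lists of
# per-draw maps, undoing the channel standardization.
split_destandardize <- function(fit, out, n_subj, n, V) {
  colnames(out) <- fit$channels
  lapply(seq_len(n_subj), function(i) {
    lapply(seq_len(n), function(j) {
      rows <- ((i - 1) * n + (j - 1)) * V + seq_len(V)
      apply_channel_stats(out[rows, , drop = FALSE], fit$channel_stats,
                          inverse = TRUE)
    })
  })
}

#' Deviation of observed subjects from their reconstructions
#'
#' Residual maps `observed - mean(reconstructions)` per subject, the raw
#' material of the abnormality scores.
#' @param object A fitted `surface_ddpm`.
#' @param newdata Subjects (list or `cortex_cohort`).
#' @param t_start,n,seed As in [predict.surface_ddpm()].
#' @param ... Unused.
#' @return List of V x channels residual matrices.
#' @export
residuals.surface_ddpm <- function(object, newdata, t_start = NULL, n = 10L,
                                   seed = NULL, ...) {
  subjects <- if (inherits(newdata, "cortex_cohort")) newdata$subjects else newdata
  recon <- predict(object, newdata, t_start = t_start, n = n, seed = seed)
  lapply(seq_along(subjects), function(i) {
    m <- Reduce(`+`, recon[[i]]) / length(recon[[i]])
    subjects[[i]]$features[, object$channels, drop = FALSE] - m
  })
}
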