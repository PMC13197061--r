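test_that("spherical convolution matches an explicit gather-and-dot loop", {
  set.seed(14)
  ico <- get_ico(2)
  nv <- nrow(ico$vertices)
  cin <- 3L; cout <- 2L
  x <- matrix(rnorm(nv * cin), nv, cin)
  w <- array(rnorm(cout * cin * 7) * 0.3, c(cout, cin, 7))
  bias <- rnorm(cout)
  out <- spherical_conv(x, ico, w, bias)
  # brute force: for every vertex gather [self, ring (pad = self)] and dot
  ref <- matrix(0, nv, cout)
  for (v in seq_len(nv)) {
    taps <- c(v, ico$neighbor_table[v, ])
    for (co in seq_len(cout)) {
      acc <- bias[co]
      for (k in 1:7) for (ci in seq_len(cin))
        acc <- acc + w[co, ci, k] * x[taps[k], ci]
      ref[v, co] <- acc
    }
  }
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("identity kernel reproduces the input and any kernel maps constants to constants", {
  ico <- get_ico(1)
  nv <- nrow(ico$vertices)
  x <- matrix(rnorm(nv * 2), nv, 2)
  w_id <- array(0, c(2, 2, 7))
  w_id[1, 1, 1] <- 1; w_id[2, 2, 1] <- 1   # center tap = identity
  expect_equal(spherical_conv(x, ico, w_id), x, tolerance = 1e-12)

  set.seed(5)
  w <- array(rnorm(2 * 1 * 7), c(2, 1, 7))
  const <- matrix(3.2, nv, 1)
  out <- spherical_conv(const, ico, w)
  tap_sums <- apply(w, 1, sum) * 3.2
  expect_lt(max(abs(sweep(out, 2, tap_sums))), 1e-10)
})

test_that("time embedding is deterministic, injective at small t, and spans slow frequencies", {
  e0 <- time_embedding(0, 32)
  e1 <- time_embedding(1, 32)
  expect_identical(time_embedding(5, 32), time_embedding(5, 32))
  expect_gt(max(abs(e0 - e1)), 0)
  # slowest frequency has period 2*pi*10^4 >= any practical T
  freqs <- 10000^(-(0:15) / 15)
  expect_gte(2 * pi / min(freqs), 1000)
  # the embedding actually uses that ladder
  expect_equal(time_embedding(3, 32)[1, 1:16], sin(3 * freqs), tolerance = 1e-12)
  expect_error(time_embedding(1, 7), "even")
})

test_that("demographic embedding distinguishes covariate values and zero output layers vanish", {
  config <- tiny_config()
  params <- init_denoiser_params(config, seed = 2)
  e1 <- demographic_embedding(0.6, 0, params)
  e2 <- demographic_embedding(0.8, 0, params)
  e3 <- demographic_embedding(0.6, 1, params)
  expect_gt(max(abs(e1 - e2)), 0)
  expect_gt(max(abs(e1 - e3)), 0)
  pz <- params
  pz$age_W2[] <- 0; pz$age_b2[] <- 0
  pz$sex_W2[] <- 0; pz$sex_b2[] <- 0
  expect_equal(demographic_embedding(0.6, 1, pz), matrix(0, 1, 8),
               tolerance = 0)
})

test_that("age input has a finite nonzero gradient through the network loss", {
  config <- tiny_config()
  set.seed(6)
  params <- init_denoiser_params(config, seed = 3)
  params <- lapply(params, function(p) p + matrix(rnorm(length(p)) * 0.05, nrow(p)))
  geom <- cortexdiff:::denoiser_geometry(config)
  V <- 42
  x <- matrix(rnorm(V * 2), V, 2)
  mask <- matrix(sample(c(-1, 1), V, TRUE), ncol = 1)
  target <- matrix(rnorm(V * 2), V, 2)
  lossfun <- function(age) {
    vh <- denoiser_forward(params, config, geom, x, 10, age, 1, mask)
    mean((vh - target)^2)
  }
  h <- 1e-5
  grad <- (lossfun(0.7 + h) - lossfun(0.7 - h)) / (2 * h)
  expect_true(is.finite(grad))
  expect_gt(abs(grad), 0)
})

test_that("unet output has the feature shape and batch items do not leak across blocks", {
  config <- tiny_config()
  params <- init_denoiser_params(config, seed = 4)
  set.seed(11)
  params <- lapply(params, function(p) p + matrix(rnorm(length(p)) * 0.05, nrow(p)))
  geom <- cortexdiff:::denoiser_geometry(config)
  V <- 42L
  x1 <- matrix(rnorm(V * 2), V, 2); m1 <- matrix(sign(rnorm(V)), ncol = 1)
  x2 <- matrix(rnorm(V * 2), V, 2); m2 <- matrix(sign(rnorm(V)), ncol = 1)
  out12 <- denoiser_forward(params, config, geom, rbind(x1, x2),
                            c(3, 9), c(0.6, 0.7), c(0, 1), rbind(m1, m2))
  out21 <- denoiser_forward(params, config, geom, rbind(x2, x1),
                            c(9, 3), c(0.7, 0.6), c(1, 0), rbind(m2, m1))
  expect_identical(dim(out12), c(2L * V, 2L))   # mask channel not reproduced
  expect_equal(out12[seq_len(V), ], out21[V + seq_len(V), ], tolerance = 1e-12)
  expect_equal(out12[V + seq_len(V), ], out21[seq_len(V), ], tolerance = 1e-12)
  # deterministic in inference mode
  rep2 <- denoiser_forward(params, config, geom, rbind(x1, x2),
                           c(3, 9), c(0.6, 0.7), c(0, 1), rbind(m1, m2))
  expect_identical(out12, rep2)
})

test_that("changing the mask changes the output of a randomly perturbed network", {
  config <- tiny_config()
  params <- init_denoiser_params(config, seed = 5)
  set.seed(21)
  params <- lapply(params, function(p) p + matrix(rnorm(length(p)) * 0.1, nrow(p)))
  geom <- cortexdiff:::denoiser_geometry(config)
  V <- 42
  x <- matrix(rnorm(V * 2), V, 2)
  m1 <- matrix(rep(1, V), ncol = 1)
  m2 <- matrix(rep(-1, V), ncol = 1)
  o1 <- denoiser_forward(params, config, geom, x, 5, 0.6, 0, m1)
  o2 <- denoiser_forward(params, config, geom, x, 5, 0.6, 0, m2)
  expect_gt(max(abs(o1 - o2)), 0)
})

test_that("a short training run beats the predict-zero baseline by at least 30 percent", {
  # desk-scale check of learning: small cohort, order 1, few hundred steps
  cohort <- small_cohort(n = 24, seed = 31, order = 1)
  fit <- surface_ddpm(cohort, T_steps = 100L, hidden_dims = c(8L, 16L),
                      n_levels = 2L, time_embed_dim = 16L, steps = 500L,
                      batch_size = 4L, seed = 6)
  val <- make_cohort(cohort_spec(n_subjects = 8, order = 1, seed = 32),
                     ico = cohort$ico, parcellation = cohort$parcellation)
  vstd <- standardize_channels(val, stats = fit$channel_stats)
  dn <- cortexdiff:::make_denoiser_fn(fit$params, fit$config, fit$geom)
  set.seed(7)
  loss_model <- 0; loss_zero <- 0; nrep <- 120
  for (r in seq_len(nrep)) {
    s <- vstd$subjects[[sample(8, 1)]]
    x0 <- s$features
    t <- sample(fit$sched$T, 1)
    eps <- matrix(rnorm(length(x0)), nrow(x0))
    xt <- q_sample(x0, t, eps, fit$sched)
    vt <- v_target(x0, eps, t, fit$sched)
    vh <- dn(xt, t, list(age = s$age / 100, sex = s$sex,
                         mask = cortexdiff:::encode_mask(s$mask)))
    loss_model <- loss_model + mean((vh - vt)^2) / nrep
    loss_zero <- loss_zero + mean(vt^2) / nrep
  }
  expect_lt(loss_model, 0.7 * loss_zero)
})
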