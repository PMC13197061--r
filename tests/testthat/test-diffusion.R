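test_that("cosine schedule normalizes, decreases monotonically and nearly vanishes at T", {
  s <- cosine_schedule(1000)
  expect_equal(s$alpha_bar0, 1)
  expect_true(all(diff(c(s$alpha_bar0, s$alpha_bars)) < 0))
  expect_lt(s$alpha_bars[1000], 1e-3)
  expect_true(all(s$betas > 0 & s$betas <= 0.999))
  # self-consistency after clipping: alpha_bars is the product of alphas
  expect_equal(s$alpha_bars, cumprod(1 - s$betas), tolerance = 1e-12)
  # posterior variance never exceeds beta
  expect_true(all(s$posterior_vars <= s$betas + 1e-15))
  expect_error(cosine_schedule(0), "positive")
})

test_that("q_sample implements the closed-form forward marginal", {
  s <- cosine_schedule(100)
  x0 <- matrix(rnorm(20), 10, 2)
  t <- 37
  expect_equal(q_sample(x0, t, x0 * 0, s), sqrt(s$alpha_bars[t]) * x0)
  # at tiny t the state is close to x0
  eps <- matrix(rnorm(20), 10, 2)
  expect_lt(max(abs(q_sample(x0, 1, eps, s) - x0)), 0.2)
  expect_error(q_sample(x0, 0, eps, s), "must be an integer")
  expect_error(q_sample(x0, 101, eps, s), "must be an integer")
  expect_error(q_sample(x0, t, eps[1:5, ], s), "shapes differ")
})

test_that("q_sample empirical variance matches 1 - alpha_bar within Monte-Carlo error", {
  s <- cosine_schedule(100)
  t <- 50
  n <- 1e4
  set.seed(31)
  draws <- vapply(seq_len(n), function(i) q_sample(0, t, rnorm(1), s),
                  numeric(1))
  v_hat <- var(draws)
  v_true <- 1 - s$alpha_bars[t]
  se <- v_true * sqrt(2 / (n - 1))   # se of a normal sample variance
  expect_lt(abs(v_hat - v_true), 3 * se)
})

test_that("v-parameterization is an exact rotation and round-trips to 1e-10", {
  s <- cosine_schedule(200)
  set.seed(8)
  for (t in c(1, 7, 100, 200)) {
    x0 <- matrix(rnorm(30), 15, 2)
    eps <- matrix(rnorm(30), 15, 2)
    xt <- q_sample(x0, t, eps, s)
    v <- v_target(x0, eps, t, s)
    # rotation identity: |v|^2 + |xt|^2 = |x0|^2 + |eps|^2
    expect_equal(sum(v^2) + sum(xt^2), sum(x0^2) + sum(eps^2),
                 tolerance = 1e-10)
    rec <- x0_eps_from_v(xt, v, t, s)
    expect_lt(max(abs(rec$x0_hat - x0)), 1e-10)
    expect_lt(max(abs(rec$eps_hat - eps)), 1e-10)
    # consistency: re-noising the recovered pair reproduces xt
    expect_lt(max(abs(q_sample(rec$x0_hat, t, rec$eps_hat, s) - xt)), 1e-10)
  }
  # degenerate directions
  expect_equal(v_target(matrix(1, 2, 2), matrix(0, 2, 2), 10, s),
               -sqrt(1 - s$alpha_bars[10]) * matrix(1, 2, 2))
  expect_equal(v_target(matrix(0, 2, 2), matrix(1, 2, 2), 10, s),
               sqrt(s$alpha_bars[10]) * matrix(1, 2, 2))
})

test_that("final reverse step is deterministic and a perfect constant oracle is recovered", {
  s <- cosine_schedule(50)
  const <- 1.7
  # oracle that always predicts the v consistent with x0 = const
  oracle <- function(x, t, cond) {
    ab <- s$alpha_bars[t]
    (sqrt(ab) * x - const) / sqrt(1 - ab) # solve x0_hat = const for v
  }
  x1 <- matrix(rnorm(10), 5, 2)
  v1 <- oracle(x1, 1, NULL)
  expect_identical(p_sample_step(x1, v1, 1, s),
                   p_sample_step(x1, v1, 1, s))   # no noise at t = 1
  set.seed(2)
  x <- matrix(rnorm(10), 5, 2)
  out <- reverse_chain(x, 50, oracle, NULL, s)
  expect_lt(max(abs(out - const)), 1e-6)
})

test_that("reverse chain with the analytic Gaussian oracle recovers mean and variance", {
  # x0 ~ N(m, s2) i.i.d. per vertex: E[x0 | xt] has closed form, and the
  # reverse chain driven by it must reproduce the data distribution.
  T_ <- 250
  sch <- cosine_schedule(T_)
  m <- 0.8; s2 <- 0.49
  oracle <- function(x, t, cond) {
    ab <- sch$alpha_bars[t]
    x0_hat <- (sqrt(ab) * s2 * x + (1 - ab) * m) / (ab * s2 + 1 - ab)
    (sqrt(ab) * x - x0_hat) / sqrt(1 - ab)
  }
  nv <- 162; nchain <- 2000 / nv * nv   # 2000 i.i.d. values via vertex slots
  set.seed(77)
  x <- matrix(rnorm(2000), ncol = 1)
  out <- reverse_chain(x, T_, oracle, NULL, sch)
  n <- length(out)
  se_mean <- sqrt(s2 / n)
  se_var <- s2 * sqrt(2 / (n - 1))
  expect_lt(abs(mean(out) - m), 3 * se_mean)
  expect_lt(abs(var(as.vector(out)) - s2), 3 * se_var)
})

test_that("partial reconstruction is seed-deterministic and handles the t_start = 0 edge", {
  s <- cosine_schedule(40)
  x0 <- matrix(rnorm(24), 12, 2)
  dn <- function(x, t, cond) x * 0   # arbitrary fixed denoiser
  r0 <- partial_reconstruct(x0, 0, dn, NULL, n = 3, sched = s, seed = 5)
  expect_length(r0, 3)
  for (r in r0) expect_identical(r, x0)
  ra <- partial_reconstruct(x0, 20, dn, NULL, n = 2, sched = s, seed = 9)
  rb <- partial_reconstruct(x0, 20, dn, NULL, n = 2, sched = s, seed = 9)
  expect_identical(ra, rb)
  rc <- partial_reconstruct(x0, 20, dn, NULL, n = 2, sched = s, seed = 10)
  expect_false(identical(ra, rc))
  expect_error(partial_reconstruct(x0, 41, dn, NULL, n = 1, sched = s),
               "t_start")
})

test_that("identity-memorizing oracle pulls partial reconstructions onto its target map", {
  s <- cosine_schedule(60)
  target <- matrix(rep(c(-0.5, 1.2), each = 12), 12, 2)
  oracle <- function(x, t, cond) {
    ab <- s$alpha_bars[t]
    (sqrt(ab) * x - target) / sqrt(1 - ab)
  }
  x0 <- matrix(rnorm(24), 12, 2)
  rec <- partial_reconstruct(x0, 60, oracle, NULL, n = 4, sched = s, seed = 3)
  for (r in rec) expect_lt(max(abs(r - target)), 1e-4)
})

test_that("training loss is zero for a perfect denoiser and |v|^2-sized for the zero denoiser", {
  s <- cosine_schedule(80)
  set.seed(12)
  batch <- lapply(1:5, function(i) matrix(rnorm(20), 10, 2))
  # a denoiser that knows each item's true x0 (passed as its condition) can
  # recover the exact noise from xt, hence the exact velocity: loss must be 0
  perfect <- function(xt, t, x0) {
    ab <- s$alpha_bars[t]
    eps <- (xt - sqrt(ab) * x0) / sqrt(1 - ab)
    sqrt(ab) * eps - sqrt(1 - ab) * x0
  }
  expect_equal(diffusion_loss(batch, batch, perfect, s, seed = 1), 0,
               tolerance = 1e-20)

  # zero-predicting denoiser: loss equals mean |v|^2 under the same draws
  l0 <- diffusion_loss(batch, NULL, function(x, t, cond) x * 0, s, seed = 4)
  set.seed(4)
  per <- vapply(seq_along(batch), function(i) {
    x0 <- batch[[i]]
    t <- sample.int(s$T, 1)
    eps <- matrix(rnorm(length(x0)), nrow(x0))
    invisible(q_sample(x0, t, eps, s))
    mean(v_target(x0, eps, t, s)^2)
  }, numeric(1))
  expect_equal(l0, mean(per), tolerance = 1e-12)
  expect_error(diffusion_loss(list(), NULL, function(x, t, c) x, s), "empty")
})

test_that("loss estimates are stable across seeds for a fixed denoiser", {
  s <- cosine_schedule(80)
  set.seed(21)
  batch <- lapply(1:40, function(i) matrix(rnorm(20), 10, 2))
  dn <- function(x, t, cond) 0.5 * x
  ls <- vapply(1:6, function(sd) diffusion_loss(batch, NULL, dn, s, seed = sd),
               numeric(1))
  # Monte-Carlo repetitions agree within a few standard errors of each other
  expect_lt(diff(range(ls)), 6 * sd(ls) + 1e-12)
  expect_gt(sd(ls), 0)
})
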