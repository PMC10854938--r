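test_that("schedule construction matches the independent cumulative product", {
  sch <- make_schedule(10, 1e-4, 0.2)
  expect_equal(sch$alpha_bar,
               c(0.9999000000, 0.9775911200, 0.9340665909, 0.8717332137,
                 0.7941973873, 0.7059179355, 0.6117720135, 0.5165938832,
                 0.4247492307, 0.3397993845), tolerance = 1e-9)
  expect_true(all(diff(sch$alpha_bar) <= 0))
  expect_equal(sch$f^2 + sch$g^2, rep(1, 10))
  # degenerate single-step noiseless schedule
  s0 <- make_schedule(1, 0, 0)
  expect_equal(s0$alpha_bar, 1)
  expect_equal(s0$f, 1)
  expect_equal(s0$g, 0)
  expect_error(make_schedule(5, 0.5, 0.2), "beta")
  expect_error(make_schedule(0), "T_steps")
})

test_that("forward diffusion hits its boundary cases exactly", {
  sch <- make_schedule(1, 0, 0)
  x0 <- array(rnorm(24), c(2, 4, 3))
  z <- array(rnorm(24), c(2, 4, 3))
  expect_equal(forward_diffuse(x0, 1, sch, z), x0)      # alpha_bar = 1
  expect_equal(forward_diffuse(x0, 0, make_schedule(5), z), x0)
  sch1 <- make_schedule(1, 0.36, 0.36)
  expect_equal(forward_diffuse(x0 * 0, 1, sch1, z), 0.6 * z)
  expect_error(forward_diffuse(x0, 2, sch1), "timestep")
  expect_error(forward_diffuse(x0, 1, sch1, rnorm(3)), "shape")
})

test_that("forward diffusion Monte-Carlo moments match the closed form", {
  sch <- make_schedule(1, 0.36, 0.36)   # alpha_bar = 0.64
  n <- 1e5
  withr::with_seed(11, {
    x <- forward_diffuse(numeric(n), 1, sch)
  })
  se_mean <- 0.6 / sqrt(n)
  se_var <- 0.36 * sqrt(2 / (n - 1))
  expect_lt(abs(mean(x) - 0), 3 * se_mean)
  expect_lt(abs(stats::var(x) - 0.36), 3 * se_var)
})

test_that("posterior matches the two-Gaussian Bayes oracle", {
  # alpha_bar_{t-1} = 0.9, beta_t = 0.1 at t = 2
  sch <- make_schedule(2, 0.1, 0.1)
  expect_equal(sch$alpha_bar, c(0.9, 0.81))
  pp <- posterior_params(1, 0, 2, sch)
  # independent derivation: product of N(x; sqrt(abar_s) x0, 1 - abar_s) and
  # N(x_t; sqrt(alpha_t) x, beta_t) by precision weighting
  prec <- 1 / (1 - 0.9) + 0.9 / 0.1
  var_oracle <- 1 / prec
  mean_oracle <- var_oracle * (sqrt(0.9) * 0 / (1 - 0.9) + sqrt(0.9) * 1 / 0.1)
  expect_equal(pp$variance, var_oracle, tolerance = 1e-12)
  expect_equal(pp$mean, mean_oracle, tolerance = 1e-12)
  # no-noise step collapses onto x_t
  s0 <- make_schedule(3, 0, 0)
  p0 <- posterior_params(0.7, 0.1, 2, s0)
  expect_equal(p0$mean, 0.7)
  expect_equal(p0$variance, 0)
  expect_error(posterior_params(1, 0, 0, sch), "timestep")
})

test_that("bridge at s = t-1 equals the posterior on random schedules", {
  withr::with_seed(21, {
    for (rep in 1:8) {
      T_steps <- sample(3:30, 1)
      sch <- make_schedule(T_steps, runif(1, 1e-5, 5e-3), runif(1, 0.01, 0.3))
      x0 <- rnorm(5); x_t <- rnorm(5)
      for (t in sample(seq_len(T_steps), min(5, T_steps))) {
        b <- bridge_params(x_t, x0, t - 1L, t, sch)
        p <- posterior_params(x_t, x0, t, sch)
        expect_equal(b$mean, p$mean, tolerance = 1e-10)
        expect_equal(b$variance, p$variance, tolerance = 1e-10)
      }
    }
  })
})

test_that("bridge matches bivariate-normal conditioning and its boundaries", {
  sch <- make_schedule(10, 1e-3, 0.25)
  x0 <- 0.4; x_t <- -1.2; s <- 2L; t <- 5L
  b <- bridge_params(x_t, x0, s, t, sch)
  # oracle: joint Gaussian of (x_s, x_t) given x0, conditioned on x_t
  f_s <- sqrt(sch$alpha_bar[s]); f_t <- sqrt(sch$alpha_bar[t])
  g_s2 <- 1 - sch$alpha_bar[s]; g_t2 <- 1 - sch$alpha_bar[t]
  cov_st <- (f_t / f_s) * g_s2
  mean_oracle <- f_s * x0 + cov_st / g_t2 * (x_t - f_t * x0)
  var_oracle <- g_s2 - cov_st^2 / g_t2
  expect_equal(b$mean, mean_oracle, tolerance = 1e-12)
  expect_equal(b$variance, var_oracle, tolerance = 1e-12)
  # s = 0 collapses onto the clean endpoint
  b0 <- bridge_params(x_t, x0, 0L, t, sch)
  expect_equal(b0$mean, x0)
  expect_equal(b0$variance, 0)
  expect_error(bridge_params(x_t, x0, 5L, 5L, sch), "s < t")
})

test_that("iterated posterior sampling reproduces the forward marginals", {
  sch <- make_schedule(6, 0.05, 0.3)
  x0 <- 0.8
  n <- 4000
  withr::with_seed(31, {
    x <- forward_diffuse(rep(x0, n), sch$T, sch)
    for (t in sch$T:1) {
      pp <- posterior_params(x, x0, t, sch)
      x <- pp$mean + sqrt(pp$variance) * rnorm(n)
      tm <- t - 1L
      ab <- if (tm == 0L) 1 else sch$alpha_bar[tm]
      se_m <- sqrt((1 - ab) / n) + 1e-3
      expect_lt(abs(mean(x) - sqrt(ab) * x0), 4 * se_m)
      expect_lt(abs(stats::var(x) - (1 - ab)), 4 * (1 - ab + 0.05) * sqrt(2 / n))
    }
  })
})
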