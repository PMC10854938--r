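#' Gaussian diffusion schedule
#'
#' Builds the scale sequences of a variance-preserving Gaussian diffusion with
#' `T` steps and a linear noise schedule: `beta_t` rises linearly from
#' `beta_min` to `beta_max`, `alpha_t = 1 - beta_t`,
#' `alpha_bar_t = prod_{s<=t} alpha_s`, and the signal/noise scale pair
#' `f_t = sqrt(alpha_bar_t)`, `g_t = sqrt(1 - alpha_bar_t)`. Index 0 denotes
#' the clean endpoint: `alpha_bar_0 = 1`, `f_0 = 1`, `g_0 = 0`.
#'
#' @param T_steps number of diffusion steps (`T >= 1`).
#' @param beta_min,beta_max linear schedule bounds, `0 <= beta_min <= beta_max < 1`.
#' @return a `diffusion_schedule` list with fields `T`, `beta`, `alpha`,
#'   `alpha_bar`, `f`, `g` (each of length `T`, indexed by `t = 1..T`).
#' @examples
#' sch <- make_schedule(10, 1e-4, 0.02)
#' all(diff(sch$alpha_bar) <= 0)
#' @export
make_schedule <- function(T_steps, beta_min = 1e-4, beta_max = 0.02) {
  if (T_steps < 1) stop("`T_steps` must be >= 1")
  if (!(beta_min >= 0 && beta_min <= beta_max && beta_max < 1))
    stop("need 0 <= beta_min <= beta_max < 1")
  beta <- if (T_steps == 1L) beta_min else seq(beta_min, beta_max, length.out = T_steps)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar,
                 f = sqrt(alpha_bar), g = sqrt(1 - alpha_bar)),
            class = "diffusion_schedule")
}

# alpha_bar / f / g with the t = 0 boundary (clean endpoint)
sched_abar <- function(sch, t) if (t == 0L) 1 else sch$alpha_bar[t]
sched_f    <- function(sch, t) if (t == 0L) 1 else sch$f[t]
sched_g    <- function(sch, t) if (t == 0L) 0 else sch$g[t]

check_t <- function(sch, t, lo = 0L) {
  if (length(t) != 1L || t != round(t) || t < lo || t > sch$T)
    stop("timestep t must be an integer in [", lo, ", ", sch$T, "]")
  as.integer(t)
}

#' Closed-form forward diffusion
#'
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * Z`, with
#' `Z ~ N(0, I)` drawn at call time unless supplied.
#'
#' @param x0 numeric array (any shape), the clean signal.
#' @param t timestep in `0..T` (`t = 0` returns `x0`).
#' @param schedule a [make_schedule()] object.
#' @param noise optional standard-normal array of the same shape as `x0`.
#' @return array of the same shape as `x0`.
#' @export
forward_diffuse <- function(x0, t, schedule, noise = NULL) {
  t <- check_t(schedule, t)
  if (is.null(noise)) noise <- array(stats::rnorm(length(x0)), dim(x0) %||% length(x0))
  if (length(noise) != length(x0)) stop("`noise` must match the shape of `x0`")
  ab <- sched_abar(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

#' Reverse-process posterior q(x_{t-1} | x_t, x0)
#'
#' Mean and variance of the Gaussian posterior of the predecessor state:
#' `mean = (x_t - beta_t / sqrt(1 - alpha_bar_t) * Zhat) / sqrt(alpha_t)` with
#' `Zhat = (x_t - sqrt(alpha_bar_t) * x0) / sqrt(1 - alpha_bar_t)` the noise
#' implied by the pair `(x_t, x0)`, and
#' `variance = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`.
#'
#' @param x_t,x0 numeric arrays of identical shape.
#' @param t timestep in `1..T` (`t = 0` has no predecessor).
#' @param schedule a [make_schedule()] object.
#' @return list with `mean` (array) and `variance` (scalar).
#' @export
posterior_params <- function(x_t, x0, t, schedule) {
  t <- check_t(schedule, t, lo = 1L)
  ab_t  <- sched_abar(schedule, t)
  ab_tm <- sched_abar(schedule, t - 1L)
  beta_t <- schedule$beta[t]
  if (1 - ab_t <= 0) return(list(mean = x_t, variance = 0))  # no noise yet
  zhat <- (x_t - sqrt(ab_t) * x0) / sqrt(1 - ab_t)
  mean <- (x_t - beta_t / sqrt(1 - ab_t) * zhat) / sqrt(schedule$alpha[t])
  var <- (1 - ab_tm) / (1 - ab_t) * beta_t
  list(mean = mean, variance = var)
}

#' Diffusion bridge q(x_s | x_t, x0), s < t
#'
#' The general conditional of an intermediate state given a later state and
#' the clean endpoint, in the `f/g` scale parameterisation: with
#' `f_{t|s} = f_t / f_s` and `g_{t|s}^2 = g_t^2 - f_{t|s}^2 * g_s^2`,
#' `mean = f_{s|0} * (g_{t|s}^2 / g_{t|0}^2) * x0 +
#'         f_{t|s} * (g_{s|0}^2 / g_{t|0}^2) * x_t` and
#' `variance = g_{s|0}^2 * g_{t|s}^2 / g_{t|0}^2`. At `s = t - 1` this
#' coincides with [posterior_params()]; at `s = 0` it collapses onto `x0`.
#'
#' @param x_t,x0 numeric arrays of identical shape.
#' @param s,t timesteps with `0 <= s < t <= T`.
#' @param schedule a [make_schedule()] object.
#' @return list with `mean` (array) and `variance` (scalar).
#' @export
bridge_params <- function(x_t, x0, s, t, schedule) {
  t <- check_t(schedule, t, lo = 1L)
  s <- check_t(schedule, s, lo = 0L)
  if (s >= t) stop("need s < t")
  f_s <- sched_f(schedule, s); f_t <- sched_f(schedule, t)
  g_s <- sched_g(schedule, s); g_t <- sched_g(schedule, t)
  f_ts <- f_t / f_s
  g_ts2 <- g_t^2 - f_ts^2 * g_s^2
  g_t2 <- g_t^2
  if (g_t2 <= 0) return(list(mean = x_t, variance = 0))
  mean <- f_s * (g_ts2 / g_t2) * x0 + f_ts * (g_s^2 / g_t2) * x_t
  var <- g_s^2 * g_ts2 / g_t2
  list(mean = mean, variance = max(var, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
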