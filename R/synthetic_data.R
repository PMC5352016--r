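# Stochastic stand-in for real magnetization data.  The analytic layer only
# assumes an exponential moment autocorrelation; any dynamics reproducing it
# together with detailed balance will do.  Two minimal models are provided:
# a random telegraph process (the strong-uniaxial picture, moment pinned to
# +/- the easy axis) and an Ornstein-Uhlenbeck process (Gaussian surrogate
# for one Cartesian component of an isotropic particle).  Both use exact
# per-step updates, so there is no discretization bias beyond the grid
# itself, and both are exactly reproducible from (params, seed).

new_trajectory <- function(times, muz, params) {
  structure(list(times = times, muz = muz, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf("Moment trajectory (%s model)\n", p$model))
  cat(sprintf("  %d samples, dt = %.4g s, duration = %.4g s\n",
              length(x$muz), p$dt, length(x$muz) * p$dt))
  cat(sprintf("  tau = %.4g s, seed = %d\n", p$tau, p$seed))
  invisible(x)
}

#' @describeIn simulate_telegraph Trajectory as a data frame with columns
#'   `t_s` and `muz_emu`.
#' @param x A `trajectory`.
#' @param row.names,optional Passed through for S3 compatibility; unused.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(t_s = x$times, muz_emu = x$muz)
}

check_dt <- function(dt, tau) {
  assert_positive(dt, "dt")
  if (dt > tau / 20 * (1 + 1e-12)) {
    stop("`dt` must not exceed tau/20 (sampling adequacy)", call. = FALSE)
  }
}

applied_field <- function(b_field, times) {
  if (is.numeric(b_field) && length(b_field) == 1L) {
    rep(b_field, length(times))
  } else if (is.list(b_field)) {
    amp <- b_field$amplitude
    omega <- b_field$omega
    phase <- if (is.null(b_field$phase)) 0 else b_field$phase
    assert_scalar(amp, "b_field$amplitude")
    assert_scalar(omega, "b_field$omega")
    amp * cos(omega * times + phase)
  } else {
    stop("`b_field` must be a scalar (G) or list(amplitude, omega, phase)",
         call. = FALSE)
  }
}

#' Simulate random-telegraph moment dynamics of a uniaxial particle
#'
#' Two-state Markov chain for the moment projection of a strongly uniaxial
#' particle: \eqn{\mu_z = \pm\mu}, with Arrhenius-split flip rates
#' \deqn{r_{+\to-} = \frac{1}{2\tau} e^{-\mu B/k_B T}, \qquad
#'       r_{-\to+} = \frac{1}{2\tau} e^{+\mu B/k_B T},}
#' so that the zero-field relaxation rate is exactly \eqn{1/\tau} and
#' detailed balance gives the equilibrium magnetization
#' \eqn{\langle\mu_z\rangle = \mu\tanh(\mu B/k_B T)}.  At \eqn{B = 0} the
#' autocorrelation is \eqn{\mu^2 e^{-|t|/\tau}}.  Flips are drawn with the
#' exact per-step probabilities \eqn{1 - e^{-r\,dt}}; the initial state is
#' drawn from the equilibrium distribution at the initial field.
#'
#' @param mu Moment magnitude, emu.
#' @param tau Zero-field relaxation time, s.
#' @param temperature Absolute temperature, K.
#' @param b_field Applied field along the easy axis: a constant (G) or
#'   `list(amplitude, omega, phase)` describing
#'   \eqn{B(t) = b\cos(\omega t + \phi)} for linear-response runs.
#' @param duration Total simulated time, s.
#' @param dt Time step, s; must not exceed `tau/20`.
#' @param seed Integer seed; identical `(params, seed)` give identical
#'   trajectories, and the caller's RNG stream is left untouched.
#' @return An object of class `trajectory` with fields `times`, `muz` and
#'   `params`.
#' @examples
#' tr <- simulate_telegraph(mu = 5e-14, tau = 1e-9, temperature = 310,
#'                          duration = 2e-6, dt = 5e-11, seed = 42)
#' var(tr$muz) / (5e-14)^2  # ~1: the projection is pinned at +/- mu
#' @export
simulate_telegraph <- function(mu, tau, temperature, b_field = 0,
                               duration, dt = tau / 50, seed = 1L) {
  for (nm in c("mu", "tau", "temperature", "duration")) {
    assert_scalar(get(nm), nm)
    assert_positive(get(nm), nm)
  }
  check_dt(dt, tau)
  n <- floor(duration / dt)
  if (n < 10) stop("`duration` too short for the chosen `dt`", call. = FALSE)
  times <- (seq_len(n) - 1) * dt
  b <- applied_field(b_field, times)
  x <- mu * b / (.kB * temperature)
  if (any(abs(x) > 30)) {
    stop("|mu B / kB T| exceeds 30; rates would overflow", call. = FALSE)
  }
  p_down <- -expm1(-exp(-x) / (2 * tau) * dt)
  p_up <- -expm1(-exp(x) / (2 * tau) * dt)
  states <- with_seed(seed, {
    s0 <- if (stats::runif(1) < stats::plogis(2 * x[1])) 1L else -1L
    telegraph_chain(p_down, p_up, s0)
  })
  new_trajectory(times, mu * states,
                 list(model = "telegraph", mu = mu, tau = tau,
                      temperature = temperature, b_field = b_field,
                      dt = dt, seed = as.integer(seed)))
}

#' Simulate Ornstein-Uhlenbeck moment dynamics of an isotropic particle
#'
#' Stationary Gaussian process with mean zero, variance `msq_moment` and
#' autocorrelation \eqn{e^{-|t|/\tau}}, serving as surrogate for one
#' Cartesian moment component of an isotropic particle.  Uses the exact
#' discretization \eqn{x_{n+1} = \rho x_n + \sqrt{(1-\rho^2)\sigma^2}\,\xi}
#' with \eqn{\rho = e^{-dt/\tau}}, so the sampled chain has the continuous
#' process's exact covariances at the grid points (no Euler bias).
#'
#' @param msq_moment Stationary variance \eqn{\langle\mu_z^2\rangle}, emu^2.
#' @inheritParams simulate_telegraph
#' @return An object of class `trajectory`.
#' @examples
#' tr <- simulate_ou(msq_moment = 8.3e-28, tau = 1e-9,
#'                   duration = 2e-6, dt = 5e-11, seed = 1)
#' @export
simulate_ou <- function(msq_moment, tau, duration, dt = tau / 50, seed = 1L) {
  for (nm in c("msq_moment", "tau", "duration")) {
    assert_scalar(get(nm), nm)
    assert_positive(get(nm), nm)
  }
  check_dt(dt, tau)
  n <- floor(duration / dt)
  if (n < 10) stop("`duration` too short for the chosen `dt`", call. = FALSE)
  rho <- exp(-dt / tau)
  sd_stat <- sqrt(msq_moment)
  x <- with_seed(seed, {
    x0 <- stats::rnorm(1, 0, sd_stat)
    innov <- stats::rnorm(n, 0, sd_stat * sqrt(1 - rho^2))
    as.numeric(stats::filter(innov, rho, method = "recursive", init = x0))
  })
  new_trajectory((seq_len(n) - 1) * dt, x,
                 list(model = "ou", msq_moment = msq_moment, tau = tau,
                      dt = dt, seed = as.integer(seed)))
}

#' Sample autocorrelation of a trajectory with an exponential fit
#'
#' Computes the biased (normalized-by-n) sample autocovariance up to
#' `max_lag` and fits \eqn{C(t) = \sigma^2 e^{-t/\tau}} by log-linear
#' regression over the leading run of positive covariances above 5% of the
#' lag-0 value.  When the correlation decays within a couple of samples
#' (e.g. white noise) the time scale cannot be resolved and the fit is
#' flagged: `resolved = FALSE` and `tau` is reported at the grid scale.
#'
#' @param traj A `trajectory`.
#' @param max_lag Largest lag, s; at most a tenth of the trajectory length.
#' @return A list with `acf` (data frame `lag_s`, `covariance`), `variance`
#'   (lag-0 covariance), `tau` (fitted), and `resolved` (logical).
#' @examples
#' tr <- simulate_ou(1, tau = 1, duration = 2e3, dt = 0.05, seed = 7)
#' estimate_acf(tr, max_lag = 5)$tau
#' @export
estimate_acf <- function(traj, max_lag) {
  stopifnot(inherits(traj, "trajectory"))
  assert_positive(max_lag, "max_lag")
  dt <- traj$params$dt
  n <- length(traj$muz)
  if (max_lag > n * dt / 10) {
    stop("`max_lag` must not exceed a tenth of the trajectory duration",
         call. = FALSE)
  }
  nlag <- max(1L, as.integer(round(max_lag / dt)))
  a <- stats::acf(traj$muz, lag.max = nlag, type = "covariance",
                  plot = FALSE, demean = TRUE)
  cv <- as.numeric(a$acf)
  lags <- (seq_along(cv) - 1) * dt
  variance <- cv[1]

  # leading run of positive covariances, kept above 5% of the variance so
  # the noisy tail does not dominate the log fit
  run <- which(cv <= 0)
  run_end <- if (length(run)) run[1] - 1L else length(cv)
  fit_idx <- seq_len(run_end)
  fit_idx <- fit_idx[cv[fit_idx] >= 0.05 * variance]
  if (length(fit_idx) >= 3L) {
    fit <- lm(log(cv[fit_idx]) ~ lags[fit_idx])
    slope <- coef(fit)[[2]]
    tau_hat <- if (slope < 0) -1 / slope else Inf
  } else {
    tau_hat <- dt
  }
  resolved <- is.finite(tau_hat) && tau_hat > 2 * dt && length(fit_idx) >= 3L
  if (!resolved && !is.finite(tau_hat)) tau_hat <- dt
  list(acf = data.frame(lag_s = lags, covariance = cv),
       variance = variance, tau = tau_hat, resolved = resolved)
}

#' Welch-averaged spectral density estimate of a trajectory
#'
#' Splits the demeaned trajectory into non-overlapping segments, averages
#' the segment periodograms, and rescales to the two-sided angular-frequency
#' convention of [moment_psd()]: \eqn{S(\omega_k) = dt\,|X_k|^2/n}.  The
#' integral \eqn{\int S(\omega)\,d\omega/2\pi} over the returned grid equals
#' the sample variance (Parseval), up to the segment-mean correction.
#'
#' @param traj A `trajectory`.
#' @param segments Number of segments, at least 8.
#' @return A data frame with columns `omega` (rad/s, two-sided, ascending)
#'   and `density` (emu^2 s).
#' @examples
#' tr <- simulate_ou(1, tau = 1, duration = 4e3, dt = 0.05, seed = 3)
#' sp <- estimate_psd(tr, segments = 16)
#' @export
estimate_psd <- function(traj, segments = 16L) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(segments) || length(segments) != 1L || segments < 8) {
    stop("`segments` must be a single number >= 8", call. = FALSE)
  }
  segments <- as.integer(segments)
  dt <- traj$params$dt
  x <- traj$muz - mean(traj$muz)
  nper <- length(x) %/% segments
  if (nper < 32L) {
    stop("too few samples per segment (need at least 32)", call. = FALSE)
  }
  acc <- numeric(nper)
  for (s in seq_len(segments)) {
    seg <- x[((s - 1L) * nper + 1L):(s * nper)]
    acc <- acc + Mod(stats::fft(seg))^2
  }
  density <- dt * acc / (segments * nper)
  k <- seq_len(nper) - 1L
  k[k > nper %/% 2] <- k[k > nper %/% 2] - nper
  omega <- 2 * pi * k / (nper * dt)
  ord <- order(omega)
  data.frame(omega = omega[ord], density = density[ord])
}

#' Linear-response susceptibility estimate from a driven simulation
#'
#' Drives the telegraph model with \eqn{B(t) = b\cos(\omega t)} in the
#' linear regime (\eqn{\mu b/k_B T \le 0.2}) and projects the moment onto
#' the in-phase and quadrature components:
#' \eqn{\hat\alpha' = 2\overline{\mu_z\cos\omega t}/b},
#' \eqn{\hat\alpha'' = 2\overline{\mu_z\sin\omega t}/b}.  The analytic
#' expectation (Debye response) is [alpha_real()] / [alpha_imag()] with
#' \eqn{\langle\mu_z^2\rangle = \mu^2}.
#'
#' @inheritParams simulate_telegraph
#' @param b_amplitude Driving amplitude, G; must keep
#'   \eqn{\mu b/k_B T \le 0.2}.
#' @param omega Driving angular frequency, rad/s; `duration` must cover at
#'   least 200 driving periods.
#' @return A list with `alpha_real`, `alpha_imag` (emu/G), `omega` and the
#'   simulation parameters.
#' @examples
#' \donttest{
#' est <- estimate_response(mu = 5e-14, tau = 1e-9, temperature = 310,
#'                          b_amplitude = 0.08, omega = 1e9,
#'                          duration = 3e-6, dt = 5e-11, seed = 5)
#' }
#' @export
estimate_response <- function(mu, tau, temperature, b_amplitude, omega,
                              duration, dt = tau / 50, seed = 1L) {
  assert_positive(b_amplitude, "b_amplitude")
  assert_positive(omega, "omega")
  eps <- mu * b_amplitude / (.kB * temperature)
  if (eps > 0.2 * (1 + 1e-12)) {
    stop("`b_amplitude` outside the linear regime (mu b / kB T must be <= 0.2)",
         call. = FALSE)
  }
  if (duration < 200 * 2 * pi / omega) {
    stop("`duration` must cover at least 200 driving periods", call. = FALSE)
  }
  traj <- simulate_telegraph(mu, tau, temperature,
                             b_field = list(amplitude = b_amplitude,
                                            omega = omega, phase = 0),
                             duration = duration, dt = dt, seed = seed)
  ct <- cos(omega * traj$times)
  st <- sin(omega * traj$times)
  list(
    alpha_real = 2 * mean(traj$muz * ct) / b_amplitude,
    alpha_imag = 2 * mean(traj$muz * st) / b_amplitude,
    omega = omega,
    params = traj$params
  )
}
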