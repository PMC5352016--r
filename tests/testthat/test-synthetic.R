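# Shared long equilibrium run (zero field): reused by the spectral and
# fluctuation-dissipation blocks below.
tr_eq <- simulate_telegraph(mu = test_mu, tau = test_tau,
                            temperature = test_temp, b_field = 0,
                            duration = 1e5 * test_tau, dt = test_tau / 20,
                            seed = 101)
sp_eq <- estimate_psd(tr_eq, segments = 40)

test_that("zero-field telegraph equilibrium has zero mean and full variance", {
  tr <- simulate_telegraph(mu = test_mu, tau = test_tau,
                           temperature = test_temp, b_field = 0,
                           duration = 1e4 * test_tau, dt = test_tau / 50,
                           seed = 7)
  expect_true(all(tr$muz %in% c(-test_mu, test_mu)))
  n_tau <- 1e4
  se_mean <- test_mu * sqrt(2 / n_tau)       # exponential-correlation SE
  expect_lt(abs(mean(tr$muz)), 3 * se_mean)
  v <- mean((tr$muz - mean(tr$muz))^2)
  expect_equal(v, test_mu^2, tolerance = 3 * sqrt(2 / n_tau))
})

test_that("telegraph statistics follow tanh(mu B / kB T) from linear response to saturation", {
  # linear regime: <mu_z>/B recovers the static susceptibility mu^2 / kB T
  b_small <- 0.1 * test_kbt / test_mu
  tr <- simulate_telegraph(mu = test_mu, tau = test_tau,
                           temperature = test_temp, b_field = b_small,
                           duration = 4e5 * test_tau, dt = test_tau / 20,
                           seed = 13)
  alpha0_est <- mean(tr$muz) / b_small
  expect_equal(alpha0_est, test_mu^2 / test_kbt, tolerance = 0.10)

  # saturation: mu B / kB T = 10 pins the moment along the field
  b_large <- 10 * test_kbt / test_mu
  trs <- simulate_telegraph(mu = test_mu, tau = test_tau,
                            temperature = test_temp, b_field = b_large,
                            duration = 1e3 * test_tau, dt = test_tau / 20,
                            seed = 17)
  expect_gt(mean(trs$muz) / test_mu, 0.99)
})

test_that("trajectories are exactly reproducible from (params, seed)", {
  a <- simulate_telegraph(test_mu, test_tau, test_temp, 0,
                          duration = 500 * test_tau, seed = 99)
  b <- simulate_telegraph(test_mu, test_tau, test_temp, 0,
                          duration = 500 * test_tau, seed = 99)
  expect_identical(a$muz, b$muz)
  c <- simulate_telegraph(test_mu, test_tau, test_temp, 0,
                          duration = 500 * test_tau, seed = 100)
  expect_false(identical(a$muz, c$muz))
  o1 <- simulate_ou(1, 1, duration = 200, dt = 0.05, seed = 5)
  o2 <- simulate_ou(1, 1, duration = 200, dt = 0.05, seed = 5)
  expect_identical(o1$muz, o2$muz)
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_ou(1, 1, duration = 200, dt = 0.05, seed = 2))
  expect_identical(runif(1), before)
})

test_that("Ornstein-Uhlenbeck surrogate is stationary with the exact autocorrelation", {
  tr <- simulate_ou(msq_moment = 1, tau = 1, duration = 1e4, dt = 1 / 50,
                    seed = 23)
  v <- mean((tr$muz - mean(tr$muz))^2)
  expect_equal(v, 1, tolerance = 3 * sqrt(2 / 1e4))
  # lag-tau sample autocorrelation near 1/e
  k <- round(1 / tr$params$dt)
  x <- tr$muz - mean(tr$muz)
  r <- mean(x[seq_len(length(x) - k)] * x[-seq_len(k)]) / v
  expect_equal(r, exp(-1), tolerance = 0.05)
  # a different seed gives a different path but the same physics
  tr2 <- simulate_ou(msq_moment = 1, tau = 1, duration = 1e4, dt = 1 / 50,
                     seed = 24)
  expect_false(identical(tr$muz, tr2$muz))
  expect_equal(estimate_acf(tr2, max_lag = 5)$tau, 1, tolerance = 0.1)
})

test_that("autocorrelation estimator recovers variance and relaxation time", {
  tr <- simulate_ou(msq_moment = 2.5, tau = 1, duration = 1e4, dt = 1 / 50,
                    seed = 29)
  est <- estimate_acf(tr, max_lag = 6)
  expect_equal(est$tau, 1, tolerance = 0.1)
  expect_true(est$resolved)
  # lag 0 is exactly the biased sample variance
  expect_equal(est$variance, mean((tr$muz - mean(tr$muz))^2))
  expect_equal(est$acf$covariance[1], est$variance)

  # telegraph trajectories decay with the same exponential law
  trt <- simulate_telegraph(test_mu, test_tau, test_temp, 0,
                            duration = 2e4 * test_tau, dt = test_tau / 50,
                            seed = 31)
  expect_equal(estimate_acf(trt, max_lag = 6 * test_tau)$tau, test_tau,
               tolerance = 0.1)
})

test_that("white-noise input is flagged as unresolved at the grid scale", {
  dt <- 0.01
  wn <- structure(
    list(times = (0:49999) * dt,
         muz = local({set.seed(37); rnorm(50000)}),
         params = list(model = "ou", tau = dt, dt = dt, seed = 37L)),
    class = "trajectory")
  est <- estimate_acf(wn, max_lag = 1)
  expect_false(est$resolved)
  expect_lt(est$tau, 2 * dt)
})

test_that("Welch spectrum reproduces the Lorentzian plateau, half-power point and variance", {
  plateau <- psd_band_mean(sp_eq, 0, 0.1 / test_tau)
  expect_equal(plateau, 2 * test_tau * test_mu^2, tolerance = 0.15)
  half <- psd_band_mean(sp_eq, 0.9 / test_tau, 1.1 / test_tau)
  expect_equal(half / plateau, 0.5, tolerance = 0.15)
  # Parseval: integral over the angular grid returns the sample variance
  domega <- diff(sp_eq$omega[1:2])
  integral <- sum(sp_eq$density) * domega / (2 * pi)
  expect_equal(integral, mean((tr_eq$muz - mean(tr_eq$muz))^2),
               tolerance = 0.05)
})

test_that("driven simulations recover the Debye susceptibility", {
  alpha0 <- test_mu^2 / test_kbt
  b <- 0.2 * test_kbt / test_mu

  # quasi-static drive: in-phase response, vanishing quadrature
  est0 <- estimate_response(test_mu, test_tau, test_temp, b,
                            omega = 0.05 / test_tau,
                            duration = 5e4 * test_tau, dt = test_tau / 20,
                            seed = 43)
  expect_equal(est0$alpha_real, alpha0, tolerance = 0.10)
  expect_lt(abs(est0$alpha_imag), 0.15 * alpha0)

  # at omega tau = 1 the dissipative part peaks at mu^2 / (2 kB T)
  est1 <- estimate_response(test_mu, test_tau, test_temp, b,
                            omega = 1 / test_tau,
                            duration = 1e5 * test_tau, dt = test_tau / 20,
                            seed = 47)
  expect_equal(est1$alpha_imag, alpha0 / 2, tolerance = 0.15)

  # halving the drive within the linear regime leaves the estimate unchanged
  est_half <- estimate_response(test_mu, test_tau, test_temp, b / 2,
                                omega = 1 / test_tau,
                                duration = 1e5 * test_tau, dt = test_tau / 20,
                                seed = 53)
  mod1 <- sqrt(est1$alpha_real^2 + est1$alpha_imag^2)
  mod2 <- sqrt(est_half$alpha_real^2 + est_half$alpha_imag^2)
  expect_equal(mod2 / mod1, 1, tolerance = 0.2)
})

test_that("fluctuation and dissipation sides close on the FDT and the NEP", {
  s_uni <- noise_spectrum(msq_moment = test_mu^2, tau = test_tau,
                          temperature = test_temp, eta = 1)
  b <- 0.2 * test_kbt / test_mu
  durations <- c(`0.3` = 3e5, `1` = 1e5, `3` = 1e5)
  for (wt in c(0.3, 1, 3)) {
    w <- wt / test_tau
    s_hat <- psd_band_mean(sp_eq, 0.9 * w, 1.1 * w)
    est <- estimate_response(test_mu, test_tau, test_temp, b, omega = w,
                             duration = durations[[as.character(wt)]] * test_tau,
                             dt = test_tau / 20, seed = 59 + wt)
    # alpha''(w) = w S(w) / (2 kB T), both sides estimated from simulation
    expect_equal(est$alpha_imag, w * s_hat / (2 * test_kbt),
                 tolerance = 0.2)
    if (wt == 1) {
      nep_hat <- s_hat / (est$alpha_real^2 + est$alpha_imag^2)
      expect_equal(nep_hat, nep(s_uni), tolerance = 0.25)
    }
  }
})

test_that("simulators and estimators reject inadequate inputs", {
  expect_error(simulate_telegraph(test_mu, test_tau, test_temp, 0,
                                  duration = 100 * test_tau,
                                  dt = test_tau / 5), "tau/20")
  expect_error(simulate_ou(1, 1, duration = 100, dt = 0.3), "tau/20")
  expect_error(simulate_telegraph(test_mu, test_tau, test_temp,
                                  b_field = 40 * test_kbt / test_mu,
                                  duration = 100 * test_tau), "overflow|30")
  tr <- simulate_ou(1, 1, duration = 300, dt = 0.05, seed = 2)
  expect_error(estimate_acf(tr, max_lag = 100), "tenth")
  expect_error(estimate_psd(tr, segments = 4), ">= 8")
  expect_error(estimate_psd(simulate_ou(1, 1, duration = 20, dt = 0.05),
                            segments = 16), "at least 32")
  expect_error(estimate_response(test_mu, test_tau, test_temp,
                                 b_amplitude = test_kbt / test_mu,
                                 omega = 1 / test_tau,
                                 duration = 1e4 * test_tau), "linear")
  expect_error(estimate_response(test_mu, test_tau, test_temp,
                                 b_amplitude = 0.1 * test_kbt / test_mu,
                                 omega = 1 / test_tau,
                                 duration = 10 * test_tau), "200")
})
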