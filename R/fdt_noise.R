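# Fluctuation-dissipation machinery.  The moment projection mu_z of a
# superparamagnetic particle decays with a single relaxation time tau, so its
# equilibrium fluctuations have an exponential autocorrelation and a
# Lorentzian two-sided spectrum over angular frequency,
#   S(omega) = <mu_z^2> 2 tau / (1 + omega^2 tau^2)   [emu^2 s].
# The FDT ties S to the dissipative part of the generalized susceptibility,
#   alpha''(omega) = omega S(omega) / (2 kB T),
# and Kramers-Kronig fixes the real part.  The ratio S/|alpha|^2 is the
# noise-equivalent power of the particle viewed as a magnetic antenna; it is
# frequency independent.

#' One-axis moment fluctuation model of a particle
#'
#' Collects the quantities the fluctuation-dissipation calculations need:
#' the mean squared moment projection, the relaxation time, the temperature
#' and the anisotropy factor \eqn{\eta}.  Usually constructed from a
#' [particle()]; the raw fields can also be supplied directly.
#'
#' @param p A [particle()], or `NULL` when supplying raw fields.
#' @param msq_moment Mean squared moment projection
#'   \eqn{\langle\mu_z^2\rangle}, emu^2.
#' @param tau Relaxation time, s.
#' @param temperature Absolute temperature, K.
#' @param eta Anisotropy factor, 3 (isotropic) or 1 (strong uniaxial).
#' @return An object of class `noise_spectrum`.
#' @examples
#' s <- noise_spectrum(particle(volume = 1e-16, tau = 1.3e-12))
#' nep(s)
#' @export
noise_spectrum <- function(p = NULL, msq_moment = NULL, tau = NULL,
                           temperature = NULL, eta = NULL) {
  if (!is.null(p)) {
    stopifnot(inherits(p, "particle"))
    msq_moment <- mean_squared_moment(p)
    tau <- p$tau
    temperature <- p$temperature
    eta <- particle_eta(p)
  }
  for (nm in c("msq_moment", "tau", "temperature")) {
    assert_scalar(get(nm), nm)
    assert_positive(get(nm), nm)
  }
  if (!eta %in% c(1, 3)) stop("`eta` must be 1 or 3", call. = FALSE)
  structure(
    list(msq_moment = msq_moment, tau = tau,
         temperature = temperature, eta = as.integer(eta)),
    class = "noise_spectrum"
  )
}

#' @export
print.noise_spectrum <- function(x, ...) {
  cat("Moment fluctuation spectrum (one axis)\n")
  cat(sprintf("  <mu_z^2>: %.4g emu^2   tau: %.4g s\n", x$msq_moment, x$tau))
  cat(sprintf("  T: %.4g K   eta: %d\n", x$temperature, x$eta))
  cat(sprintf("  NEP: %.4g G^2/Hz (%.4g nT^2/Hz)\n",
              nep(x), g2_per_hz_to_nt2_per_hz(nep(x))))
  invisible(x)
}

#' Equilibrium autocorrelation of the moment projection
#'
#' \eqn{\langle\mu_z(0)\mu_z(t)\rangle = \langle\mu_z^2\rangle
#' e^{-|t|/\tau}}: even in the lag, maximal at zero lag.
#'
#' @param s A [noise_spectrum()].
#' @param t Lag, s (vectorised).
#' @return Correlation, emu^2.
#' @export
autocorrelation <- function(s, t) {
  stopifnot(inherits(s, "noise_spectrum"))
  s$msq_moment * exp(-abs(t) / s$tau)
}

#' Two-sided spectral power density of the moment projection
#'
#' The Fourier transform of the exponential autocorrelation: a Lorentzian
#' over angular frequency,
#' \eqn{S(\omega) = \langle\mu_z^2\rangle\, 2\tau/(1+\omega^2\tau^2)}.
#' Integrating \eqn{S(\omega)\,d\omega/2\pi} over the real line returns the
#' variance \eqn{\langle\mu_z^2\rangle}.
#'
#' @param s A [noise_spectrum()].
#' @param omega Angular frequency, rad/s (vectorised, finite).
#' @return Spectral density, emu^2 s.
#' @export
moment_psd <- function(s, omega) {
  stopifnot(inherits(s, "noise_spectrum"))
  if (any(!is.finite(omega))) stop("`omega` must be finite", call. = FALSE)
  s$msq_moment * 2 * s$tau / (1 + omega^2 * s$tau^2)
}

#' Generalized susceptibility of the particle
#'
#' The complex coefficient relating the induced moment to an oscillating
#' applied field.  The fluctuation-dissipation theorem gives the imaginary
#' (dissipative) part directly from the fluctuation spectrum,
#' \deqn{\alpha''(\omega) = \frac{\omega}{2 k_B T} S(\omega)
#'   = \frac{\langle\mu_z^2\rangle}{k_B T}
#'     \frac{\omega\tau}{1+\omega^2\tau^2},}
#' and the Kramers-Kronig relations fix the real part,
#' \deqn{\alpha'(\omega) = \frac{\langle\mu_z^2\rangle}{k_B T}
#'   \frac{1}{1+\omega^2\tau^2}.}
#' `alpha_imag` is defined for \eqn{\omega \ge 0} (physical driving
#' frequencies); its odd extension covers negative frequencies.
#'
#' @param s A [noise_spectrum()].
#' @param omega Angular frequency, rad/s (vectorised; non-negative for
#'   `alpha_imag`).
#' @return Susceptibility, emu/G (`alpha_abs2`: its squared modulus,
#'   (emu/G)^2).
#' @examples
#' s <- noise_spectrum(particle(volume = 1e-16, tau = 1e-9))
#' alpha_real(s, 0) * mag_constants()$kb_erg_per_k * 310  # = <mu_z^2>
#' @export
alpha_imag <- function(s, omega) {
  stopifnot(inherits(s, "noise_spectrum"))
  assert_nonnegative(omega, "omega")
  s$msq_moment / (.kB * s$temperature) *
    omega * s$tau / (1 + omega^2 * s$tau^2)
}

#' @rdname alpha_imag
#' @export
alpha_real <- function(s, omega) {
  stopifnot(inherits(s, "noise_spectrum"))
  if (any(!is.finite(omega))) stop("`omega` must be finite", call. = FALSE)
  s$msq_moment / (.kB * s$temperature) / (1 + omega^2 * s$tau^2)
}

#' @rdname alpha_imag
#' @export
alpha_abs2 <- function(s, omega) {
  stopifnot(inherits(s, "noise_spectrum"))
  if (any(!is.finite(omega))) stop("`omega` must be finite", call. = FALSE)
  (s$msq_moment / (.kB * s$temperature))^2 / (1 + omega^2 * s$tau^2)
}

#' Noise-equivalent power of the particle as a magnetic antenna
#'
#' NEP is the input-field spectral power that produces, per unit bandwidth,
#' the same output as the antenna's own fluctuations: the ratio
#' \eqn{S(\omega)/|\alpha(\omega)|^2}.  For the Lorentzian/Debye pair this
#' ratio is frequency independent,
#' \deqn{b^2_{NEP} = \frac{2 (k_B T)^2 \tau}{\langle\mu_z^2\rangle}
#'   = \frac{2 \eta (k_B T)^2 \tau}{M_s^2 V^2},}
#' in G\eqn{^2}/Hz.  Both closed forms are implemented -- the
#' `noise_spectrum` method uses the variance route, the `particle` method
#' the \eqn{\eta/M_s^2V^2} route -- and agree identically since
#' \eqn{\langle\mu_z^2\rangle = (M_s V)^2/\eta}.
#'
#' @param x A [noise_spectrum()] or a [particle()].
#' @param ... Unused.
#' @return NEP, G^2/Hz.  See [nep_report()] for both unit systems at once.
#' @examples
#' nep(particle(volume = 1e-16, tau = 1.3e-12))  # ~5.7e-12 G^2/Hz
#' @export
nep <- function(x, ...) UseMethod("nep")

#' @rdname nep
#' @export
nep.noise_spectrum <- function(x, ...) {
  2 * (.kB * x$temperature)^2 * x$tau / x$msq_moment
}

#' @rdname nep
#' @export
nep.particle <- function(x, ...) {
  2 * particle_eta(x) * (.kB * x$temperature)^2 * x$tau /
    (x$ms^2 * x$volume^2)
}

#' @rdname nep
#' @return `nep_report()`: a named list with the NEP in `g2_per_hz` and
#'   `nt2_per_hz` side by side (the unit trap between the radical-pair
#'   comparison, quoted in nT^2/Hz, and the feasibility threshold, quoted in
#'   G^2/Hz, is easy to fall into).
#' @export
nep_report <- function(x, ...) {
  v <- nep(x, ...)
  list(g2_per_hz = v, nt2_per_hz = g2_per_hz_to_nt2_per_hz(v))
}
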