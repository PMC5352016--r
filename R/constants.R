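# Gaussian CGS is the internal unit system throughout: magnetic fields in
# gauss (G), moments in emu (= G cm^3), energies in erg, times in seconds.
# Laboratory-facing quantities are quoted in nT and Hz; the converters below
# are the single crossing point between the two systems.

.kB <- 1.380649e-16      # Boltzmann constant, erg/K (exact SI value rescaled)
.gamma_e <- 176          # electron gyromagnetic ratio, rad s^-1 nT^-1
.G_PER_NT <- 1e-5        # 1 nT = 1e-5 G

#' Physical constants used by the package
#'
#' Returns the constants every other function relies on, in the package's
#' internal Gaussian CGS unit system.  The electron gyromagnetic ratio is
#' kept at the working value 176 rad s\eqn{^{-1}} nT\eqn{^{-1}} used in the
#' radical-pair spectral-density estimates.
#'
#' @return A named list with elements `kb_erg_per_k`, `gamma_e_rad_s_nt`,
#'   `gauss_per_nanotesla` and `two_pi`.
#' @examples
#' mag_constants()$gamma_e_rad_s_nt
#' @export
mag_constants <- function() {
  list(
    kb_erg_per_k = .kB,
    gamma_e_rad_s_nt = .gamma_e,
    gauss_per_nanotesla = .G_PER_NT,
    two_pi = 2 * pi
  )
}

#' Convert field spectral power densities between nT^2/Hz and G^2/Hz
#'
#' A field spectral power density scales with the square of the field unit,
#' so 1 nT\eqn{^2}/Hz = 10\eqn{^{-10}} G\eqn{^2}/Hz.  The two functions are
#' exact inverses.
#'
#' @param psd Spectral power density (vectorised), must be non-negative.
#' @return The same density in the other unit system.
#' @examples
#' nt2_per_hz_to_g2_per_hz(1e-4)  # 1e-14 G^2/Hz
#' @export
nt2_per_hz_to_g2_per_hz <- function(psd) {
  assert_nonnegative(psd, "psd")
  psd * .G_PER_NT^2
}

#' @rdname nt2_per_hz_to_g2_per_hz
#' @export
g2_per_hz_to_nt2_per_hz <- function(psd) {
  assert_nonnegative(psd, "psd")
  psd / .G_PER_NT^2
}

#' Convert spectral densities between per-rad/s and per-Hz conventions
#'
#' A density quoted "per Hz" is 2\eqn{\pi} times the same two-sided density
#' per rad/s: the variance carried in a 1 Hz band equals that carried in a
#' 2\eqn{\pi} rad/s band.  This single convention reconciles rad-based
#' gyromagnetic ratios with per-Hz quoting of field noise.
#'
#' @param psd Spectral density (vectorised), must be non-negative.
#' @return The density in the other convention.
#' @examples
#' angular_psd_to_per_hz(1 / (2 * pi))  # 1
#' @export
angular_psd_to_per_hz <- function(psd) {
  assert_nonnegative(psd, "psd")
  psd * 2 * pi
}

#' @rdname angular_psd_to_per_hz
#' @export
per_hz_to_angular_psd <- function(psd) {
  assert_nonnegative(psd, "psd")
  psd / (2 * pi)
}

#' @rdname nt2_per_hz_to_g2_per_hz
#' @param field Magnetic field amplitude (vectorised), non-negative.
#' @export
nanotesla_to_gauss <- function(field) {
  assert_nonnegative(field, "field")
  field * .G_PER_NT
}

#' @rdname nt2_per_hz_to_g2_per_hz
#' @export
gauss_to_nanotesla <- function(field) {
  assert_nonnegative(field, "field")
  field / .G_PER_NT
}
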