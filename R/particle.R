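# The particle-as-amplifier model: a single-domain nanocrystal above its
# blocking temperature behaves as a giant paramagnet.  Its Curie
# susceptibility chi = V Ms^2 / (3 kB T) converts, via k = 1 + 4 pi chi,
# into the relative permeability with which it amplifies an applied field.

#' Construct a single-domain magnetic nanoparticle
#'
#' Bundles the physical parameters of a single-domain nanocrystal.  The
#' particle's magnetic moment \eqn{\mu = M_s V} (emu) is a derived quantity,
#' available through [magnetic_moment()].  The anisotropy regime controls the
#' moment-projection statistics: an isotropic (or cubic) particle spreads its
#' moment over all three axes (\eqn{\eta = 3}), while strong uniaxial
#' anisotropy confines it to \eqn{\pm} the easy axis (\eqn{\eta = 1}).
#'
#' @param volume Particle volume, cm^3.
#' @param ms Saturation magnetization, G.  500 G is a generous upper estimate
#'   for biogenic iron oxides; see [saturation_magnetization()] for material
#'   presets (magnetite 475 G, greigite 240 G).
#' @param temperature Absolute temperature, K.  Defaults to 310 K
#'   (physiological).
#' @param tau Moment relaxation (Neel) time, s.  Defaults to 1 ns, a
#'   realistic order of magnitude for magnetite nanoparticles.
#' @param anisotropy `"isotropic"` or `"strong_uniaxial"`.
#' @return An object of class `particle`.
#' @examples
#' p <- particle(volume = 1.3e-17)
#' magnetic_moment(p)
#' @export
particle <- function(volume, ms = 500, temperature = 310, tau = 1e-9,
                     anisotropy = c("isotropic", "strong_uniaxial")) {
  anisotropy <- match.arg(anisotropy)
  for (nm in c("volume", "ms", "temperature", "tau")) {
    assert_scalar(get(nm), nm)
    assert_positive(get(nm), nm)
  }
  structure(
    list(volume = volume, ms = ms, temperature = temperature,
         tau = tau, anisotropy = anisotropy),
    class = "particle"
  )
}

#' @export
print.particle <- function(x, ...) {
  cat("Single-domain magnetic nanoparticle\n")
  cat(sprintf("  volume:      %.4g cm^3 (cube edge %.3g nm)\n",
              x$volume, equivalent_cube_edge(x$volume)))
  cat(sprintf("  Ms:          %.4g G    moment: %.4g emu\n",
              x$ms, magnetic_moment(x)))
  cat(sprintf("  temperature: %.4g K    tau: %.4g s\n", x$temperature, x$tau))
  cat(sprintf("  anisotropy:  %s (eta = %d)\n", x$anisotropy, particle_eta(x)))
  invisible(x)
}

#' @rdname particle
#' @param p A `particle` object.
#' @export
magnetic_moment <- function(p) {
  stopifnot(inherits(p, "particle"))
  p$ms * p$volume
}

#' @rdname particle
#' @export
particle_eta <- function(p) {
  stopifnot(inherits(p, "particle"))
  if (p$anisotropy == "isotropic") 3L else 1L
}

#' Saturation magnetization presets for candidate biogenic materials
#'
#' @param material One of `"upper"` (500 G, generous upper estimate),
#'   `"magnetite"` (475 G, midpoint of the 470-480 G range) or
#'   `"greigite"` (240 G).
#' @return Saturation magnetization in G.
#' @examples
#' saturation_magnetization("magnetite")
#' @export
saturation_magnetization <- function(material = c("upper", "magnetite", "greigite")) {
  material <- match.arg(material)
  c(upper = 500, magnetite = 475, greigite = 240)[[material]]
}

#' Volume susceptibility of a superparamagnetic particle
#'
#' Above the blocking temperature the particle's moment reorients thermally
#' and the particle shows the Curie (paramagnetic) susceptibility
#' \deqn{\chi = V M_s^2 / (3 k_B T),}
#' dimensionless in CGS, linear in volume and inversely proportional to
#' temperature.
#'
#' @param p A [particle()].
#' @return Volume susceptibility \eqn{\chi} (dimensionless, CGS).
#' @examples
#' susceptibility(particle(volume = 1.22e-17))
#' @export
susceptibility <- function(p) {
  stopifnot(inherits(p, "particle"))
  p$volume * p$ms^2 / (3 * .kB * p$temperature)
}

#' Relative permeability from the volume susceptibility
#'
#' In CGS, \eqn{k = 1 + 4\pi\chi}.  The permeability is the factor by which
#' the particle amplifies an external field at its surface.
#'
#' @param chi Volume susceptibility, non-negative (vectorised).
#' @return Relative permeability \eqn{k \ge 1}.
#' @examples
#' permeability(susceptibility(particle(volume = 1.22e-17)))
#' @export
permeability <- function(chi) {
  assert_nonnegative(chi, "chi")
  1 + 4 * pi * chi
}

#' Field at the particle surface for a given external driving field
#'
#' The simplest iron-core-electromagnet picture: the maximum enhanced field
#' near the particle is \eqn{B_1 = k\, b_1}.
#'
#' @param k Relative permeability, \eqn{\ge 1} (vectorised).
#' @param b1 External driving field amplitude, nT (vectorised, non-negative).
#' @return Amplified field, nT.
#' @examples
#' amplified_field(300, 1)
#' @export
amplified_field <- function(k, b1) {
  if (!is.numeric(k) || anyNA(k) || any(k < 1)) {
    stop("`k` must be >= 1 (a permeability)", call. = FALSE)
  }
  assert_nonnegative(b1, "b1")
  k * b1
}

#' Minimum particle volume delivering a target permeability
#'
#' Inverts the susceptibility/permeability chain: the smallest volume whose
#' permeability at the given `ms` and `temperature` reaches `k_target` is
#' \deqn{V = 3 k_B T (k - 1) / (4 \pi M_s^2).}
#' The result round-trips exactly through [susceptibility()] and
#' [permeability()].
#'
#' @param k_target Required relative permeability, > 1.
#' @param ms Saturation magnetization, G.
#' @param temperature Absolute temperature, K.
#' @return Volume, cm^3.
#' @examples
#' # the minimum amplifier volume for 300-fold amplification
#' min_volume_for_permeability(300)
#' @export
min_volume_for_permeability <- function(k_target, ms = 500, temperature = 310) {
  if (!is.numeric(k_target) || anyNA(k_target) || any(k_target <= 1)) {
    stop("`k_target` must be > 1", call. = FALSE)
  }
  assert_positive(ms, "ms")
  assert_positive(temperature, "temperature")
  3 * .kB * temperature * (k_target - 1) / (4 * pi * ms^2)
}

#' Edge of the cube with a given volume
#'
#' @param volume Volume, cm^3 (vectorised, positive).
#' @return Cube edge length, nm.
#' @examples
#' equivalent_cube_edge(1e-16)  # ~46 nm
#' @export
equivalent_cube_edge <- function(volume) {
  assert_positive(volume, "volume")
  volume^(1 / 3) * 1e7
}

#' Mean squared moment projection on the observation axis
#'
#' The exchange interaction pins the magnitude of the moment at
#' \eqn{\mu = M_s V}; thermal agitation randomises its direction.  The mean
#' squared projection on a given axis is \eqn{\mu^2/3} for an isotropic (or
#' cubic) particle and the full \eqn{\mu^2} under strong uniaxial anisotropy,
#' i.e. \eqn{\langle\mu_z^2\rangle = \mu^2/\eta}.
#'
#' @param p A [particle()].
#' @return \eqn{\langle\mu_z^2\rangle}, emu^2.
#' @examples
#' mean_squared_moment(particle(volume = 1e-16))
#' @export
mean_squared_moment <- function(p) {
  stopifnot(inherits(p, "particle"))
  magnetic_moment(p)^2 / particle_eta(p)
}

#' Is a particle small enough to be superparamagnetic?
#'
#' Compares the volume against the boundary between superparamagnetic and
#' blocked single-domain magnetite crystals of small aspect ratio, about
#' 1e-16 cm^3.  The comparison is strict (`volume < bound`); a particle
#' exactly at the boundary is classified as blocked.
#'
#' @param volume Particle volume, cm^3 (vectorised, positive).
#' @param bound Boundary volume, cm^3.
#' @return Logical.
#' @examples
#' is_superparamagnetic(1.3e-17)
#' @export
is_superparamagnetic <- function(volume, bound = 1e-16) {
  assert_positive(volume, "volume")
  assert_positive(bound, "bound")
  volume < bound
}
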