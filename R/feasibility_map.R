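# The feasibility sweep: over a log-spaced grid of volumes and relaxation
# times, evaluate the NEP and the two volume-only constraints (enough
# permeability, still superparamagnetic) and ask whether any cell is also
# quiet enough to fall below the behavioural noise threshold.  NEP increases
# with tau and decreases with V, so the minimum over the admissible region
# sits at its largest-volume, shortest-tau corner.

#' Build a feasibility map over the volume-relaxation-time plane
#'
#' Evaluates, on a log-spaced \eqn{V \times \tau} grid, the particle's
#' noise-equivalent power and three boolean masks: `permeable` (relative
#' permeability at least `k_min`), `superparamagnetic` (volume strictly
#' below `v_bound`) and `quiet` (NEP at or below `nep_threshold`).  The
#' first two depend on volume only; `quiet` depends on both axes.  Every
#' cell is computed with the scalar pipeline ([susceptibility()],
#' [permeability()], [nep()]), so the map is exactly reproducible pointwise.
#'
#' @param ms Saturation magnetization, G.
#' @param temperature Absolute temperature, K.
#' @param anisotropy `"isotropic"` or `"strong_uniaxial"`.
#' @param k_min Required relative permeability.
#' @param v_bound Superparamagnetic volume boundary, cm^3.
#' @param nep_threshold Behavioural noise-power threshold, G^2/Hz.
#' @param v_range Length-2 volume range, cm^3.
#' @param tau_range Length-2 relaxation-time range, s.  The default lower
#'   end, 1.3e-12 s, is the shortest relaxation time reported for magnetite
#'   nanoparticles; ~1 ns is more realistic.
#' @param resolution Grid points per axis (scalar or length 2).
#' @return An object of class `feasibility_map` with fields `v_grid`,
#'   `tau_grid`, `nep_grid` (volume x tau matrix, G^2/Hz), `k` (per volume),
#'   `mask_permeability`, `mask_superparamagnetic` (per volume),
#'   `mask_quiet` (matrix) and `params`.
#' @examples
#' m <- build_feasibility_map(resolution = 60)
#' viable_region_empty(m)
#' @export
build_feasibility_map <- function(ms = 500, temperature = 310,
                                  anisotropy = c("isotropic", "strong_uniaxial"),
                                  k_min = 300, v_bound = 1e-16,
                                  nep_threshold = 1e-14,
                                  v_range = c(1e-18, 1e-15),
                                  tau_range = c(1.3e-12, 1e-7),
                                  resolution = 200) {
  anisotropy <- match.arg(anisotropy)
  assert_positive(ms, "ms")
  assert_positive(temperature, "temperature")
  assert_positive(k_min, "k_min")
  assert_positive(v_bound, "v_bound")
  assert_positive(nep_threshold, "nep_threshold")
  assert_positive(v_range, "v_range")
  assert_positive(tau_range, "tau_range")
  if (length(v_range) != 2L || v_range[2] <= v_range[1]) {
    stop("`v_range` must be an increasing length-2 range", call. = FALSE)
  }
  if (length(tau_range) != 2L || tau_range[2] <= tau_range[1]) {
    stop("`tau_range` must be an increasing length-2 range", call. = FALSE)
  }
  resolution <- as.integer(rep_len(resolution, 2L))
  if (any(resolution < 1L)) stop("`resolution` must be >= 1", call. = FALSE)

  v_grid <- 10^seq(log10(v_range[1]), log10(v_range[2]), length.out = resolution[1])
  tau_grid <- 10^seq(log10(tau_range[1]), log10(tau_range[2]), length.out = resolution[2])
  if (resolution[1] == 1L) v_grid <- v_range[1]
  if (resolution[2] == 1L) tau_grid <- tau_range[1]

  eta <- if (anisotropy == "isotropic") 3L else 1L
  k <- permeability(v_grid * ms^2 / (3 * .kB * temperature))
  nep_grid <- outer(2 * eta * (.kB * temperature)^2 / (ms^2 * v_grid^2), tau_grid)

  structure(
    list(
      v_grid = v_grid,
      tau_grid = tau_grid,
      nep_grid = nep_grid,
      k = k,
      mask_permeability = k >= k_min,
      mask_superparamagnetic = v_grid < v_bound,
      mask_quiet = nep_grid <= nep_threshold,
      params = list(ms = ms, temperature = temperature, eta = eta,
                    anisotropy = anisotropy, k_min = k_min,
                    v_bound = v_bound, nep_threshold = nep_threshold)
    ),
    class = "feasibility_map"
  )
}

#' Is the viable region of a feasibility map empty?
#'
#' A cell is viable when it passes all three masks: permeable enough,
#' superparamagnetic, and quiet (NEP at or below the threshold).  Returns
#' the emptiness verdict together with a diagnostic: the minimum NEP over
#' the admissible (permeable and superparamagnetic) region, the cell that
#' attains it, and its ratio to the threshold.  A ratio above 1 means even
#' the best admissible particle is noisier than the behavioural threshold.
#'
#' @param map A [build_feasibility_map()] result.
#' @return An object of class `viability`: a list with `empty` (logical),
#'   `min_nep` (G^2/Hz, `NA` if no cell is admissible), `v_at`, `tau_at`,
#'   and `ratio_to_threshold`.
#' @examples
#' viable_region_empty(build_feasibility_map(resolution = 60))
#' @export
viable_region_empty <- function(map) {
  stopifnot(inherits(map, "feasibility_map"))
  admissible <- map$mask_permeability & map$mask_superparamagnetic
  if (!any(admissible)) {
    out <- list(empty = TRUE, min_nep = NA_real_, v_at = NA_real_,
                tau_at = NA_real_, ratio_to_threshold = NA_real_)
    return(structure(out, class = "viability"))
  }
  sub <- map$nep_grid[admissible, , drop = FALSE]
  idx <- which(sub == min(sub), arr.ind = TRUE)[1, ]
  v_at <- map$v_grid[admissible][idx[1]]
  tau_at <- map$tau_grid[idx[2]]
  min_nep <- sub[idx[1], idx[2]]
  structure(
    list(
      empty = !any(map$mask_quiet[admissible, , drop = FALSE]),
      min_nep = min_nep,
      v_at = v_at,
      tau_at = tau_at,
      ratio_to_threshold = min_nep / map$params$nep_threshold
    ),
    class = "viability"
  )
}

#' @export
print.viability <- function(x, ...) {
  if (x$empty) {
    cat("Viable region is EMPTY: no admissible particle is quiet enough.\n")
  } else {
    cat("Viable region is NON-EMPTY.\n")
  }
  if (!is.na(x$min_nep)) {
    cat(sprintf("  min NEP over admissible region: %.4g G^2/Hz\n", x$min_nep))
    cat(sprintf("  attained at V = %.4g cm^3, tau = %.4g s\n", x$v_at, x$tau_at))
    cat(sprintf("  ratio to threshold: %.4g\n", x$ratio_to_threshold))
  } else {
    cat("  no cell satisfies the permeability and superparamagnetism masks\n")
  }
  invisible(x)
}

#' @export
print.feasibility_map <- function(x, ...) {
  p <- x$params
  cat("Feasibility map over the V-tau plane\n")
  cat(sprintf("  grid: %d volumes x %d relaxation times (log-spaced)\n",
              length(x$v_grid), length(x$tau_grid)))
  cat(sprintf("  V: [%.3g, %.3g] cm^3   tau: [%.3g, %.3g] s\n",
              min(x$v_grid), max(x$v_grid), min(x$tau_grid), max(x$tau_grid)))
  cat(sprintf("  Ms = %g G, T = %g K, %s; k_min = %g, v_bound = %.3g cm^3\n",
              p$ms, p$temperature, p$anisotropy, p$k_min, p$v_bound))
  cat(sprintf("  NEP threshold: %.3g G^2/Hz\n", p$nep_threshold))
  print(viable_region_empty(x))
  invisible(x)
}

#' @describeIn build_feasibility_map Flatten the map to a long data frame
#'   with columns `v_cm3`, `tau_s`, `nep_g2_per_hz`, `k`,
#'   `superparamagnetic`, `quiet` (the canonical CSV layout).
#' @param x A `feasibility_map`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @export
as.data.frame.feasibility_map <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  nv <- length(x$v_grid)
  nt <- length(x$tau_grid)
  data.frame(
    v_cm3 = rep(x$v_grid, times = nt),
    tau_s = rep(x$tau_grid, each = nv),
    nep_g2_per_hz = as.vector(x$nep_grid),
    k = rep(x$k, times = nt),
    superparamagnetic = rep(x$mask_superparamagnetic, times = nt),
    quiet = as.vector(x$mask_quiet)
  )
}

#' @describeIn build_feasibility_map Plot the map: log-log image of
#'   log10(NEP) with the admissible band (permeable and superparamagnetic)
#'   and the NEP-threshold contour overlaid.
#' @export
plot.feasibility_map <- function(x, ...) {
  lv <- log10(x$v_grid)
  lt <- log10(x$tau_grid)
  image(lt, lv, t(log10(x$nep_grid)),
        xlab = expression(log[10] ~ tau ~ "(s)"),
        ylab = expression(log[10] ~ V ~ (cm^3)),
        main = "NEP (log10 G^2/Hz) with admissible band and threshold", ...)
  admissible <- x$mask_permeability & x$mask_superparamagnetic
  if (any(admissible)) {
    rng <- range(lv[admissible])
    lines(range(lt), rep(rng[1], 2), lty = 2)
    lines(range(lt), rep(rng[2], 2), lty = 2)
  }
  # threshold contour: tau(V) at which NEP equals the threshold
  p <- x$params
  tau_crit <- p$nep_threshold * p$ms^2 * x$v_grid^2 /
    (2 * p$eta * (.kB * p$temperature)^2)
  ok <- tau_crit >= min(x$tau_grid) & tau_crit <= max(x$tau_grid)
  if (any(ok)) lines(log10(tau_crit[ok]), lv[ok], col = "red", lwd = 2)
  box()
  invisible(x)
}
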