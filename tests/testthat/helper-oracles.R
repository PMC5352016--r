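# Independent numerical oracles used across tests.

# Kramers-Kronig: reconstruct the real part of a causal susceptibility from
# its imaginary part by principal-value quadrature,
#   alpha'(w) = (2/pi) P int_0^inf w' a''(w') / (w'^2 - w^2) dw'.
# The singularity is removed by subtracting the (vanishing) principal-value
# integral of the constant w a''(w), leaving a smooth integrand evaluated by
# trapezoid on a wide log grid.  Uses only pointwise values of a''.
kk_real_from_imag <- function(alpha_imag_fun, omega, n = 24001) {
  grid <- 10^seq(log10(omega) - 6, log10(omega) + 6, length.out = n)
  f <- grid * alpha_imag_fun(grid)
  fw <- omega * alpha_imag_fun(omega)
  integrand <- (f - fw) / (grid^2 - omega^2)
  (2 / pi) * sum(diff(grid) * (head(integrand, -1) + tail(integrand, -1)) / 2)
}

# mean Welch density over bins with omega in (lo, hi]
psd_band_mean <- function(spec, lo, hi) {
  sel <- spec$omega > lo & spec$omega <= hi
  stopifnot(any(sel))
  mean(spec$density[sel])
}

# reference particle used by most simulation tests: a boundary-volume
# magnetite-like crystal at physiological temperature with tau = 1 ns
test_mu <- 5e-14            # emu  (500 G x 1e-16 cm^3)
test_tau <- 1e-9            # s
test_temp <- 310            # K
test_kbt <- mag_constants()$kb_erg_per_k * test_temp
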