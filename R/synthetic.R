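# Synthetic instrument traces with the statistical structure each analysis
# stage assumes: forward models of the fitted decays/peaks plus the noise the
# real instruments produce. Every generator seeds a local RNG stream and
# restores global RNG state on exit, so outputs are reproducible and calls
# never leak state.

with_local_seed <- function(seed, code) {
  if (!is.finite(seed)) stop_invalid("seed must be a finite integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a DLS correlogram
#'
#' Forward model of the single-exponential intensity autocorrelation
#' \eqn{g_2 - 1 = A e^{-2\Gamma\tau}} with \eqn{\Gamma = D q^2}, sampled on
#' a logarithmic delay grid spanning \eqn{0.01/\Gamma} to \eqn{10/\Gamma},
#' with multiplicative Gaussian noise of relative standard deviation
#' `noise_sd`.
#'
#' @param D translational diffusion constant (m^2/s).
#' @param q scattering wave vector (1/m).
#' @param amplitude intercept A (dimensionless, default 0.9).
#' @param noise_sd relative noise level (default 0.01; 0 for exact model).
#' @param n_points number of delays (>= 20, default 200).
#' @param temperature_C sample temperature recorded on the trace.
#' @param seed RNG seed.
#' @return A [correlogram()].
#' @export
gen_correlogram <- function(D, q, amplitude = 0.9, noise_sd = 0.01,
                            n_points = 200, temperature_C = 35, seed = 1) {
  if (D <= 0 || q <= 0 || amplitude <= 0 || noise_sd < 0)
    stop_invalid("D, q, amplitude must be positive and noise_sd >= 0")
  if (n_points < 20) stop_invalid("need n_points >= 20")
  gamma <- D * q^2
  tau <- exp(seq(log(0.01 / gamma), log(10 / gamma), length.out = n_points))
  y <- amplitude * exp(-2 * gamma * tau)
  if (noise_sd > 0)
    y <- with_local_seed(seed, y * (1 + stats::rnorm(n_points, 0, noise_sd)))
  correlogram(tau, y, q, temperature_C,
              label = sprintf("synthetic D=%.3g", D))
}

#' Simulate a 1D SAXS profile
#'
#' Power-law background \eqn{c\,q^{-p}} plus, for multilamellar samples, a
#' pair of Gaussian Bragg peaks at \eqn{q^* = 2\pi/d} and \eqn{2q^*} with the
#' second order at 0.4 times the first-order weight (configurable). Noise is
#' Gaussian with standard deviation `noise_fraction * sqrt(I)` scaled to the
#' local intensity, emulating counting statistics after reduction.
#'
#' @param d_spacing_nm lamellar repeat distance (nm).
#' @param lamellar_weight peak weight relative to the background at q*
#'   (0 for a unilamellar, peak-free profile).
#' @param powerlaw_exponent background exponent p in \eqn{q^{-p}} (default 2.5).
#' @param noise_fraction noise scale (default 0.02; 0 for exact model).
#' @param q_grid wave-vector grid (1/nm), default 300 points on \[0.2, 3\].
#' @param peak_width_invnm Gaussian peak sigma (default 0.03).
#' @param second_order_ratio second- to first-order peak weight (default 0.4).
#' @param scale overall intensity scale c (default 100).
#' @param temperature_C recorded temperature.
#' @param seed RNG seed.
#' @return A [saxs_profile()].
#' @export
gen_saxs_profile <- function(d_spacing_nm, lamellar_weight = 1,
                             powerlaw_exponent = 2.5, noise_fraction = 0.02,
                             q_grid = seq(0.2, 3, length.out = 300),
                             peak_width_invnm = 0.03, second_order_ratio = 0.4,
                             scale = 100, temperature_C = 25, seed = 1) {
  if (d_spacing_nm <= 0) stop_invalid("d_spacing must be positive")
  q1 <- 2 * pi / d_spacing_nm
  bg <- scale * q_grid^(-powerlaw_exponent)
  gauss <- function(q0) exp(-(q_grid - q0)^2 / (2 * peak_width_invnm^2))
  bg_at_q1 <- scale * q1^(-powerlaw_exponent)
  I <- bg + lamellar_weight * bg_at_q1 *
    (gauss(q1) + second_order_ratio * gauss(2 * q1))
  if (noise_fraction > 0) {
    I <- with_local_seed(seed, {
      out <- I + stats::rnorm(length(I), 0, noise_fraction * sqrt(I))
      pmax(out, 1e-6 * min(I))
    })
  }
  saxs_profile(q_grid, I, temperature_C = temperature_C,
               label = sprintf("synthetic d=%.3g nm", d_spacing_nm))
}

#' Simulate a DSC cooling/heating trace
#'
#' Gaussian exotherm centred at `T_c_C` whose integrated area equals
#' `enthalpy_J_per_g * beta` (beta the scan rate in C/s, so that
#' [integrate_enthalpy()] recovers the enthalpy), superposed on a linear
#' instrumental baseline `a + b*T` with additive Gaussian noise.
#'
#' @param T_c_C transition temperature (Celsius).
#' @param fwhm_C full width at half maximum of the exotherm (C).
#' @param enthalpy_J_per_g specific transition enthalpy (J per g of sample).
#' @param scan_rate_C_per_min scan rate (default 2).
#' @param baseline numeric length-2 `c(a, b)` of the linear baseline (W/g
#'   and W/g/C).
#' @param noise_sd additive heat-flow noise (W/g).
#' @param T_range scan span in Celsius (default 5 to 40).
#' @param n_points samples along the ramp (default 701).
#' @param direction `"cooling"` (default) or `"heating"`.
#' @param seed RNG seed.
#' @return A [dsc_trace()] (exotherm-positive convention).
#' @export
gen_dsc_trace <- function(T_c_C = 22.84, fwhm_C = 1.2, enthalpy_J_per_g = 0.335,
                          scan_rate_C_per_min = 2, baseline = c(0, 0),
                          noise_sd = 0, T_range = c(5, 40), n_points = 701,
                          direction = "cooling", seed = 1) {
  if (enthalpy_J_per_g < 0) stop_invalid("enthalpy must be >= 0")
  if (fwhm_C <= 0) stop_invalid("fwhm must be positive")
  Tm <- seq(T_range[1], T_range[2], length.out = n_points)
  if (identical(direction, "cooling")) Tm <- rev(Tm)
  beta <- scan_rate_C_per_min / 60
  sigma <- fwhm_C / (2 * sqrt(2 * log(2)))
  # Gaussian of unit area in temperature, scaled to area = enthalpy * beta
  peak <- enthalpy_J_per_g * beta *
    exp(-(Tm - T_c_C)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  hf <- peak + baseline[1] + baseline[2] * Tm
  if (noise_sd > 0)
    hf <- with_local_seed(seed, hf + stats::rnorm(n_points, 0, noise_sd))
  dsc_trace(Tm, hf, scan_rate_C_per_min, direction = direction,
            label = sprintf("synthetic Tc=%.2f", T_c_C))
}

#' Simulate a temperature-ramped viscosity curve
#'
#' \eqn{\eta(T) = \eta_{solv}(T)\,\eta_{r,base}\,[1 + J\,L((T - T_m)/s)]}
#' with \eqn{L} the logistic function and scale \eqn{s = w/(2\ln 9)} chosen
#' so that `width_C` is exactly the 10-90% rise span of the step, matching
#' the width definition used by [thickening_metrics()]. Multiplicative
#' Gaussian noise of relative sd `noise_sd`.
#'
#' @param eta_r_base baseline relative viscosity over the solvent (>= 1 for
#'   a suspension; 1 gives a bare solvent curve when `jump_fraction = 0`).
#' @param jump_fraction fractional viscosity step at the transition (e.g.
#'   0.8 for an 80% jump).
#' @param T_m_C transition midpoint (Celsius).
#' @param width_C 10-90% rise span of the step (C).
#' @param T_range scan span (default 5 to 40 C).
#' @param n_points samples (default 351).
#' @param shear_rate_per_s recorded shear rate (default 30).
#' @param noise_sd relative noise (default 0).
#' @param solvent_model function T_C -> viscosity (Pa*s); default
#'   [water_viscosity()].
#' @param seed RNG seed.
#' @return A [viscosity_curve()] in mPa*s.
#' @export
gen_viscosity_curve <- function(eta_r_base = 1.2, jump_fraction = 0.1,
                                T_m_C = 23.5, width_C = 2,
                                T_range = c(5, 40), n_points = 351,
                                shear_rate_per_s = 30, noise_sd = 0,
                                solvent_model = water_viscosity, seed = 1) {
  if (width_C <= 0) stop_invalid("width must be positive")
  Tm <- seq(T_range[1], T_range[2], length.out = n_points)
  s <- width_C / (2 * log(9))
  step <- 1 / (1 + exp(-(Tm - T_m_C) / s))
  eta <- solvent_model(Tm) * 1e3 * eta_r_base * (1 + jump_fraction * step)
  if (noise_sd > 0)
    eta <- with_local_seed(seed, eta * (1 + stats::rnorm(n_points, 0, noise_sd)))
  viscosity_curve(Tm, eta, shear_rate_per_s,
                  label = sprintf("synthetic jump=%.2f", jump_fraction))
}

#' Simulate a TCSPC decay histogram
#'
#' Expected per-bin counts from a multi-exponential decay (optionally
#' convolved with a Gaussian instrument response of given FWHM), normalized
#' to `total_counts` and sampled with independent Poisson counting noise.
#'
#' @param amplitudes component amplitude fractions (will be normalized).
#' @param lifetimes_ns component lifetimes (ns).
#' @param total_counts expected total photon count (>= 1000).
#' @param bin_width_ns histogram bin width (default 0.1 ns).
#' @param n_bins number of bins (default 1000).
#' @param irf_fwhm_ns Gaussian IRF FWHM in ns, or `NULL` for an ideal
#'   instrument.
#' @param background_fraction fraction of counts in a flat background
#'   (default 0).
#' @param temperature_C recorded temperature.
#' @param seed RNG seed; `NULL` for the noise-free expectation rounded to
#'   integers is not offered -- use a large `total_counts` instead.
#' @return A [decay_histogram()].
#' @export
gen_decay_histogram <- function(amplitudes, lifetimes_ns, total_counts = 1e6,
                                bin_width_ns = 0.1, n_bins = 1000,
                                irf_fwhm_ns = NULL, background_fraction = 0,
                                temperature_C = 35, seed = 1) {
  if (total_counts < 1000) stop_invalid("need total_counts >= 1000")
  if (length(amplitudes) != length(lifetimes_ns))
    stop_invalid("amplitudes and lifetimes must have equal length")
  t <- (seq_len(n_bins) - 0.5) * bin_width_ns
  a <- amplitudes / sum(amplitudes)
  y <- rowSums(vapply(seq_along(a),
                      function(j) a[j] * exp(-t / lifetimes_ns[j]),
                      numeric(n_bins)))
  if (!is.null(irf_fwhm_ns)) {
    s <- irf_fwhm_ns / (2 * sqrt(2 * log(2)))
    k <- exp(-(t - 5 * s)^2 / (2 * s^2)); k <- k / sum(k)
    y <- stats::convolve(y, rev(k), type = "open")[seq_len(n_bins)]
  }
  expected <- y / sum(y) * total_counts * (1 - background_fraction) +
    total_counts * background_fraction / n_bins
  counts <- with_local_seed(seed, stats::rpois(n_bins, expected))
  irf_counts <- if (!is.null(irf_fwhm_ns)) round(k / max(k) * 1e4) else NULL
  decay_histogram(t, counts, irf_counts = irf_counts,
                  temperature_C = temperature_C,
                  label = sprintf("synthetic tau=(%s)",
                                  paste(signif(lifetimes_ns, 4), collapse = ",")))
}
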