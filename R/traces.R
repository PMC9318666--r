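#' @title Instrument trace containers
#' @name traces
#' @description Light-weight validated containers for the five kinds of raw
#'   trace the package analyses: DLS correlograms, 1D SAXS profiles, DSC
#'   thermograms, temperature-ramped viscosity curves and TCSPC decay
#'   histograms. Each constructor checks the physical invariants of its data
#'   (monotone abscissae, positive rates, integer counts, ...) and returns a
#'   classed list so downstream fitters can dispatch and validate cheaply.
#'
#'   Unit conventions at the user interface: temperatures in degrees Celsius,
#'   DLS delay times in seconds and wave vectors in 1/m, SAXS wave vectors in
#'   1/nm, heat flow in W/g, viscosities in mPa*s (= cP), TCSPC times in ns.
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("vesiscope_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' DLS correlogram trace
#'
#' Holds a baseline-subtracted intensity autocorrelation function
#' \eqn{g_2(q,\tau) - 1} sampled at strictly increasing delay times, together
#' with the scattering wave vector and sample temperature needed to turn a
#' relaxation rate into a diffusion constant and hydrodynamic size.
#'
#' @param delay_s strictly increasing positive delay times (seconds).
#' @param g2_minus_1 normalized autocorrelation amplitude (dimensionless,
#'   baseline already subtracted); same length as `delay_s`.
#' @param q scattering wave vector (1/m); see [compute_wave_vector()].
#' @param temperature_C sample temperature (degrees Celsius).
#' @param label free-text sample label.
#' @return An object of class `"correlogram"`.
#' @seealso [fit_correlogram()], [gen_correlogram()]
#' @export
correlogram <- function(delay_s, g2_minus_1, q, temperature_C, label = "") {
  delay_s <- as.numeric(delay_s); g2_minus_1 <- as.numeric(g2_minus_1)
  if (length(delay_s) != length(g2_minus_1))
    stop_invalid("delay_s and g2_minus_1 must have equal length")
  if (any(!is.finite(delay_s)) || any(delay_s <= 0) || any(diff(delay_s) <= 0))
    stop_invalid("delay_s must be finite, positive and strictly increasing")
  if (any(!is.finite(g2_minus_1)))
    stop_invalid("g2_minus_1 must be finite")
  if (!is.finite(q) || q <= 0) stop_invalid("q must be a positive scalar (1/m)")
  if (!is.finite(temperature_C) || temperature_C <= -273.15)
    stop_invalid("temperature_C must be above absolute zero")
  structure(list(delay_s = delay_s, g2_minus_1 = g2_minus_1, q = q,
                 temperature_C = temperature_C, label = as.character(label)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("DLS correlogram%s: %d delays [%.3g, %.3g] s, q = %.4g 1/m, T = %.2f C\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$delay_s), min(x$delay_s), max(x$delay_s),
              x$q, x$temperature_C))
  invisible(x)
}

#' 1D SAXS profile
#'
#' Scattered intensity versus wave vector after vendor reduction and
#' background subtraction. Temperature is carried as metadata only.
#'
#' @param q_invnm strictly increasing wave vector grid (1/nm).
#' @param intensity scattered intensity (arbitrary units).
#' @param sigma optional intensity uncertainties (same length).
#' @param temperature_C sample temperature (Celsius); metadata.
#' @param label free-text sample label.
#' @return An object of class `"saxs_profile"`.
#' @seealso [detect_lamellar_peaks()], [gen_saxs_profile()]
#' @export
saxs_profile <- function(q_invnm, intensity, sigma = NULL,
                         temperature_C = NA_real_, label = "") {
  q_invnm <- as.numeric(q_invnm); intensity <- as.numeric(intensity)
  if (length(q_invnm) != length(intensity))
    stop_invalid("q_invnm and intensity must have equal length")
  if (any(!is.finite(q_invnm)) || any(diff(q_invnm) <= 0))
    stop_invalid("q_invnm must be finite and strictly increasing")
  if (any(!is.finite(intensity))) stop_invalid("intensity must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q_invnm) || any(!is.finite(sigma)) || any(sigma < 0))
      stop_invalid("sigma must be finite, non-negative, same length as q")
  }
  structure(list(q_invnm = q_invnm, intensity = intensity, sigma = sigma,
                 temperature_C = temperature_C, label = as.character(label)),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile%s: %d points, q in [%.3g, %.3g] 1/nm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q_invnm), min(x$q_invnm), max(x$q_invnm)))
  invisible(x)
}

#' DSC thermogram
#'
#' Specific heat flow versus temperature on a single cooling or heating ramp.
#' The stored sign convention is "exotherm positive": readers flip the sign
#' when the vendor exports exotherms as negative (see [read_dsc_csv()]).
#'
#' @param temperature_C temperatures (Celsius), monotone along the scan
#'   direction (decreasing for `direction = "cooling"`).
#' @param heat_flow_W_per_g specific heat flow (W/g), exotherm positive.
#' @param scan_rate_C_per_min scan rate magnitude (degrees C per minute).
#' @param direction `"cooling"` or `"heating"`.
#' @param label free-text sample label.
#' @return An object of class `"dsc_trace"`.
#' @seealso [detect_transition()], [integrate_enthalpy()], [gen_dsc_trace()]
#' @export
dsc_trace <- function(temperature_C, heat_flow_W_per_g, scan_rate_C_per_min,
                      direction = c("cooling", "heating"), label = "") {
  direction <- match.arg(direction)
  temperature_C <- as.numeric(temperature_C)
  heat_flow_W_per_g <- as.numeric(heat_flow_W_per_g)
  if (length(temperature_C) != length(heat_flow_W_per_g))
    stop_invalid("temperature and heat flow must have equal length")
  if (any(!is.finite(temperature_C)) || any(!is.finite(heat_flow_W_per_g)))
    stop_invalid("temperature and heat flow must be finite")
  d <- diff(temperature_C)
  ok <- if (direction == "cooling") all(d < 0) else all(d > 0)
  if (!ok) stop_invalid("temperature must be strictly monotone along the scan direction")
  if (!is.finite(scan_rate_C_per_min) || scan_rate_C_per_min <= 0)
    stop_invalid("scan_rate_C_per_min must be positive")
  structure(list(temperature_C = temperature_C,
                 heat_flow_W_per_g = heat_flow_W_per_g,
                 scan_rate_C_per_min = scan_rate_C_per_min,
                 direction = direction, label = as.character(label)),
            class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("DSC trace%s: %s at %.3g C/min, %d points, T in [%.2f, %.2f] C\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$direction, x$scan_rate_C_per_min, length(x$temperature_C),
              min(x$temperature_C), max(x$temperature_C)))
  invisible(x)
}

#' Temperature-ramped viscosity curve
#'
#' Steady-shear viscosity versus temperature at a fixed shear rate; also used
#' for dimensionless relative-viscosity curves (then `eta_mPas` holds the
#' ratio and `relative = TRUE`).
#'
#' @param temperature_C monotone increasing temperatures (Celsius).
#' @param eta_mPas positive viscosities (mPa*s) or relative viscosities.
#' @param shear_rate_per_s applied shear rate (1/s); metadata.
#' @param label free-text sample label.
#' @param relative logical; `TRUE` when the curve is a dimensionless ratio.
#' @return An object of class `"viscosity_curve"`.
#' @seealso [relative_viscosity()], [thickening_metrics()], [gen_viscosity_curve()]
#' @export
viscosity_curve <- function(temperature_C, eta_mPas, shear_rate_per_s = NA_real_,
                            label = "", relative = FALSE) {
  temperature_C <- as.numeric(temperature_C); eta_mPas <- as.numeric(eta_mPas)
  if (length(temperature_C) != length(eta_mPas))
    stop_invalid("temperature and eta must have equal length")
  if (any(!is.finite(temperature_C)) || any(diff(temperature_C) <= 0))
    stop_invalid("temperature_C must be finite and strictly increasing")
  if (any(!is.finite(eta_mPas)) || any(eta_mPas <= 0))
    stop_invalid("eta must be finite and positive")
  structure(list(temperature_C = temperature_C, eta_mPas = eta_mPas,
                 shear_rate_per_s = shear_rate_per_s, label = as.character(label),
                 relative = isTRUE(relative)),
            class = "viscosity_curve")
}

#' @export
print.viscosity_curve <- function(x, ...) {
  cat(sprintf("%s curve%s: %d points, T in [%.2f, %.2f] C\n",
              if (x$relative) "Relative viscosity" else "Viscosity",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$temperature_C), min(x$temperature_C), max(x$temperature_C)))
  invisible(x)
}

#' TCSPC decay histogram
#'
#' Photon counts versus time after the excitation pulse, on a uniform time
#' grid, with an optional instrument response function on the same grid.
#'
#' @param time_ns uniformly spaced bin centres (ns).
#' @param counts non-negative integer photon counts per bin.
#' @param irf_counts optional instrument response histogram (same binning).
#' @param temperature_C sample temperature (Celsius); metadata.
#' @param label free-text sample label.
#' @return An object of class `"decay_histogram"`.
#' @seealso [fit_biexponential()], [gen_decay_histogram()]
#' @export
decay_histogram <- function(time_ns, counts, irf_counts = NULL,
                            temperature_C = NA_real_, label = "") {
  time_ns <- as.numeric(time_ns); counts <- as.numeric(counts)
  if (length(time_ns) != length(counts))
    stop_invalid("time_ns and counts must have equal length")
  if (length(time_ns) < 2) stop_invalid("need at least 2 bins")
  dt <- diff(time_ns)
  if (any(!is.finite(time_ns)) || any(dt <= 0) ||
      max(dt) - min(dt) > 1e-6 * mean(dt))
    stop_invalid("time_ns must be uniform and increasing")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop_invalid("counts must be non-negative integers")
  if (!is.null(irf_counts)) {
    irf_counts <- as.numeric(irf_counts)
    if (length(irf_counts) != length(time_ns) || any(!is.finite(irf_counts)) ||
        any(irf_counts < 0))
      stop_invalid("irf_counts must be non-negative, same length as time_ns")
  }
  structure(list(time_ns = time_ns, counts = round(counts),
                 irf_counts = irf_counts, temperature_C = temperature_C,
                 label = as.character(label), bin_width_ns = mean(dt)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay%s: %d bins of %.4g ns, %.3g total counts\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$time_ns), x$bin_width_ns, sum(x$counts)))
  invisible(x)
}
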