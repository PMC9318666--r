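# DSC stage: transition detection and exotherm integration.

# Order a trace by increasing temperature regardless of scan direction.
.dsc_by_temperature <- function(trace) {
  o <- order(trace$temperature_C)
  list(T = trace$temperature_C[o], hf = trace$heat_flow_W_per_g[o])
}

#' Detect the gel-fluid transition in a DSC trace
#'
#' Subtracts a linear baseline fitted to the outer 15% of the temperature
#' range on each side, locates the extremum of the baseline-subtracted heat
#' flow, and measures its full width at half maximum by linear interpolation
#' of the half-height crossings. A peak smaller than `snr` times the
#' baseline-region residual noise is reported as no transition. The result
#' is invariant to adding any linear function of temperature (absorbed by
#' the baseline) and to reversing the point order together with the
#' direction metadata.
#'
#' @param trace a [dsc_trace()] with at least 50 points spanning the peak.
#' @param snr detection threshold in units of baseline noise (default 5).
#' @return A list of class `"dsc_transition"`: `found`, `T_c_C`, `fwhm_C`,
#'   `peak_height_W_per_g`.
#' @seealso [integrate_enthalpy()], [gen_dsc_trace()]
#' @export
detect_transition <- function(trace, snr = 5) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (length(trace$temperature_C) < 50)
    stop_invalid("need at least 50 points")
  d <- .dsc_by_temperature(trace)
  n <- length(d$T)
  edge <- d$T <= stats::quantile(d$T, 0.15) | d$T >= stats::quantile(d$T, 0.85)
  bl_fit <- stats::lm(d$hf[edge] ~ d$T[edge])
  baseline <- stats::coef(bl_fit)[1] + stats::coef(bl_fit)[2] * d$T
  y <- d$hf - baseline
  noise <- stats::sd(stats::resid(bl_fit))

  ipk <- which.max(y)           # exotherm stored positive
  height <- y[ipk]
  if (!is.finite(height) || height <= max(snr * noise, 1e-12)) {
    return(structure(list(found = FALSE, T_c_C = NA_real_, fwhm_C = NA_real_,
                          peak_height_W_per_g = NA_real_),
                     class = "dsc_transition"))
  }
  half <- height / 2
  # interpolated half-height crossings on each side of the peak
  left <- NA_real_; right <- NA_real_
  for (i in seq(ipk, 2)) if (y[i - 1] < half && y[i] >= half) {
    left <- d$T[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (d$T[i] - d$T[i - 1])
    break
  }
  for (i in seq(ipk, n - 1)) if (y[i] >= half && y[i + 1] < half) {
    right <- d$T[i] + (y[i] - half) / (y[i] - y[i + 1]) * (d$T[i + 1] - d$T[i])
    break
  }
  fwhm <- right - left
  structure(list(found = TRUE, T_c_C = d$T[ipk],
                 fwhm_C = if (is.finite(fwhm) && fwhm > 0) fwhm else NA_real_,
                 peak_height_W_per_g = height),
            class = "dsc_transition")
}

#' @export
print.dsc_transition <- function(x, ...) {
  if (!x$found) cat("DSC: no transition above the noise threshold\n")
  else cat(sprintf("DSC transition: T_c = %.2f C, FWHM = %.2f C, height = %.3g W/g\n",
                   x$T_c_C, x$fwhm_C, x$peak_height_W_per_g))
  invisible(x)
}

#' Integrate a DSC exotherm to a specific enthalpy
#'
#' \eqn{\Delta H = \int |\Phi - \Phi_{baseline}|\, dT / \beta} with
#' \eqn{\Phi} the specific heat flow (W/g) and \eqn{\beta} the scan rate in
#' degrees C per second, so the result is in J per gram of sample. The
#' baseline is the straight line between the window endpoints (trapezoidal
#' quadrature). When no window is given it defaults to
#' \eqn{T_c \pm 4\,\mathrm{FWHM}} from [detect_transition()], clipped to the
#' data range. If the local baseline slopes at the two window edges disagree
#' strongly the window probably clips the peak; a warning flag is set.
#'
#' @param trace a [dsc_trace()].
#' @param window numeric length-2 integration window in degrees C, or `NULL`
#'   for the automatic window.
#' @return A list of class `"dsc_enthalpy"`: `enthalpy_J_per_g`, `window_C`,
#'   `baseline` description, `edge_warning`.
#' @export
integrate_enthalpy <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "dsc_trace"))
  d <- .dsc_by_temperature(trace)
  if (is.null(window)) {
    tr <- detect_transition(trace)
    if (!tr$found) {
      return(structure(list(enthalpy_J_per_g = 0, window_C = range(d$T),
                            baseline = "linear-endpoints", edge_warning = FALSE),
                       class = "dsc_enthalpy"))
    }
    w <- if (is.finite(tr$fwhm_C)) 4 * tr$fwhm_C else diff(range(d$T)) / 4
    window <- c(max(min(d$T), tr$T_c_C - w), min(max(d$T), tr$T_c_C + w))
  }
  sel <- d$T >= window[1] & d$T <= window[2]
  if (sum(sel) < 5) stop_invalid("integration window contains too few points")
  Tw <- d$T[sel]; hf <- d$hf[sel]
  n <- length(Tw)
  # linear baseline between the window endpoints, each anchor averaged over
  # the outer 5% of the window so endpoint noise does not tilt the baseline;
  # signed trapezoid then magnitude, so noise does not rectify into a bias
  k <- max(3, ceiling(0.05 * n))
  i1 <- 1:k; i2 <- (n - k + 1):n
  T1 <- mean(Tw[i1]); h1 <- mean(hf[i1])
  T2 <- mean(Tw[i2]); h2 <- mean(hf[i2])
  base <- h1 + (h2 - h1) * (Tw - T1) / (T2 - T1)
  y <- hf - base
  area <- abs(sum(diff(Tw) * (y[-1] + y[-n]) / 2))     # W/g * C
  beta <- trace$scan_rate_C_per_min / 60               # C/s
  # crude edge check: local slopes over the outer 10% of the window
  k <- max(3, ceiling(0.1 * n))
  s1 <- stats::coef(stats::lm(hf[1:k] ~ Tw[1:k]))[2]
  s2 <- stats::coef(stats::lm(hf[(n - k + 1):n] ~ Tw[(n - k + 1):n]))[2]
  scale <- max(abs(hf)) / max(diff(range(Tw)), 1e-9)
  edge_warning <- is.finite(s1) && is.finite(s2) &&
    abs(s1 - s2) > 0.5 * max(scale, 1e-12)
  structure(list(enthalpy_J_per_g = area / beta, window_C = window,
                 baseline = "linear-endpoints", edge_warning = edge_warning),
            class = "dsc_enthalpy")
}

#' @export
print.dsc_enthalpy <- function(x, ...) {
  cat(sprintf("DSC enthalpy: %.4g J/g over [%.2f, %.2f] C (%s baseline)%s\n",
              x$enthalpy_J_per_g, x$window_C[1], x$window_C[2], x$baseline,
              if (x$edge_warning) " [window may clip the peak]" else ""))
  invisible(x)
}

#' Relative decrease of a transition enthalpy
#'
#' Percent decrease of the specific enthalpy of a mixed (e.g.
#' polymer-containing) sample relative to the neat sample:
#' \eqn{100 (\Delta H_{neat} - \Delta H_{mix}) / \Delta H_{neat}}.
#'
#' @param neat_J_per_g neat-sample enthalpy (> 0).
#' @param mixed_J_per_g mixed-sample enthalpy.
#' @return Percent decrease (negative when the mixed enthalpy is larger).
#' @examples
#' relative_enthalpy_change(0.335, 0.234)  # ~30.1 %
#' @export
relative_enthalpy_change <- function(neat_J_per_g, mixed_J_per_g) {
  if (!is.finite(neat_J_per_g) || neat_J_per_g <= 0)
    stop_invalid("neat enthalpy must be positive")
  100 * (neat_J_per_g - mixed_J_per_g) / neat_J_per_g
}
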