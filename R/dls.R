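# DLS stage: single-exponential correlogram fits, Stokes-Einstein sizing,
# adsorbed-layer thickness and its molecular-weight scaling.

#' Fit a single-exponential decay to a DLS correlogram
#'
#' Fits \eqn{g_2(\tau) - 1 = A e^{-2\Gamma\tau}} by nonlinear least squares
#' (Levenberg-Marquardt) and derives the translational diffusion constant
#' \eqn{D_T = \Gamma / q^2} and the hydrodynamic radius through the
#' Stokes-Einstein relation at the trace temperature. The decay rate
#' \eqn{\Gamma} of a physical correlogram is positive by convention.
#'
#' Initialization: \eqn{A_0} is the first correlogram value and
#' \eqn{\Gamma_0} comes from the delay at which the amplitude has fallen to
#' \eqn{A_0/e}. Convergence tolerance 1e-10 on the sum of squares, at most
#' 1000 iterations. A trace that does not decay (or yields a negative rate)
#' is flagged `converged = FALSE` rather than erroring.
#'
#' @param trace a [correlogram()] with at least 8 delay points.
#' @param viscosity_Pas solvent viscosity used for sizing; defaults to pure
#'   water at the trace temperature.
#' @return An object of class `"dls_fit"`: amplitude `A`, relaxation rate
#'   `gamma` (1/s), `D_T` (m^2/s), hydrodynamic radius `R_h` and diameter
#'   `diameter_nm`, `residual_ss`, `converged`, plus the trace.
#' @seealso [gen_correlogram()] for the matching forward model.
#' @examples
#' tr <- gen_correlogram(D = 5.2e-12, q = 2.635e7, amplitude = 0.9,
#'                       noise_sd = 0.01, n_points = 150, seed = 1)
#' fit <- fit_correlogram(tr)
#' coef(fit)
#' @export
fit_correlogram <- function(trace,
                            viscosity_Pas = water_viscosity(trace$temperature_C)) {
  stopifnot(inherits(trace, "correlogram"))
  if (length(trace$delay_s) < 8) stop_invalid("need at least 8 delay points")
  tau <- trace$delay_s; y <- trace$g2_minus_1

  failed <- function() {
    structure(list(amplitude = NA_real_, gamma = NA_real_, D_T = NA_real_,
                   R_h = NA_real_, diameter_nm = NA_real_,
                   residual_ss = NA_real_, converged = FALSE, trace = trace,
                   viscosity_Pas = viscosity_Pas),
              class = "dls_fit")
  }

  A0 <- y[1]
  if (!is.finite(A0) || A0 <= 0 || stats::sd(y) < 1e-12 * max(abs(y), 1e-300))
    return(failed())
  # delay at which the amplitude first falls below A0/e
  idx <- which(y <= A0 / exp(1))[1]
  g0 <- if (is.na(idx)) 1 / (2 * max(tau)) else 1 / (2 * tau[idx])

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-2 * G * tau),
                      start = list(A = A0, G = g0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co[["G"]] <= 0 || co[["A"]] <= 0) return(failed())

  D_T <- co[["G"]] / trace$q^2
  R_h <- stokes_einstein(D_T, trace$temperature_C, viscosity_Pas,
                         direction = "D_to_R")
  structure(list(amplitude = co[["A"]], gamma = co[["G"]], D_T = D_T,
                 R_h = R_h, diameter_nm = 2 * R_h * 1e9,
                 residual_ss = sum(stats::resid(fit)^2), converged = TRUE,
                 trace = trace, viscosity_Pas = viscosity_Pas),
            class = "dls_fit")
}

#' @export
print.dls_fit <- function(x, ...) {
  if (!x$converged) {
    cat("DLS fit: did not converge (non-decaying or degenerate trace)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("DLS single-exponential fit%s\n",
                     "  A        = %.4g\n  Gamma    = %.6g 1/s\n",
                     "  D_T      = %.6g m^2/s\n  diameter = %.4g nm\n"),
              if (nzchar(x$trace$label)) paste0(" '", x$trace$label, "'") else "",
              x$amplitude, x$gamma, x$D_T, x$diameter_nm))
  invisible(x)
}

#' @export
coef.dls_fit <- function(object, ...) {
  c(amplitude = object$amplitude, gamma = object$gamma,
    D_T = object$D_T, R_h = object$R_h)
}

#' @export
predict.dls_fit <- function(object, delay_s = object$trace$delay_s, ...) {
  if (!object$converged) stop_invalid("cannot predict from a failed fit")
  object$amplitude * exp(-2 * object$gamma * delay_s)
}

#' @export
residuals.dls_fit <- function(object, ...) {
  object$trace$g2_minus_1 - predict(object)
}

#' @export
summary.dls_fit <- function(object, ...) {
  print(object)
  if (object$converged)
    cat(sprintf("  residual SS = %.3g over %d points; solvent eta = %.4g Pa.s\n",
                object$residual_ss, length(object$trace$delay_s),
                object$viscosity_Pas))
  invisible(object)
}

#' Adsorbed-polymer layer thickness from hydrodynamic diameters
#'
#' Half the diameter increase of a vesicle upon polymer adsorption:
#' \eqn{\delta = (d_{mix} - d_{neat})/2}. Negative values (apparent
#' shrinkage) are returned as-is with a warning attribute, never clamped.
#'
#' @param diameter_with_polymer_nm hydrodynamic diameter in the polymer
#'   solution (nm).
#' @param diameter_neat_nm reference diameter of the bare vesicle (nm).
#' @return Layer thickness in nm (may be negative).
#' @examples
#' bound_layer_thickness(157.7, 119.9)  # 18.9 nm
#' @export
bound_layer_thickness <- function(diameter_with_polymer_nm, diameter_neat_nm) {
  if (any(!is.finite(diameter_with_polymer_nm)) ||
      any(diameter_with_polymer_nm <= 0) ||
      !is.finite(diameter_neat_nm) || diameter_neat_nm <= 0)
    stop_invalid("diameters must be positive")
  delta <- (diameter_with_polymer_nm - diameter_neat_nm) / 2
  attr(delta, "negative") <- delta < 0
  delta
}

#' Molecular-weight scaling of the adsorbed layer
#'
#' Ordinary least squares of \eqn{\log_{10}\delta} on \eqn{\log_{10} M_w}.
#' For an adsorbed flexible coil the slope is the Flory-type size exponent:
#' ~0.5 for theta and ~0.59 for good-solvent statistics. Pairs with
#' \eqn{\delta \le 0} carry no size information and are excluded (and
#' reported). The slope is invariant to the logarithm base since both axes
#' are transformed alike.
#'
#' @param molar_mass_g_mol polymer molar masses (g/mol), length >= 2.
#' @param delta_nm adsorbed-layer thicknesses (nm), same length.
#' @return Object of class `"layer_scaling"`: `slope`, `log_prefactor`
#'   (base-10 intercept, i.e. delta = 10^log_prefactor * Mw^slope with delta
#'   in nm), `excluded` (indices dropped), plus the retained data.
#' @examples
#' fit_layer_scaling(c(1.5e3, 2e4, 1e5, 4e5), c(0.75, 4.85, 7.9, 18.9))
#' @export
fit_layer_scaling <- function(molar_mass_g_mol, delta_nm) {
  if (length(molar_mass_g_mol) != length(delta_nm))
    stop_invalid("molar mass and delta vectors must have equal length")
  if (any(!is.finite(molar_mass_g_mol)) || any(molar_mass_g_mol <= 0))
    stop_invalid("molar masses must be positive")
  excluded <- which(!is.finite(delta_nm) | delta_nm <= 0)
  keep <- setdiff(seq_along(delta_nm), excluded)
  if (length(keep) < 2)
    stop_invalid("need at least 2 pairs with positive delta")
  x <- log10(molar_mass_g_mol[keep]); y <- log10(delta_nm[keep])
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 log_prefactor = unname(stats::coef(fit)[1]),
                 excluded = excluded,
                 molar_mass_g_mol = molar_mass_g_mol[keep],
                 delta_nm = delta_nm[keep], lm = fit),
            class = "layer_scaling")
}

#' @export
print.layer_scaling <- function(x, ...) {
  cat(sprintf("Adsorbed-layer scaling: delta ~ Mw^%.3f (log10 prefactor %.3f, %d points%s)\n",
              x$slope, x$log_prefactor, length(x$delta_nm),
              if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

#' @export
coef.layer_scaling <- function(object, ...) {
  c(slope = object$slope, log_prefactor = object$log_prefactor)
}

#' @export
predict.layer_scaling <- function(object, molar_mass_g_mol = object$molar_mass_g_mol, ...) {
  10^object$log_prefactor * molar_mass_g_mol^object$slope
}
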