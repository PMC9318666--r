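# Rheology stage: relative viscosity, hard-sphere suspension models,
# vesicle geometry -> volume fraction, interparticle distances and
# thermal-thickening metrics.

N_AVOGADRO <- 6.02214076e23

#' Relative viscosity of a sample curve over a reference curve
#'
#' Pointwise ratio \eqn{\eta_r(T) = \eta_{sample}(T)/\eta_{ref}(T)} after
#' linear interpolation of the reference onto the sample temperatures.
#' Sample points outside the reference range are dropped.
#'
#' @param sample,reference [viscosity_curve()] objects with overlapping
#'   temperature ranges.
#' @return A dimensionless [viscosity_curve()] (`relative = TRUE`).
#' @export
relative_viscosity <- function(sample, reference) {
  stopifnot(inherits(sample, "viscosity_curve"),
            inherits(reference, "viscosity_curve"))
  lo <- max(min(sample$temperature_C), min(reference$temperature_C))
  hi <- min(max(sample$temperature_C), max(reference$temperature_C))
  if (lo >= hi) stop_invalid("sample and reference temperature ranges do not overlap")
  sel <- sample$temperature_C >= lo & sample$temperature_C <= hi
  Ts <- sample$temperature_C[sel]
  ref <- stats::approx(reference$temperature_C, reference$eta_mPas, xout = Ts)$y
  viscosity_curve(Ts, sample$eta_mPas[sel] / ref,
                  shear_rate_per_s = sample$shear_rate_per_s,
                  label = paste0(sample$label, " / ", reference$label),
                  relative = TRUE)
}

#' Einstein dilute hard-sphere viscosity
#'
#' \eqn{\eta_r = 1 + 2.5\,\phi}: the dilute limit for rigid non-interacting
#' spheres.
#'
#' @param phi particle volume fraction in \[0, 1).
#' @return Relative viscosity (dimensionless).
#' @examples
#' einstein_model(0.092)  # 1.23
#' @export
einstein_model <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi >= 1))
    stop_invalid("phi must lie in [0, 1)")
  1 + 2.5 * phi
}

#' Krieger-Dougherty concentrated hard-sphere viscosity
#'
#' \eqn{\eta_r = (1 - \phi/\phi_{max})^{-A\phi_{max}}}, diverging at the
#' maximum packing fraction. The defaults A = 2.7 and phi_max = 0.71 are the
#' literature values for submicron hard spheres; the first-order expansion
#' recovers \eqn{1 + A\phi}.
#'
#' @param phi particle volume fraction, `0 <= phi < phi_max`.
#' @param A intrinsic-viscosity coefficient (default 2.7).
#' @param phi_max maximum packing fraction (default 0.71).
#' @return Relative viscosity (dimensionless).
#' @examples
#' krieger_dougherty(0.092)  # ~1.305
#' @export
krieger_dougherty <- function(phi, A = 2.7, phi_max = 0.71) {
  if (any(!is.finite(phi)) || any(phi < 0))
    stop_invalid("phi must be non-negative")
  if (any(phi >= phi_max))
    stop_invalid("phi must be below phi_max (viscosity diverges at packing)")
  (1 - phi / phi_max)^(-A * phi_max)
}

#' Vesicle shell geometry
#'
#' Container for the geometric and composition parameters from which the
#' vesicle number density and volume fraction follow. Defaults carry
#' standard fluid-phase values for a DMPC-type bilayer (bare thickness
#' 4.4 nm, area per lipid 0.60 nm^2; the gel-phase analogues are ~4.8 nm and
#' 0.47 nm^2).
#'
#' @param outer_diameter_nm outer vesicle diameter (nm), > 2x thickness.
#' @param bilayer_thickness_nm bare bilayer thickness (nm), excluding
#'   interlamellar water.
#' @param area_per_lipid_nm2 area per lipid headgroup (nm^2).
#' @param lipid_molar_mass_g_mol lipid molar mass (g/mol; 678 for DMPC).
#' @param lipid_mass_concentration_g_L nominal lipid concentration (g/L).
#' @return Object of class `"vesicle_geometry"`.
#' @export
vesicle_geometry <- function(outer_diameter_nm,
                             bilayer_thickness_nm = 4.4,
                             area_per_lipid_nm2 = 0.60,
                             lipid_molar_mass_g_mol = 678,
                             lipid_mass_concentration_g_L = 17) {
  vals <- c(outer_diameter_nm, bilayer_thickness_nm, area_per_lipid_nm2,
            lipid_molar_mass_g_mol, lipid_mass_concentration_g_L)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("all geometry fields must be positive")
  if (outer_diameter_nm <= 2 * bilayer_thickness_nm)
    stop_invalid("outer diameter must exceed twice the bilayer thickness")
  structure(list(outer_diameter_nm = outer_diameter_nm,
                 bilayer_thickness_nm = bilayer_thickness_nm,
                 area_per_lipid_nm2 = area_per_lipid_nm2,
                 lipid_molar_mass_g_mol = lipid_molar_mass_g_mol,
                 lipid_mass_concentration_g_L = lipid_mass_concentration_g_L),
            class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf(paste0("Vesicle geometry: d = %.1f nm, bilayer %.2f nm, ",
                     "a_L = %.2f nm^2, M = %.0f g/mol, c = %.3g g/L\n"),
              x$outer_diameter_nm, x$bilayer_thickness_nm,
              x$area_per_lipid_nm2, x$lipid_molar_mass_g_mol,
              x$lipid_mass_concentration_g_L))
  invisible(x)
}

#' Vesicle volume fraction from bilayer geometry
#'
#' For a unilamellar shell the lipid count per vesicle is
#' \eqn{N = 4\pi(R_{out}^2 + R_{in}^2)/a_L} (both leaflets), with
#' \eqn{R_{in} = R_{out} - t}. The vesicle number density follows from the
#' nominal lipid mass concentration, and the volume fraction counts the full
#' outer sphere, i.e. it includes the water enclosed inside the vesicle --
#' the hydrodynamically relevant volume for suspension viscosity.
#'
#' @param geometry a [vesicle_geometry()].
#' @return A list: `phi` (volume fraction), `lipids_per_vesicle`,
#'   `number_density_per_m3`.
#' @examples
#' vesicle_volume_fraction(vesicle_geometry(119.9))$phi  # ~0.097
#' @export
vesicle_volume_fraction <- function(geometry) {
  stopifnot(inherits(geometry, "vesicle_geometry"))
  R_out <- geometry$outer_diameter_nm / 2
  R_in <- R_out - geometry$bilayer_thickness_nm
  if (R_in <= 0) stop_invalid("inner radius is non-positive")
  N_lipid <- 4 * pi * (R_out^2 + R_in^2) / geometry$area_per_lipid_nm2
  mass_per_vesicle_g <- N_lipid * geometry$lipid_molar_mass_g_mol / N_AVOGADRO
  number_density_per_m3 <-
    geometry$lipid_mass_concentration_g_L / mass_per_vesicle_g * 1e3  # 1/m^3
  phi <- number_density_per_m3 * (4 / 3) * pi * (R_out * 1e-9)^3
  list(phi = phi, lipids_per_vesicle = N_lipid,
       number_density_per_m3 = number_density_per_m3)
}

#' Mean face-to-face distance between randomly placed spheres
#'
#' \eqn{L = d\,[(2/(\pi\phi))^{1/3} - 1]} for spheres of diameter \eqn{d} at
#' volume fraction \eqn{\phi}. At \eqn{\phi \ge 2/\pi} the formula reaches
#' contact; 0 is returned with a `contact` attribute.
#'
#' @param phi volume fraction, 0 < phi.
#' @param diameter_nm sphere diameter (nm).
#' @return Face-to-face distance in nm (attribute `contact` when clamped).
#' @examples
#' face_to_face_distance(0.092, 100)  # ~90.6 nm
#' @export
face_to_face_distance <- function(phi, diameter_nm) {
  if (any(!is.finite(phi)) || any(phi <= 0)) stop_invalid("phi must be positive")
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop_invalid("diameter must be positive")
  L <- diameter_nm * ((2 / (pi * phi))^(1 / 3) - 1)
  contact <- phi >= 2 / pi
  L[contact] <- 0
  attr(L, "contact") <- contact
  L
}

#' Gap between adsorbed polymer layers on neighbouring particles
#'
#' With bound coils extending ~2 R_g from each surface, the free gap is
#' \eqn{L - 2 \times 2R_g}... here parameterized directly as
#' `L - 2 * layer_extent`. A negative gap means the bound layers overlap.
#'
#' @param L_nm face-to-face distance between bare surfaces (nm).
#' @param layer_extent_nm extent of one bound layer from the surface
#'   (typically 2 R_g of the adsorbed coil, nm).
#' @return Gap in nm with attribute `overlap` (`TRUE` when negative).
#' @examples
#' bound_chain_gap(90, 23)  # 44 nm
#' @export
bound_chain_gap <- function(L_nm, layer_extent_nm) {
  if (any(!is.finite(L_nm)) || any(L_nm < 0) ||
      any(!is.finite(layer_extent_nm)) || any(layer_extent_nm < 0))
    stop_invalid("distances must be non-negative")
  gap <- L_nm - 2 * layer_extent_nm
  attr(gap, "overlap") <- gap < 0
  gap
}

#' Thermal-thickening metrics of a relative-viscosity curve
#'
#' Quantifies the viscosity step at the gel-fluid transition. Plateaus are
#' medians over configurable windows below and above the melting
#' temperature (default `T_m - [6, 2]` and `T_m + [2, 6]` degrees C, which
#' avoids the ripple-phase region); the jump is the plateau-to-plateau
#' increase in percent, and `peak_jump_percent` additionally reports the
#' peak-to-lower-plateau increase. The transition width is the temperature
#' span between the 10% and 90% crossings of the normalized step (linear
#' interpolation on a 5-point running-median smoothed curve), and the slopes
#' are least-squares d(eta_r)/dT on each plateau window.
#'
#' @param eta_r_curve a dimensionless [viscosity_curve()] spanning at least
#'   the plateau windows.
#' @param T_m_C melting/transition temperature (degrees C).
#' @param plateau_offsets_C numeric length-2 `c(near, far)` offsets from
#'   `T_m_C` defining both plateau windows (default `c(2, 6)`).
#' @return A list of class `"thickening_metrics"`: `jump_percent`,
#'   `peak_jump_percent`, `transition_width_C` (`NA` with `flat = TRUE` when
#'   there is no step), `slope_below`, `slope_above`, `plateau_below`,
#'   `plateau_above`.
#' @seealso [gen_viscosity_curve()] for the matching forward model.
#' @export
thickening_metrics <- function(eta_r_curve, T_m_C, plateau_offsets_C = c(2, 6)) {
  stopifnot(inherits(eta_r_curve, "viscosity_curve"))
  Tv <- eta_r_curve$temperature_C; y <- eta_r_curve$eta_mPas
  near <- plateau_offsets_C[1]; far <- plateau_offsets_C[2]
  below <- Tv >= T_m_C - far & Tv <= T_m_C - near
  above <- Tv >= T_m_C + near & Tv <= T_m_C + far
  if (sum(below) < 3 || sum(above) < 3)
    stop_invalid("curve does not span the plateau windows around T_m")
  p_lo <- stats::median(y[below]); p_hi <- stats::median(y[above])
  jump <- 100 * (p_hi - p_lo) / p_lo
  peak_jump <- 100 * (max(y[Tv >= T_m_C - far & Tv <= T_m_C + far]) - p_lo) / p_lo
  slope_below <- unname(stats::coef(stats::lm(y[below] ~ Tv[below]))[2])
  slope_above <- unname(stats::coef(stats::lm(y[above] ~ Tv[above]))[2])

  width <- NA_real_; flat <- FALSE
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (abs(p_hi - p_lo) <= 5 * max(noise, 1e-12)) {
    flat <- TRUE
  } else {
    # the step is monotone between the plateaus, so isotonic regression is
    # the natural noise-robust estimate of the rise profile
    s <- (y - p_lo) / (p_hi - p_lo)
    mid <- which(Tv >= T_m_C - far & Tv <= T_m_C + far)
    iso <- stats::isoreg(Tv[mid], s[mid])$yf
    t10 <- .mid_crossing(Tv[mid], iso, 0.1)
    t90 <- .mid_crossing(Tv[mid], iso, 0.9)
    if (is.finite(t10) && is.finite(t90) && t90 > t10) width <- t90 - t10
  }
  structure(list(jump_percent = jump, peak_jump_percent = peak_jump,
                 transition_width_C = width, flat = flat,
                 slope_below = slope_below, slope_above = slope_above,
                 plateau_below = p_lo, plateau_above = p_hi),
            class = "thickening_metrics")
}

# crossing of a level by a non-decreasing step function: midpoint between
# the last x below the level and the first x at/above it (isotonic fits are
# piecewise constant, so interpolation across the jump is the fair estimate)
.mid_crossing <- function(x, s, level) {
  below <- which(s < level)
  if (length(below) == 0 || max(below) == length(x)) return(NA_real_)
  i <- max(below)   # s is non-decreasing, so s[i + 1] >= level
  (x[i] + x[i + 1]) / 2
}

#' @export
print.thickening_metrics <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("Thermal thickening: flat curve (plateau ratio %.3f)\n",
                x$plateau_above / x$plateau_below))
  } else {
    cat(sprintf(paste0("Thermal thickening: jump %.1f%% (peak %.1f%%), ",
                       "width %.2f C, slopes %.3g / %.3g per C\n"),
                x$jump_percent, x$peak_jump_percent, x$transition_width_C,
                x$slope_below, x$slope_above))
  }
  invisible(x)
}

#' Compare observed relative viscosities with hard-sphere models
#'
#' Evaluates the parameter-free Einstein and Krieger-Dougherty predictions
#' at given volume fractions and tabulates signed residuals
#' (observed - predicted) and the per-model RMS. No fitting is performed:
#' the volume fractions come from geometry, not from the viscosity data.
#' Points at or above the Krieger-Dougherty packing fraction are excluded
#' from that model and reported.
#'
#' @param phi volume fractions (from [vesicle_volume_fraction()]).
#' @param eta_r_observed measured relative viscosities, same length.
#' @param A,phi_max Krieger-Dougherty constants (defaults 2.7 and 0.71).
#' @return A list of class `"model_comparison"`: `table` (data.frame with
#'   phi, observed, predictions and residuals), `rms` (named vector),
#'   `excluded_kd` (indices beyond packing).
#' @export
compare_models <- function(phi, eta_r_observed, A = 2.7, phi_max = 0.71) {
  if (length(phi) != length(eta_r_observed))
    stop_invalid("phi and eta_r_observed must have equal length")
  pred_e <- einstein_model(phi)
  ok_kd <- phi < phi_max
  pred_kd <- rep(NA_real_, length(phi))
  pred_kd[ok_kd] <- krieger_dougherty(phi[ok_kd], A, phi_max)
  tab <- data.frame(phi = phi, observed = eta_r_observed,
                    einstein = pred_e, resid_einstein = eta_r_observed - pred_e,
                    krieger_dougherty = pred_kd,
                    resid_kd = eta_r_observed - pred_kd)
  rms <- c(einstein = sqrt(mean(tab$resid_einstein^2)),
           krieger_dougherty = sqrt(mean(tab$resid_kd[ok_kd]^2)))
  structure(list(table = tab, rms = rms, excluded_kd = which(!ok_kd)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Suspension-model comparison (observed - predicted):\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("RMS: Einstein %.4g, Krieger-Dougherty %.4g%s\n",
              x$rms[["einstein"]], x$rms[["krieger_dougherty"]],
              if (length(x$excluded_kd))
                sprintf(" (%d point(s) beyond packing excluded)",
                        length(x$excluded_kd)) else ""))
  invisible(x)
}
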