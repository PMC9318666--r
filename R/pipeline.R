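# Study-level orchestration: a structured configuration describing one
# vesicle-polymer study (one neat condition plus one condition per polymer
# molar mass, probed at a gel- and a fluid-phase temperature), a generator
# that emits the full synthetic dataset for that design, and run_study(),
# which runs every analysis stage and assembles a report.

#' Study configuration
#'
#' All parameters of a vesicle-polymer study in one validated list. The
#' defaults describe the reference design this package targets: 100 nm-class
#' DMPC-type vesicles (119.9 nm hydrodynamic diameter) at 17 g/L nominal
#' lipid, polymer molar masses 1.5, 20, 100 and 400 kg/mol, an adsorbed
#' layer scaling as delta = 0.0106 nm * Mw^0.58 (good-solvent exponent), a
#' gel-fluid transition near 23 C, and fluorescence-lifetime truth values on
#' Forster-Hoffman lines at 15 and 35 C.
#'
#' @param seed master RNG seed; per-trace seeds are derived from it.
#' @param vesicle a [vesicle_geometry()].
#' @param polymer_molar_masses polymer molar masses (g/mol).
#' @param layer_prefactor_nm,layer_exponent adsorbed-layer scaling
#'   delta(Mw) = prefactor * Mw^exponent (nm, g/mol).
#' @param temperatures_C the two probe temperatures (gel, fluid).
#' @param dsc list: `T_c_C`, `fwhm_C`, `enthalpy_neat`, `enthalpy_mixed`
#'   (J/g), `scan_rate_C_per_min`.
#' @param transition list: `T_m_C`, `width_C`, `jump_fraction`,
#'   `eta_r_base` for the viscosity ramp.
#' @param saxs list: `d_spacing_nm`, `multilamellar_weight` for the
#'   unextruded reference profile.
#' @param lifetimes named list per temperature (e.g. `"35"`) of target mean
#'   lifetimes (ns), one per condition (neat first), on the calibration
#'   line.
#' @param calibration named list per temperature of `c(A, B)` truth
#'   constants on the ln-ns / ln-cP scale.
#' @param noise list of per-instrument noise levels: `dls` (relative),
#'   `saxs` (fraction of sqrt(I)), `dsc` (W/g), `visc` (relative), `tcspc_counts`
#'   (expected total counts; Poisson).
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(
    seed = 7,
    vesicle = vesicle_geometry(119.9),
    polymer_molar_masses = c(1.5e3, 2e4, 1e5, 4e5),
    layer_prefactor_nm = 0.0106, layer_exponent = 0.58,
    temperatures_C = c(15, 35),
    dsc = list(T_c_C = 22.84, fwhm_C = 1.2, enthalpy_neat = 0.335,
               enthalpy_mixed = 0.234, scan_rate_C_per_min = 2),
    transition = list(T_m_C = 23.5, width_C = 2, jump_fraction = 0.1,
                      eta_r_base = 1.3),
    saxs = list(d_spacing_nm = 6.28, multilamellar_weight = 2),
    lifetimes = list(`15` = c(28.91, 27.38, 27.59, 28.42, 28.74),
                     `35` = c(24.01, 20.61, 21.43, 22.72, 23.91)),
    calibration = list(`15` = c(A = 3.29224, B = 0.0145013),
                       `35` = c(A = 3.0248708, B = 0.045732721)),
    noise = list(dls = 0.01, saxs = 0.02, dsc = 2e-5, visc = 0.005,
                 tcspc_counts = 1e6)) {
  stopifnot(inherits(vesicle, "vesicle_geometry"))
  if (any(polymer_molar_masses <= 0)) stop_invalid("molar masses must be positive")
  if (layer_prefactor_nm <= 0) stop_invalid("layer prefactor must be positive")
  n_cond <- length(polymer_molar_masses) + 1
  for (Tn in names(lifetimes))
    if (length(lifetimes[[Tn]]) != n_cond)
      stop_invalid("lifetimes must have one value per condition (neat first)")
  structure(list(seed = as.integer(seed), vesicle = vesicle,
                 polymer_molar_masses = polymer_molar_masses,
                 layer_prefactor_nm = layer_prefactor_nm,
                 layer_exponent = layer_exponent,
                 temperatures_C = temperatures_C, dsc = dsc,
                 transition = transition, saxs = saxs,
                 lifetimes = lifetimes, calibration = calibration,
                 noise = noise),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0("Study config: neat %.1f nm vesicles + %d polymer ",
                     "conditions (Mw %s g/mol), T = {%s} C, seed %d\n"),
              x$vesicle$outer_diameter_nm, length(x$polymer_molar_masses),
              paste(format(x$polymer_molar_masses, big.mark = ""), collapse = ", "),
              paste(x$temperatures_C, collapse = ", "), x$seed))
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' Flat YAML mirror of [study_config()]; the `vesicle:` block maps to
#' [vesicle_geometry()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_invalid("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$vesicle)) y$vesicle <- do.call(vesicle_geometry, y$vesicle)
  if (!is.null(y$calibration))
    y$calibration <- lapply(y$calibration, function(v) unlist(v))
  do.call(study_config, y)
}

.condition_names <- function(config) {
  c("neat", sprintf("Mw_%g", config$polymer_molar_masses))
}

.layer_delta <- function(config) {
  config$layer_prefactor_nm * config$polymer_molar_masses^config$layer_exponent
}

# deterministic per-trace seed derived from the master seed (kept < 2^31)
.sub_seed <- function(seed, i, j = 0) (seed * 1009L + i * 101L + j) %% 2147483647L

#' Generate the full synthetic dataset for a study
#'
#' Emits, for each condition (neat vesicles plus one per polymer molar
#' mass): DLS correlograms at both probe temperatures (diffusion constants
#' follow from the condition's hydrodynamic diameter, neat diameter plus
#' twice the adsorbed-layer thickness, via Stokes-Einstein), a peak-free
#' SAXS profile, a DSC cooling trace, a viscosity ramp, and TCSPC decays at
#' both temperatures whose intensity-weighted mean lifetime equals the
#' configured target. Shared across conditions: a multilamellar "unextruded"
#' SAXS reference, a water viscosity ramp, and a Forster-Hoffman calibration
#' pair series per temperature. A manifest records every generating
#' parameter.
#'
#' The same seed yields byte-identical bundles.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, every trace is written as
#'   CSV and the manifest as JSON.
#' @return A list of class `"study_bundle"`: `conditions` (named list of
#'   per-condition traces), `shared`, `manifest`, `config`.
#' @export
gen_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  q <- compute_wave_vector(633e-9, 1.33, 173)
  deltas <- .layer_delta(config)
  diameters <- c(config$vesicle$outer_diameter_nm,
                 config$vesicle$outer_diameter_nm + 2 * deltas)
  cond_names <- .condition_names(config)
  n_cond <- length(cond_names)
  tcspc_fracs <- c(0.3, 0.7)   # short/long amplitude fractions
  tau_ratio <- 0.5             # tau1 = tau_ratio * tau2

  conditions <- list()
  truth <- list()
  for (i in seq_len(n_cond)) {
    cn <- cond_names[i]
    cond <- list()
    tr <- list(diameter_nm = diameters[i])
    # DLS at each temperature
    cond$dls <- list()
    for (j in seq_along(config$temperatures_C)) {
      Tc <- config$temperatures_C[j]
      D <- stokes_einstein(diameters[i] * 1e-9 / 2, Tc, direction = "R_to_D")
      cond$dls[[as.character(Tc)]] <-
        gen_correlogram(D, q, amplitude = 0.9, noise_sd = config$noise$dls,
                        temperature_C = Tc, seed = .sub_seed(seed, i, j))
      tr[[paste0("D_", Tc)]] <- D
    }
    # SAXS: extruded conditions are peak-free
    cond$saxs <- gen_saxs_profile(config$saxs$d_spacing_nm, lamellar_weight = 0,
                                  noise_fraction = config$noise$saxs,
                                  temperature_C = 25,
                                  seed = .sub_seed(seed, i, 10))
    # DSC
    enth <- if (i == 1) config$dsc$enthalpy_neat else config$dsc$enthalpy_mixed
    cond$dsc <- gen_dsc_trace(config$dsc$T_c_C, config$dsc$fwhm_C, enth,
                              config$dsc$scan_rate_C_per_min,
                              noise_sd = config$noise$dsc,
                              seed = .sub_seed(seed, i, 20))
    tr$enthalpy_J_per_g <- enth
    tr$T_c_C <- config$dsc$T_c_C
    # viscosity ramp
    cond$viscosity <- gen_viscosity_curve(config$transition$eta_r_base,
                                          config$transition$jump_fraction,
                                          config$transition$T_m_C,
                                          config$transition$width_C,
                                          noise_sd = config$noise$visc,
                                          seed = .sub_seed(seed, i, 30))
    # TCSPC at each temperature: biexponential with the target mean lifetime
    cond$tcspc <- list()
    for (j in seq_along(config$temperatures_C)) {
      Tc <- config$temperatures_C[j]
      tau_target <- config$lifetimes[[as.character(Tc)]][i]
      denom <- sum(tcspc_fracs * c(tau_ratio, 1)^2) /
        sum(tcspc_fracs * c(tau_ratio, 1))
      tau2 <- tau_target / denom
      taus <- c(tau_ratio * tau2, tau2)
      n_bins <- 1200
      cond$tcspc[[as.character(Tc)]] <-
        gen_decay_histogram(tcspc_fracs, taus,
                            total_counts = config$noise$tcspc_counts,
                            bin_width_ns = 0.2, n_bins = n_bins,
                            temperature_C = Tc,
                            seed = .sub_seed(seed, i, 40 + j))
      tr[[paste0("tau_avg_", Tc)]] <- tau_target
      tr[[paste0("microviscosity_", Tc)]] <-
        exp((log(tau_target) - config$calibration[[as.character(Tc)]][["A"]]) /
              config$calibration[[as.character(Tc)]][["B"]])
    }
    if (i > 1) tr$delta_nm <- deltas[i - 1]
    conditions[[cn]] <- cond
    truth[[cn]] <- tr
  }

  shared <- list()
  shared$saxs_unextruded <-
    gen_saxs_profile(config$saxs$d_spacing_nm,
                     lamellar_weight = config$saxs$multilamellar_weight,
                     noise_fraction = config$noise$saxs, temperature_C = 25,
                     seed = .sub_seed(seed, 99, 10))
  shared$water <- gen_viscosity_curve(1, 0, config$transition$T_m_C,
                                      config$transition$width_C, noise_sd = 0,
                                      seed = .sub_seed(seed, 99, 30))
  shared$calibration <- list()
  for (j in seq_along(config$temperatures_C)) {
    Tc <- config$temperatures_C[j]
    AB <- config$calibration[[as.character(Tc)]]
    eta <- c(1, 3.2, 10, 32, 100)
    tau <- exp(AB[["A"]] + AB[["B"]] * log(eta))
    tau <- with_local_seed(.sub_seed(seed, 99, 40 + j),
                           tau * (1 + stats::rnorm(length(eta), 0, 0.002)))
    shared$calibration[[as.character(Tc)]] <-
      structure(data.frame(tau_ns = tau, eta_cP = eta), temperature_C = Tc)
  }

  manifest <- list(seed = seed, condition_names = cond_names,
                   truth = truth,
                   layer = list(prefactor_nm = config$layer_prefactor_nm,
                                exponent = config$layer_exponent),
                   q = q, generated_by = "vesiscope gen_study")
  bundle <- structure(list(conditions = conditions, shared = shared,
                           manifest = manifest, config = config),
                      class = "study_bundle")
  if (!is.null(out_dir)) write_study_bundle(bundle, out_dir)
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Synthetic study bundle: %d conditions x {%s} C, seed %d\n",
              length(x$conditions),
              paste(x$config$temperatures_C, collapse = ", "),
              x$manifest$seed))
  invisible(x)
}

#' Write a study bundle to a directory of CSV files plus a JSON manifest
#'
#' @param bundle a `"study_bundle"` from [gen_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cn in names(bundle$conditions)) {
    cond <- bundle$conditions[[cn]]
    for (Tn in names(cond$dls))
      write_correlogram_csv(cond$dls[[Tn]],
                            file.path(out_dir, sprintf("dls_%s_%sC.csv", cn, Tn)))
    write_saxs_csv(cond$saxs, file.path(out_dir, sprintf("saxs_%s.csv", cn)))
    write_dsc_csv(cond$dsc, file.path(out_dir, sprintf("dsc_%s.csv", cn)))
    write_viscosity_csv(cond$viscosity,
                        file.path(out_dir, sprintf("visc_%s.csv", cn)))
    for (Tn in names(cond$tcspc))
      write_decay_csv(cond$tcspc[[Tn]],
                      file.path(out_dir, sprintf("tcspc_%s_%sC.csv", cn, Tn)))
  }
  write_saxs_csv(bundle$shared$saxs_unextruded,
                 file.path(out_dir, "saxs_unextruded.csv"))
  write_viscosity_csv(bundle$shared$water, file.path(out_dir, "visc_water.csv"))
  for (Tn in names(bundle$shared$calibration)) {
    df <- bundle$shared$calibration[[Tn]]
    .write_keyed_csv(file.path(out_dir, sprintf("calibration_%sC.csv", Tn)),
                     list(temperature_C = Tn), df)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a study bundle back from a directory
#'
#' @param dir directory written by [write_study_bundle()].
#' @param config the [study_config()] describing the design (condition
#'   names and temperatures); defaults to the package default.
#' @return A `"study_bundle"` (manifest loaded from `manifest.json` if
#'   present).
#' @export
read_study_bundle <- function(dir, config = study_config()) {
  cond_names <- .condition_names(config)
  conditions <- list()
  for (cn in cond_names) {
    cond <- list(dls = list(), tcspc = list())
    for (Tc in config$temperatures_C) {
      f <- file.path(dir, sprintf("dls_%s_%sC.csv", cn, Tc))
      if (file.exists(f)) cond$dls[[as.character(Tc)]] <- read_correlogram_csv(f)
      f <- file.path(dir, sprintf("tcspc_%s_%sC.csv", cn, Tc))
      if (file.exists(f)) cond$tcspc[[as.character(Tc)]] <- read_decay_csv(f)
    }
    f <- file.path(dir, sprintf("saxs_%s.csv", cn))
    if (file.exists(f)) cond$saxs <- read_saxs_csv(f)
    f <- file.path(dir, sprintf("dsc_%s.csv", cn))
    if (file.exists(f)) cond$dsc <- read_dsc_csv(f)
    f <- file.path(dir, sprintf("visc_%s.csv", cn))
    if (file.exists(f)) cond$viscosity <- read_viscosity_csv(f)
    conditions[[cn]] <- cond
  }
  shared <- list()
  f <- file.path(dir, "saxs_unextruded.csv")
  if (file.exists(f)) shared$saxs_unextruded <- read_saxs_csv(f)
  f <- file.path(dir, "visc_water.csv")
  if (file.exists(f)) shared$water <- read_viscosity_csv(f)
  shared$calibration <- list()
  for (Tc in config$temperatures_C) {
    f <- file.path(dir, sprintf("calibration_%sC.csv", Tc))
    if (file.exists(f)) shared$calibration[[as.character(Tc)]] <- read_calibration_csv(f)
  }
  manifest <- NULL
  f <- file.path(dir, "manifest.json")
  if (file.exists(f)) manifest <- jsonlite::read_json(f, simplifyVector = TRUE)
  structure(list(conditions = conditions, shared = shared,
                 manifest = manifest, config = config),
            class = "study_bundle")
}

#' Run the full analysis pipeline on a study bundle
#'
#' Executes every stage in order -- DLS correlogram fits (diffusion
#' constants and hydrodynamic diameters at each temperature),
#' adsorbed-layer thicknesses against the neat condition and their
#' molecular-weight scaling, SAXS lamellarity (per condition and for the
#' multilamellar reference), DSC transition and enthalpy with the relative
#' decrease versus neat, relative-viscosity thickening metrics (transition
#' temperature taken from the condition's DSC fit), the geometric volume
#' fraction with Einstein/Krieger-Dougherty predictions and interparticle
#' distances, and TCSPC lifetime fits inverted to microviscosities through
#' per-temperature Forster-Hoffman calibrations. Stages whose inputs are
#' missing are marked absent, never zero-filled. The analysis contains no
#' randomness: identical inputs give identical reports.
#'
#' @param bundle a `"study_bundle"` (from [gen_study()] or
#'   [read_study_bundle()]) or a directory path.
#' @param config used only when `bundle` is a path.
#' @return Object of class `"study_report"`: `conditions` (data.frame, one
#'   row per condition), `lifetimes` (data.frame, condition x temperature),
#'   `derived` (scaling slope, d-spacing, volume fraction, distances, model
#'   comparison, calibrations), `provenance`.
#' @export
run_study <- function(bundle, config = study_config()) {
  if (is.character(bundle)) bundle <- read_study_bundle(bundle, config)
  stopifnot(inherits(bundle, "study_bundle"))
  config <- bundle$config
  cond_names <- names(bundle$conditions)
  temps <- config$temperatures_C
  fluid_T <- as.character(max(temps))

  # --- calibrations (one per temperature) ---
  calibrations <- list()
  for (Tn in names(bundle$shared$calibration)) {
    df <- bundle$shared$calibration[[Tn]]
    calibrations[[Tn]] <- fit_forster_hoffman(df$tau_ns, df$eta_cP,
                                              temperature_C = as.numeric(Tn))
  }

  rows <- list(); tau_rows <- list()
  for (cn in cond_names) {
    cond <- bundle$conditions[[cn]]
    row <- list(condition = cn)
    # DLS
    for (Tn in names(cond$dls)) {
      fit <- fit_correlogram(cond$dls[[Tn]])
      row[[paste0("D_", Tn, "_m2s")]] <- if (fit$converged) fit$D_T else NA_real_
      if (Tn == fluid_T)
        row$diameter_nm <- if (fit$converged) fit$diameter_nm else NA_real_
    }
    # SAXS
    if (!is.null(cond$saxs)) {
      lam <- detect_lamellar_peaks(cond$saxs)
      row$lamellarity <- lam$lamellarity
      row$d_spacing_nm <- lam$d_spacing_nm
    } else {
      row$lamellarity <- NA_character_; row$d_spacing_nm <- NA_real_
    }
    # DSC
    if (!is.null(cond$dsc)) {
      tr <- detect_transition(cond$dsc)
      row$T_c_C <- if (tr$found) tr$T_c_C else NA_real_
      row$dsc_fwhm_C <- if (tr$found) tr$fwhm_C else NA_real_
      row$enthalpy_J_per_g <-
        integrate_enthalpy(cond$dsc)$enthalpy_J_per_g
    } else {
      row$T_c_C <- NA_real_; row$dsc_fwhm_C <- NA_real_
      row$enthalpy_J_per_g <- NA_real_
    }
    # rheology
    if (!is.null(cond$viscosity) && !is.null(bundle$shared$water)) {
      eta_r <- relative_viscosity(cond$viscosity, bundle$shared$water)
      T_m <- if (is.finite(row$T_c_C %||% NA_real_)) row$T_c_C
             else config$transition$T_m_C
      tm <- tryCatch(thickening_metrics(eta_r, T_m),
                     vesiscope_invalid_input = function(e) NULL)
      row$eta_r_jump_percent <- if (!is.null(tm)) tm$jump_percent else NA_real_
      row$eta_r_width_C <- if (!is.null(tm)) tm$transition_width_C else NA_real_
    } else {
      row$eta_r_jump_percent <- NA_real_; row$eta_r_width_C <- NA_real_
    }
    # TCSPC
    for (Tn in names(cond$tcspc)) {
      fit <- fit_biexponential(cond$tcspc[[Tn]])
      micro <- if (fit$converged && !is.null(calibrations[[Tn]]))
        microviscosity_from_lifetime(fit$tau_avg_ns, calibrations[[Tn]])
      else NA_real_
      tau_rows[[paste(cn, Tn)]] <-
        data.frame(condition = cn, temperature_C = as.numeric(Tn),
                   tau_avg_ns = if (fit$converged) fit$tau_avg_ns else NA_real_,
                   microviscosity_cP = micro)
    }
    rows[[cn]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  cond_df <- do.call(rbind, c(rows, make.row.names = FALSE))
  tau_df <- do.call(rbind, c(tau_rows, make.row.names = FALSE))

  # --- cross-condition derived quantities ---
  derived <- list()
  neat_d <- cond_df$diameter_nm[cond_df$condition == "neat"]
  if (length(neat_d) == 1 && is.finite(neat_d)) {
    poly <- cond_df[cond_df$condition != "neat", ]
    deltas <- bound_layer_thickness(poly$diameter_nm, neat_d)
    derived$delta_nm <- stats::setNames(as.numeric(deltas), poly$condition)
    scal <- tryCatch(fit_layer_scaling(config$polymer_molar_masses,
                                       as.numeric(deltas)),
                     vesiscope_invalid_input = function(e) NULL)
    if (!is.null(scal)) {
      derived$layer_scaling_slope <- scal$slope
      derived$layer_scaling_log_prefactor <- scal$log_prefactor
    }
  }
  if (!is.null(bundle$shared$saxs_unextruded)) {
    lam <- detect_lamellar_peaks(bundle$shared$saxs_unextruded)
    derived$unextruded <- list(lamellarity = lam$lamellarity,
                               d_spacing_nm = lam$d_spacing_nm,
                               peaks_invnm = lam$peak_positions)
  }
  vf <- vesicle_volume_fraction(config$vesicle)
  derived$phi <- vf$phi
  derived$lipids_per_vesicle <- vf$lipids_per_vesicle
  derived$eta_r_einstein <- einstein_model(vf$phi)
  derived$eta_r_krieger_dougherty <- krieger_dougherty(vf$phi)
  L <- face_to_face_distance(vf$phi, config$vesicle$outer_diameter_nm)
  derived$face_to_face_nm <- as.numeric(L)
  derived$calibrations <- lapply(calibrations, coef)

  # enthalpy decreases vs neat
  neat_H <- cond_df$enthalpy_J_per_g[cond_df$condition == "neat"]
  if (length(neat_H) == 1 && is.finite(neat_H) && neat_H > 0) {
    mixed <- cond_df[cond_df$condition != "neat", ]
    derived$enthalpy_decrease_percent <-
      stats::setNames(relative_enthalpy_change(neat_H, mixed$enthalpy_J_per_g),
                      mixed$condition)
  }

  structure(list(conditions = cond_df, lifetimes = tau_df, derived = derived,
                 provenance = list(
                   seed = if (!is.null(bundle$manifest$seed))
                     bundle$manifest$seed else NA_integer_,
                   package_version = as.character(utils::packageVersion("vesiscope")),
                   timestamp = NA_character_)),  # kept NA for bit-reproducibility
            class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n\nPer-condition results:\n")
  print(x$conditions, digits = 4, row.names = FALSE)
  cat("\nLifetimes and microviscosities:\n")
  print(x$lifetimes, digits = 4, row.names = FALSE)
  if (!is.null(x$derived$layer_scaling_slope))
    cat(sprintf("\nAdsorbed-layer scaling slope: %.3f\n",
                x$derived$layer_scaling_slope))
  if (!is.null(x$derived$unextruded))
    cat(sprintf("Unextruded reference: %s, d = %.3f nm\n",
                x$derived$unextruded$lamellarity,
                x$derived$unextruded$d_spacing_nm))
  cat(sprintf("Volume fraction phi = %.4f; Einstein eta_r = %.3f; KD eta_r = %.3f\n",
              x$derived$phi, x$derived$eta_r_einstein,
              x$derived$eta_r_krieger_dougherty))
  invisible(x)
}

#' Write a study report as JSON plus CSV tables
#'
#' @param report a `"study_report"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$conditions,
                   file.path(out_dir, "conditions.csv"), row.names = FALSE)
  utils::write.csv(report$lifetimes,
                   file.path(out_dir, "lifetimes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(conditions = report$conditions, lifetimes = report$lifetimes,
         derived = report$derived, provenance = report$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}
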