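test_that("every generator is deterministic under a fixed seed", {
  expect_identical(gen_correlogram(5e-12, 2.6e7, seed = 9),
                   gen_correlogram(5e-12, 2.6e7, seed = 9))
  expect_identical(gen_saxs_profile(6.28, 2, seed = 9),
                   gen_saxs_profile(6.28, 2, seed = 9))
  expect_identical(gen_dsc_trace(noise_sd = 1e-5, seed = 9),
                   gen_dsc_trace(noise_sd = 1e-5, seed = 9))
  expect_identical(gen_viscosity_curve(noise_sd = 0.01, seed = 9),
                   gen_viscosity_curve(noise_sd = 0.01, seed = 9))
  expect_identical(gen_decay_histogram(c(0.7, 0.3), c(5, 25), seed = 9),
                   gen_decay_histogram(c(0.7, 0.3), c(5, 25), seed = 9))
  expect_false(identical(gen_correlogram(5e-12, 2.6e7, seed = 9),
                         gen_correlogram(5e-12, 2.6e7, seed = 10)))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_correlogram(5e-12, 2.6e7, seed = 1))
  invisible(gen_decay_histogram(c(0.7, 0.3), c(5, 25), seed = 1))
  invisible(gen_study(study_config(seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise generation is recovered essentially exactly", {
  q <- compute_wave_vector(633e-9, 1.33, 173)
  fit <- fit_correlogram(gen_correlogram(5.21e-12, q, noise_sd = 0))
  expect_lt(abs(fit$D_T - 5.21e-12) / 5.21e-12, 1e-3)

  res <- detect_lamellar_peaks(gen_saxs_profile(6.28, 2, noise_fraction = 0))
  grid_step <- 2.8 / 299
  expect_lt(abs(res$peak_positions[1] - 1.0), grid_step)

  h <- integrate_enthalpy(gen_dsc_trace(22.84, 1.2, 0.335, noise_sd = 0))
  expect_lt(abs(h$enthalpy_J_per_g - 0.335) / 0.335, 1e-3)

  water <- gen_viscosity_curve(1, 0, noise_sd = 0)
  er <- relative_viscosity(gen_viscosity_curve(1.3, 0.1, 23.5, 2, noise_sd = 0),
                           water)
  m <- thickening_metrics(er, 23.5)
  expect_lt(abs(m$jump_percent - 10) / 10, 1e-2)
})

test_that("decay histograms conserve expected counts within Poisson bounds", {
  total <- 1e6
  h <- gen_decay_histogram(c(0.7, 0.3), c(5, 25), total_counts = total,
                           seed = 17)
  expect_lt(abs(sum(h$counts) - total), 3 * sqrt(total))
  expect_true(all(h$counts == round(h$counts)))
  expect_true(all(h$counts >= 0))
})

test_that("generator preconditions are enforced", {
  expect_error(gen_correlogram(-1, 2.6e7), class = "vesiscope_invalid_input")
  expect_error(gen_correlogram(5e-12, 2.6e7, n_points = 10),
               class = "vesiscope_invalid_input")
  expect_error(gen_saxs_profile(-6), class = "vesiscope_invalid_input")
  expect_error(gen_dsc_trace(enthalpy_J_per_g = -1),
               class = "vesiscope_invalid_input")
  expect_error(gen_viscosity_curve(width_C = 0), class = "vesiscope_invalid_input")
  expect_error(gen_decay_histogram(1, 10, total_counts = 100),
               class = "vesiscope_invalid_input")
})

test_that("gen_study emits a consistent bundle and manifest", {
  cfg <- study_config(seed = 5)
  b <- gen_study(cfg)
  expect_identical(b, gen_study(cfg))   # byte-identical under the same seed
  expect_length(b$conditions, 5)
  # manifest diameters follow neat + 2*delta(Mw)
  deltas <- cfg$layer_prefactor_nm * cfg$polymer_molar_masses^cfg$layer_exponent
  for (i in seq_along(deltas)) {
    cn <- names(b$conditions)[i + 1]
    expect_equal(b$manifest$truth[[cn]]$diameter_nm,
                 cfg$vesicle$outer_diameter_nm + 2 * deltas[i])
  }
  # truth lifetimes sit on the configured calibration lines
  for (Tn in c("15", "35")) {
    AB <- cfg$calibration[[Tn]]
    tau <- vapply(b$manifest$truth, function(x) x[[paste0("tau_avg_", Tn)]],
                  numeric(1))
    eta <- vapply(b$manifest$truth,
                  function(x) x[[paste0("microviscosity_", Tn)]], numeric(1))
    expect_equal(log(tau), AB[["A"]] + AB[["B"]] * log(eta), tolerance = 1e-10)
  }
})
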