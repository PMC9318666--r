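test_that("transition temperature and width are recovered from a clean exotherm", {
  # sigma = 0.5 C <=> FWHM = 1.1774 C
  tr <- gen_dsc_trace(T_c_C = 22.84, fwhm_C = 2 * sqrt(2 * log(2)) * 0.5,
                      enthalpy_J_per_g = 0.3, noise_sd = 1e-5, seed = 4)
  res <- detect_transition(tr)
  expect_true(res$found)
  expect_equal(res$T_c_C, 22.84, tolerance = 0.02 / 22.84)
  expect_equal(res$fwhm_C, 2 * sqrt(2 * log(2)) * 0.5, tolerance = 0.05)
})

test_that("a flat trace reports no transition", {
  tr <- gen_dsc_trace(enthalpy_J_per_g = 0, noise_sd = 1e-5, seed = 2)
  expect_false(detect_transition(tr)$found)
  expect_equal(integrate_enthalpy(tr)$enthalpy_J_per_g, 0, tolerance = 1e-3)
})

test_that("a linear instrumental baseline does not shift T_c", {
  clean <- gen_dsc_trace(22.84, 1.2, 0.335, noise_sd = 0)
  tilted <- gen_dsc_trace(22.84, 1.2, 0.335, baseline = c(0.02, -5e-4),
                          noise_sd = 0)
  expect_equal(detect_transition(clean)$T_c_C,
               detect_transition(tilted)$T_c_C)
})

test_that("enthalpy integration recovers the generating area within 1 percent", {
  tr <- gen_dsc_trace(22.84, 1.2, 0.335, noise_sd = 2e-5, seed = 6)
  res <- integrate_enthalpy(tr)
  expect_equal(res$enthalpy_J_per_g, 0.335, tolerance = 0.01)
  # noiseless: much tighter
  tr0 <- gen_dsc_trace(22.84, 1.2, 0.335, noise_sd = 0)
  expect_equal(integrate_enthalpy(tr0)$enthalpy_J_per_g, 0.335,
               tolerance = 1e-4)
})

test_that("enthalpy is linear in peak amplitude", {
  h1 <- integrate_enthalpy(gen_dsc_trace(23, 1.2, 0.2, noise_sd = 0))
  h2 <- integrate_enthalpy(gen_dsc_trace(23, 1.2, 0.4, noise_sd = 0))
  expect_equal(h2$enthalpy_J_per_g / h1$enthalpy_J_per_g, 2, tolerance = 1e-6)
})

test_that("enthalpy integration absorbs any linear baseline", {
  base_cases <- list(c(0, 0), c(0.05, 0), c(0, 1e-3), c(-0.02, 5e-4))
  vals <- vapply(base_cases, function(b) {
    integrate_enthalpy(gen_dsc_trace(23, 1.2, 0.3, baseline = b,
                                     noise_sd = 0),
                       window = c(17, 29))$enthalpy_J_per_g
  }, numeric(1))
  expect_true(all(abs(vals - vals[1]) / vals[1] < 1e-6))
})

test_that("enthalpy scales inversely with scan rate for a fixed peak shape", {
  tr1 <- gen_dsc_trace(23, 1.2, 0.3, scan_rate_C_per_min = 2, noise_sd = 0)
  # same heat-flow curve relabelled with twice the rate
  tr2 <- dsc_trace(tr1$temperature_C, tr1$heat_flow_W_per_g, 4,
                   direction = "cooling")
  h1 <- integrate_enthalpy(tr1, window = c(17, 29))$enthalpy_J_per_g
  h2 <- integrate_enthalpy(tr2, window = c(17, 29))$enthalpy_J_per_g
  expect_equal(h1 / h2, 2, tolerance = 1e-10)
})

test_that("results are invariant to reversing point order with direction", {
  cool <- gen_dsc_trace(23, 1.5, 0.25, noise_sd = 1e-5, seed = 8)
  heat <- dsc_trace(rev(cool$temperature_C), rev(cool$heat_flow_W_per_g),
                    cool$scan_rate_C_per_min, direction = "heating")
  expect_equal(detect_transition(cool)$T_c_C, detect_transition(heat)$T_c_C)
  expect_equal(integrate_enthalpy(cool)$enthalpy_J_per_g,
               integrate_enthalpy(heat)$enthalpy_J_per_g, tolerance = 1e-10)
})

test_that("relative enthalpy change matches the reference arithmetic", {
  expect_equal(relative_enthalpy_change(0.335, 0.234), 30.1, tolerance = 0.01)
  expect_equal(relative_enthalpy_change(0.335, 0.335), 0)
  expect_equal(relative_enthalpy_change(0.335, 0.242), 27.8, tolerance = 0.01)
  expect_error(relative_enthalpy_change(0, 0.2), class = "vesiscope_invalid_input")
})
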