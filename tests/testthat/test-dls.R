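q_bs <- compute_wave_vector(633e-9, 1.33, 173)

test_that("noiseless correlogram is recovered to machine precision", {
  tr <- gen_correlogram(D = 100 / q_bs^2, q = q_bs, amplitude = 1,
                        noise_sd = 0, n_points = 100)
  fit <- fit_correlogram(tr)
  expect_true(fit$converged)
  expect_equal(fit$gamma, 100, tolerance = 1e-8)
  expect_equal(fit$amplitude, 1, tolerance = 1e-8)
})

test_that("noisy correlogram recovers the decay rate within 2 percent", {
  D <- 500 / q_bs^2   # Gamma = 500 1/s
  tr <- gen_correlogram(D, q_bs, amplitude = 0.9, noise_sd = 0.01,
                        n_points = 200, seed = 42)
  fit <- fit_correlogram(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma - 500) / 500, 0.02)
  expect_equal(fit$D_T, D, tolerance = 0.02)
})

test_that("degenerate traces are flagged, not fitted", {
  tau <- 10^seq(-5, -1, length.out = 50)
  const <- correlogram(tau, rep(0.5, 50), q_bs, 25)
  expect_false(fit_correlogram(const)$converged)
  rising <- correlogram(tau, seq(0.1, 1, length.out = 50), q_bs, 25)
  expect_false(fit_correlogram(rising)$converged)
  expect_error(fit_correlogram(correlogram(tau[1:5], rep(0.1, 5), q_bs, 25)),
               class = "vesiscope_invalid_input")
})

test_that("dls_fit methods are mutually consistent", {
  tr <- gen_correlogram(5.2e-12, q_bs, noise_sd = 0.01, seed = 3)
  fit <- fit_correlogram(tr)
  expect_equal(unname(coef(fit)[["gamma"]] / tr$q^2), fit$D_T)
  expect_equal(tr$g2_minus_1 - predict(fit), as.numeric(residuals(fit)))
  expect_equal(sum(residuals(fit)^2), fit$residual_ss, tolerance = 1e-10)
  # sizing consistent with the Stokes-Einstein helper
  expect_equal(fit$R_h,
               stokes_einstein(fit$D_T, tr$temperature_C, direction = "D_to_R"))
})

test_that("bound layer thickness matches the reference differences", {
  expect_equal(bound_layer_thickness(157.7, 119.9), 18.9,
               ignore_attr = TRUE)
  expect_equal(bound_layer_thickness(121.4, 119.9), 0.75,
               ignore_attr = TRUE)
  expect_equal(bound_layer_thickness(119.9, 119.9), 0, ignore_attr = TRUE)
})

test_that("bound layer thickness is antisymmetric and flags shrinkage", {
  a <- bound_layer_thickness(130, 120)
  b <- bound_layer_thickness(120, 130)
  expect_equal(as.numeric(a), -as.numeric(b))
  expect_true(attr(b, "negative"))
  expect_false(attr(a, "negative"))
  expect_error(bound_layer_thickness(-1, 120), class = "vesiscope_invalid_input")
})

test_that("layer scaling recovers an exact power law to machine precision", {
  Mw <- c(1e3, 1e4, 1e5, 1e6)
  fit <- fit_layer_scaling(Mw, 0.01 * Mw^0.58)
  expect_equal(fit$slope, 0.58, tolerance = 1e-10)
  expect_equal(10^fit$log_prefactor, 0.01, tolerance = 1e-8)
  expect_equal(predict(fit, 2e4), 0.01 * 2e4^0.58, tolerance = 1e-8)
  flat <- fit_layer_scaling(Mw, rep(3, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("layer scaling on the reference thicknesses gives slope ~0.56", {
  fit <- fit_layer_scaling(ref$molar_mass, ref$delta_nm)
  # frozen from an independent least-squares evaluation in log10-log10 space
  expect_equal(fit$slope, 0.56227777, tolerance = 1e-6)
})

test_that("layer scaling slope does not depend on the logarithm base", {
  # independent oracle: same regression done in natural logs
  x <- log(ref$molar_mass); y <- log(ref$delta_nm)
  slope_ln <- unname(coef(lm(y ~ x))[2])
  expect_equal(fit_layer_scaling(ref$molar_mass, ref$delta_nm)$slope,
               slope_ln, tolerance = 1e-10)
})

test_that("layer scaling excludes non-positive thicknesses and errors when starved", {
  fit <- fit_layer_scaling(c(1e3, 1e4, 1e5), c(-0.2, 2, 8))
  expect_equal(fit$excluded, 1L)
  expect_equal(length(fit$delta_nm), 2L)
  expect_error(fit_layer_scaling(c(1e3, 1e4), c(-1, 5)),
               class = "vesiscope_invalid_input")
})
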