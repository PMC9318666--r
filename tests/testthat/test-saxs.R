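test_that("Bragg spacing is 2*pi/q for the reference peak positions", {
  expect_equal(bragg_spacing(1.0), 2 * pi)
  expect_equal(round(bragg_spacing(1.0), 2), 6.28)
  expect_equal(bragg_spacing(2.0), pi)
  expect_equal(bragg_spacing(0.9213), 6.82, tolerance = 1e-3)
  expect_error(bragg_spacing(0), class = "vesiscope_invalid_input")
  expect_error(bragg_spacing(-1), class = "vesiscope_invalid_input")
})

test_that("bragg_spacing(q) * q is exactly 2*pi", {
  q <- 10^seq(-2, 2, length.out = 41)
  expect_equal(bragg_spacing(q) * q, rep(2 * pi, 41))
})

test_that("lamellar peaks of a multilamellar profile are found at q* and 2q*", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 2, noise_fraction = 0.02,
                        seed = 7)
  res <- detect_lamellar_peaks(p)
  expect_length(res$peak_positions, 2)
  grid_step <- diff(p$q_invnm[1:2])
  expect_lt(abs(res$peak_positions[1] - 1.0), 1.5 * grid_step)
  expect_lt(abs(res$peak_positions[2] - 2.0), 1.5 * grid_step)
  expect_equal(res$d_spacing_nm, 6.28, tolerance = 0.01)
  expect_identical(res$lamellarity, "multilamellar")
})

test_that("a pure power-law profile yields no peaks and reads unilamellar", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 0, noise_fraction = 0.02,
                        seed = 7)
  res <- detect_lamellar_peaks(p)
  expect_length(res$peak_positions, 0)
  expect_identical(res$lamellarity, "unilamellar")
  expect_true(is.na(res$d_spacing_nm))
})

test_that("a lone first-order peak is indeterminate", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 2, second_order_ratio = 0,
                        noise_fraction = 0.01, seed = 5)
  res <- detect_lamellar_peaks(p)
  expect_gte(length(res$peak_positions), 1)
  expect_false(res$second_order)
  expect_identical(res$lamellarity, "indeterminate")
})

test_that("classification follows the q2/q1 ratio rule", {
  expect_identical(classify_lamellarity(c(1.0, 2.0)), "multilamellar")
  expect_identical(classify_lamellarity(numeric(0)), "unilamellar")
  expect_identical(classify_lamellarity(c(1.0, 2.3)), "indeterminate")
  expect_identical(classify_lamellarity(c(1.0, 1.95)), "multilamellar")
})

test_that("peak detection is invariant to an intensity rescale", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 2, noise_fraction = 0.02,
                        seed = 11)
  p2 <- saxs_profile(p$q_invnm, 37.5 * p$intensity)
  r1 <- detect_lamellar_peaks(p)
  r2 <- detect_lamellar_peaks(p2)
  expect_equal(r1$peak_positions, r2$peak_positions)
  expect_identical(r1$lamellarity, r2$lamellarity)
})

test_that("detection validates its window", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 2, seed = 1)
  expect_error(detect_lamellar_peaks(p, q_window = c(0.1, 5)),
               class = "vesiscope_invalid_input")
  expect_error(detect_lamellar_peaks(p, q_window = c(2.99, 3.0)),
               class = "vesiscope_invalid_input")
})

test_that("low-q power-law exponent is exact on exact data", {
  q <- seq(0.1, 1, length.out = 50)
  expect_equal(low_q_power_law(saxs_profile(q, q^-2), c(0.1, 1)), -2,
               tolerance = 1e-12)
  expect_equal(low_q_power_law(saxs_profile(q, rep(5, 50)), c(0.1, 1)), 0,
               tolerance = 1e-12)
})

test_that("low-q exponent is recovered from a noisy profile within 0.05", {
  p <- gen_saxs_profile(6.28, lamellar_weight = 0, powerlaw_exponent = 2.5,
                        noise_fraction = 0.02, seed = 9)
  expect_equal(low_q_power_law(p, c(0.25, 0.9)), -2.5, tolerance = 0.05 / 2.5)
  expect_error(low_q_power_law(saxs_profile(1:10, rep(1, 10)), c(1, 1.2)),
               class = "vesiscope_invalid_input")
})
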