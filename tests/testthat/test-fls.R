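test_that("intensity-weighted lifetime follows its closed form", {
  expect_equal(intensity_weighted_lifetime(1, 24.01), 24.01)
  expect_equal(intensity_weighted_lifetime(c(0.5, 0.5), c(10, 20)),
               (0.5 * 100 + 0.5 * 400) / (0.5 * 10 + 0.5 * 20))
  expect_error(intensity_weighted_lifetime(c(0, 0), c(1, 2)),
               class = "vesiscope_invalid_input")
  expect_error(intensity_weighted_lifetime(c(1, -1), c(1, 2)),
               class = "vesiscope_invalid_input")
})

test_that("intensity-weighted lifetime stays within the component range", {
  set.seed(1)
  for (i in 1:25) {
    a <- runif(3); tau <- runif(3, 1, 50)
    m <- intensity_weighted_lifetime(a, tau)
    expect_gte(m, min(tau)); expect_lte(m, max(tau))
  }
})

test_that("biexponential fit recovers components and mean lifetime", {
  h <- gen_decay_histogram(c(0.7, 0.3), c(5, 25), total_counts = 1e6,
                           seed = 12)
  fit <- fit_biexponential(h)
  expect_true(fit$converged)
  expect_false(fit$collapsed)
  expect_lt(abs(fit$lifetimes_ns[1] - 5) / 5, 0.03)
  expect_lt(abs(fit$lifetimes_ns[2] - 25) / 25, 0.03)
  truth <- intensity_weighted_lifetime(c(0.7, 0.3), c(5, 25))
  expect_lt(abs(fit$tau_avg_ns - truth) / truth, 0.01)
  expect_lte(fit$lifetimes_ns[1], fit$lifetimes_ns[2])
  expect_equal(sum(fit$amplitudes), 1, tolerance = 1e-8)
  expect_lt(fit$chi2_reduced, 1.3)
})

test_that("a single-exponential decay collapses gracefully", {
  h <- gen_decay_histogram(1, 10, total_counts = 1e6, seed = 3)
  fit <- suppressWarnings(fit_biexponential(h))
  expect_true(fit$converged)
  expect_equal(fit$tau_avg_ns, 10, tolerance = 0.1 / 10)
})

test_that("degenerate histograms are rejected", {
  t <- (1:200 - 0.5) * 0.1
  expect_error(fit_biexponential(decay_histogram(t, rep(0, 200))),
               class = "vesiscope_invalid_input")
  expect_error(fit_biexponential(decay_histogram(t, rep(10, 200))),
               class = "vesiscope_invalid_input")  # only 2000 counts
})

test_that("tcspc_fit predictions track the histogram", {
  h <- gen_decay_histogram(c(0.6, 0.4), c(8, 22), total_counts = 1e6,
                           seed = 21)
  fit <- fit_biexponential(h)
  r <- residuals(fit)
  ok <- !is.na(r)
  # Poisson scale: residuals should be a few sqrt(counts) at most
  expect_lt(max(abs(r[ok]) / sqrt(pmax(h$counts[ok], 1))), 6)
})

test_that("Forster-Hoffman two-point calibrations reproduce the reference constants", {
  cal35 <- fit_forster_hoffman(ref$tau35[1:2], ref$eta35[1:2], 35)
  expect_equal(cal35$slope_B, 0.0457, tolerance = 1e-3)
  expect_equal(cal35$slope_B, log(24.01 / 20.61) / log(28.75 / 1.02),
               tolerance = 1e-12)
  cal15 <- fit_forster_hoffman(ref$tau15[1:2], ref$eta15[1:2], 15)
  expect_equal(cal15$slope_B, 0.0145, tolerance = 1e-2)
})

test_that("an exact log-log line is fitted to machine precision", {
  eta <- c(0.5, 2, 11, 80)
  tau <- exp(3 + 0.05 * log(eta))
  cal <- fit_forster_hoffman(tau, eta)
  expect_equal(cal$intercept_A, 3, tolerance = 1e-12)
  expect_equal(cal$slope_B, 0.05, tolerance = 1e-12)
  expect_error(fit_forster_hoffman(c(10, 12), c(5, 5)),
               class = "vesiscope_invalid_input")
})

test_that("microviscosity inversion reproduces the reference values", {
  cal <- fit_forster_hoffman(ref$tau35[1:2], ref$eta35[1:2], 35)
  expect_equal(microviscosity_from_lifetime(23.91, cal), 26.24,
               tolerance = 1e-3)
  expect_equal(microviscosity_from_lifetime(21.43, cal), 2.39,
               tolerance = 2e-3)
})

test_that("inversion is the exact inverse of prediction", {
  cal <- fit_forster_hoffman(ref$tau35[1:2], ref$eta35[1:2], 35)
  # calibration anchors map back to themselves
  expect_equal(microviscosity_from_lifetime(ref$tau35[1], cal), ref$eta35[1],
               tolerance = 1e-10)
  expect_equal(microviscosity_from_lifetime(ref$tau35[2], cal), ref$eta35[2],
               tolerance = 1e-10)
  eta <- c(0.7, 5, 60)
  expect_equal(microviscosity_from_lifetime(predict(cal, eta), cal), eta,
               tolerance = 1e-10)
})

test_that("microviscosity is monotone in lifetime for positive slope", {
  cal <- fit_forster_hoffman(ref$tau35[1:2], ref$eta35[1:2], 35)
  taus <- seq(20, 25, by = 0.5)
  expect_true(all(diff(microviscosity_from_lifetime(taus, cal)) > 0))
})

test_that("all fluid-phase reference rows share one calibration within 1 percent", {
  cal <- fit_forster_hoffman(ref$tau35[1:2], ref$eta35[1:2], 35)
  eta_hat <- microviscosity_from_lifetime(ref$tau35, cal)
  expect_true(all(abs(eta_hat - ref$eta35) / ref$eta35 < 0.01))
})
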