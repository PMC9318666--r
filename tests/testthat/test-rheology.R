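test_that("relative viscosity is the identity on itself and linear in scale", {
  v <- gen_viscosity_curve(1.5, 0.2, 23.5, 2, noise_sd = 0.01, seed = 3)
  expect_equal(relative_viscosity(v, v)$eta_mPas,
               rep(1, length(v$temperature_C)))
  v2 <- viscosity_curve(v$temperature_C, 2 * v$eta_mPas)
  expect_equal(relative_viscosity(v2, v)$eta_mPas,
               rep(2, length(v$temperature_C)))
})

test_that("a 10 percent step over the solvent survives the ratio", {
  sample <- gen_viscosity_curve(1, 0.1, 23.5, 2, noise_sd = 0)
  water <- gen_viscosity_curve(1, 0, 23.5, 2, noise_sd = 0)
  er <- relative_viscosity(sample, water)
  expect_equal(min(er$eta_mPas), 1, tolerance = 1e-3)
  expect_equal(max(er$eta_mPas), 1.1, tolerance = 1e-3)
  w2 <- viscosity_curve(c(50, 60), c(1, 1))
  expect_error(relative_viscosity(sample, w2), class = "vesiscope_invalid_input")
})

test_that("Einstein model evaluates the dilute hard-sphere line", {
  expect_equal(einstein_model(0), 1)
  expect_equal(einstein_model(0.092), 1.23)
  expect_equal(einstein_model(0.2), 1.5)
  expect_error(einstein_model(-0.1), class = "vesiscope_invalid_input")
  expect_error(einstein_model(1), class = "vesiscope_invalid_input")
})

test_that("Krieger-Dougherty matches its closed form and limits", {
  expect_equal(krieger_dougherty(0), 1)
  expect_equal(krieger_dougherty(0.092), (1 - 0.092 / 0.71)^(-2.7 * 0.71))
  expect_equal(krieger_dougherty(0.092), 1.305, tolerance = 1e-3)
  # first-order Taylor limit: eta_r ~ 1 + A*phi
  phi <- 1e-5
  expect_equal((krieger_dougherty(phi) - 1) / phi, 2.7, tolerance = 1e-3)
  expect_error(krieger_dougherty(0.71), class = "vesiscope_invalid_input")
})

test_that("Krieger-Dougherty dominates Einstein over the whole domain", {
  phi <- seq(0.001, 0.7, length.out = 200)
  expect_true(all(krieger_dougherty(phi) >= einstein_model(phi)))
})

test_that("volume fraction from geometry matches a brute-force chain", {
  geo <- vesicle_geometry(119.9, 4.4, 0.60, 678, 17)
  res <- vesicle_volume_fraction(geo)
  # independent step-by-step recomputation
  R_out <- 119.9 / 2; R_in <- R_out - 4.4
  N <- 4 * pi * (R_out^2 + R_in^2) / 0.60
  m <- N * 678 / 6.02214076e23
  nd <- 17 / m * 1e3
  phi <- nd * 4 / 3 * pi * (R_out * 1e-9)^3
  expect_equal(res$phi, phi, tolerance = 1e-12)
  expect_equal(res$lipids_per_vesicle, N, tolerance = 1e-12)
  # ~9-10 percent for the reference composition
  expect_equal(res$phi, 0.097, tolerance = 0.01)
})

test_that("volume fraction scales linearly in concentration and area per lipid", {
  base <- vesicle_volume_fraction(vesicle_geometry(119.9))$phi
  expect_equal(vesicle_volume_fraction(
    vesicle_geometry(119.9, lipid_mass_concentration_g_L = 34))$phi,
    2 * base, tolerance = 1e-12)
  # doubling the area per lipid halves the lipids per vesicle, doubling the
  # vesicle count at fixed lipid mass
  expect_equal(vesicle_volume_fraction(
    vesicle_geometry(119.9, area_per_lipid_nm2 = 1.2))$phi,
    2 * base, tolerance = 1e-12)
})

test_that("volume fraction increases with vesicle diameter", {
  phis <- vapply(seq(60, 400, by = 20), function(d)
    vesicle_volume_fraction(vesicle_geometry(d))$phi, numeric(1))
  expect_true(all(diff(phis) > 0))
  expect_error(vesicle_geometry(8, 4.4), class = "vesiscope_invalid_input")
})

test_that("face-to-face distance matches the closed form", {
  expect_equal(as.numeric(face_to_face_distance(0.092, 100)),
               100 * ((2 / (pi * 0.092))^(1 / 3) - 1))
  expect_equal(as.numeric(face_to_face_distance(0.092, 100)), 90.6,
               tolerance = 1e-3)
  expect_equal(as.numeric(face_to_face_distance(0.092, 119.9)), 108.6,
               tolerance = 1e-3)
  # contact limit
  L <- face_to_face_distance(2 / pi, 150)
  expect_equal(as.numeric(L), 0)
  expect_true(attr(L, "contact"))
})

test_that("face-to-face distance is homogeneous of degree 1 in diameter", {
  expect_equal(as.numeric(face_to_face_distance(0.05, 250)),
               2.5 * as.numeric(face_to_face_distance(0.05, 100)))
})

test_that("bound-chain gap flags overlap", {
  expect_equal(as.numeric(bound_chain_gap(90, 23)), 44)
  expect_equal(as.numeric(bound_chain_gap(90, 45)), 0)
  g <- bound_chain_gap(90, 46)
  expect_equal(as.numeric(g), -2)
  expect_true(attr(g, "overlap"))
})

test_that("thickening metrics read a flat curve as flat", {
  water <- gen_viscosity_curve(1, 0, 23.5, 2, noise_sd = 0)
  flat <- gen_viscosity_curve(1.3, 0, 23.5, 2, noise_sd = 0.002, seed = 5)
  m <- thickening_metrics(relative_viscosity(flat, water), 23.5)
  expect_true(m$flat)
  expect_lt(abs(m$jump_percent), 1)
  expect_true(is.na(m$transition_width_C))
  short <- viscosity_curve(seq(22, 25, 0.5), rep(1.3, 7))
  expect_error(thickening_metrics(short, 23.5), class = "vesiscope_invalid_input")
})

test_that("model comparison separates the generating model", {
  phi <- c(0.02, 0.05, 0.092, 0.15)
  from_kd <- compare_models(phi, krieger_dougherty(phi))
  expect_lt(from_kd$rms[["krieger_dougherty"]], 1e-12)
  expect_gt(from_kd$rms[["einstein"]], 1e-3)
  from_e <- compare_models(phi, einstein_model(phi))
  expect_lt(from_e$rms[["einstein"]], 1e-12)
  scaled <- compare_models(phi, 1.1 * krieger_dougherty(phi))
  expect_gt(scaled$rms[["einstein"]], 0)
  expect_gt(scaled$rms[["krieger_dougherty"]], 0)
  expect_lt(scaled$rms[["krieger_dougherty"]], scaled$rms[["einstein"]])
})

test_that("model comparison excludes points beyond packing", {
  res <- compare_models(c(0.1, 0.75), c(1.4, 20))
  expect_equal(res$excluded_kd, 2L)
  expect_true(is.na(res$table$krieger_dougherty[2]))
  expect_true(is.finite(res$rms[["krieger_dougherty"]]))
})
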