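tab <- swir_property_table()

test_that("penetration depth summaries behave on constructed records", {
  fake <- list(max_depths = 0.5, exit_weights = 1)
  expect_equal(mean_penetration_depth(fake), 0.5)
  fake3 <- list(max_depths = c(0.2, 0.4, 0.6), exit_weights = c(1, 1, 1))
  expect_equal(mean_penetration_depth(fake3, weighted = FALSE), 0.4)
  expect_equal(mean_penetration_depth(fake3), 0.4)
  skew <- list(max_depths = c(0.2, 0.4, 0.6), exit_weights = c(2, 1, 1))
  expect_equal(mean_penetration_depth(skew), weighted.mean(c(0.2, 0.4, 0.6),
                                                           c(2, 1, 1)))
  empty <- list(max_depths = numeric(0), exit_weights = numeric(0))
  expect_error(mean_penetration_depth(empty), "0 detected")
})

test_that("relative power and absorbance satisfy their defining identities", {
  mk <- function(frac, n = 1e6) {
    list(incident_weight = n, n_photons = n, detected_weight = frac * n,
         exit_weights = rep(1, 10),
         config_echo = list(geometry = sensor_geometry()))
  }
  expect_equal(relative_power(mk(1)), 100)
  expect_equal(relative_power(mk(0.0251)), 2.51)
  expect_equal(absorbance(mk(0.01)), 2)
  expect_equal(absorbance(mk(1)), 0)
  expect_warning(a <- absorbance(mk(0)), "infinite")
  expect_identical(a, Inf)
})

test_that("absorbance and relative power are consistent on a real simulation", {
  m <- build_finger_model(tab, 1684, 2)
  res <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 5e4, seed = 17))
  expect_equal(absorbance(res), 2 - log10(relative_power(res)),
               tolerance = 1e-12)
  expect_gt(relative_power_se(res), 0)
  expect_lt(relative_power_se(res), relative_power(res))
})

test_that("min-max normalization handles monotone and degenerate curves", {
  expect_equal(normalize_absorbance(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(normalize_absorbance(c(5, 5, 5)), c(0, 0, 0))
  x <- c(0.3, 0.35, 0.5, 0.9)
  expect_true(all(diff(normalize_absorbance(x)) > 0))
  expect_error(normalize_absorbance(1), "at least two")
})

test_that("perturbation reweighting is exact for zero perturbation and monotone", {
  m <- build_finger_model(tab, 1684, 1)
  res <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 5e4, seed = 19))
  same <- reweight_result(res, rep(0, 7))
  expect_equal(same$detected_weight, res$detected_weight, tolerance = 1e-12)
  up <- reweight_result(res, rep(0.01, 7))
  expect_lt(up$detected_weight, res$detected_weight)
  down <- reweight_result(res, rep(-0.01, 7))
  expect_gt(down$detected_weight, res$detected_weight)
})

test_that("perturbation reweighting agrees with an independent rerun", {
  # move mu_a by a finite step and compare the reweighted estimate with a
  # fresh simulation of the perturbed medium
  m1 <- build_finger_model(tab, 1650, 1)
  m6 <- build_finger_model(tab, 1650, 6)
  g <- sensor_geometry(separation = 0.7)
  cfg <- transport_config(n_photons = 2e5, seed = 23)
  r1 <- run_simulation(m1, g, cfg)
  rw <- reweight_result(r1, m6$layers$mu_a - m1$layers$mu_a)
  direct <- run_simulation(m6, g, transport_config(n_photons = 2e5, seed = 77))
  se <- sqrt(detected_fraction_se(r1)^2 + detected_fraction_se(direct)^2)
  expect_lt(abs(rw$detected_weight - direct$detected_weight) / r1$n_photons,
            3 * se)
})

test_that("concentration sweeps share paths and respond to lactate", {
  rows <- concentration_sweep(tab, 1650, 1.0, 1:6,
                              config = transport_config(n_photons = 1e5,
                                                        seed = 29))
  expect_equal(nrow(rows), 6L)
  expect_equal(rows$c_lactate, 1:6)
  expect_equal(rows$n_detected, rep(rows$n_detected[1], 6))  # shared paths
  # more lactate, more absorption, higher absorbance
  expect_true(all(diff(rows$absorbance) > 0))
  expect_equal(rows$absorbance,
               2 - log10(rows$relative_power_pct), tolerance = 1e-12)

  one <- concentration_sweep(tab, 1650, 1.0, 2,
                             config = transport_config(n_photons = 2e4,
                                                       seed = 29))
  expect_equal(nrow(one), 1L)
  expect_error(concentration_sweep(tab, 1650, 1, numeric(0)), "non-empty")
})

test_that("grid sweep covers the requested cells with derived seeds", {
  rows <- grid_sweep(tab, wavelengths = c(1684, 1920),
                     separations = c(0.7, 1.5), c_lactate = 2,
                     config = transport_config(n_photons = 2e4, seed = 1))
  expect_equal(nrow(rows), 4L)
  expect_setequal(rows$wavelength, c(1684, 1920))
  expect_setequal(rows$separation_d, c(0.7, 1.5))
  expect_true(all(rows$relative_power_pct >= 0 &
                  rows$relative_power_pct <= 100))
})

test_that("sweep and simulation outputs serialize to portable text", {
  rows <- grid_sweep(tab, wavelengths = 1684, separations = 1, c_lactate = 2,
                     config = transport_config(n_photons = 2e4, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(rows, path, config = transport_config(n_photons = 2e4))
  back <- utils::read.csv(path)
  expect_equal(back$relative_power_pct, rows$relative_power_pct)
  expect_true(file.exists(sub("\\.csv$", ".manifest.json", path)))

  res <- run_simulation(build_finger_model(tab, 1684, 2),
                        sensor_geometry(separation = 1),
                        transport_config(n_photons = 2e4, seed = 8,
                                         record_map = TRUE,
                                         map_voxel_mm = 0.05))
  dir <- withr::local_tempdir()
  write_simulation_result(res, dir)
  expect_true(all(file.exists(file.path(dir, c("records.csv", "event_map.csv",
                                               "manifest.json")))))
  recs <- utils::read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(recs), res$n_detected)
  emap <- utils::read.csv(file.path(dir, "event_map.csv"))
  expect_equal(sum(emap$count), sum(res$event_map))
})
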