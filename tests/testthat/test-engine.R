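# End-to-end physics of the compiled engine against independent oracles.

tab <- swir_property_table()

test_that("pure-absorber slab reproduces Beer-Lambert transmittance", {
  for (p in list(c(1, 1), c(0.45, 1))) {
    fx <- make_pure_absorber_slab(p[1], p[2])
    res <- run_simulation(fx$model, full_surface_geometry(),
                          transport_config(n_photons = 1e5, seed = 42))
    trans <- res$escaped_bottom_weight / res$incident_weight
    se <- sqrt(fx$oracle_value * (1 - fx$oracle_value) / 1e5)
    expect_lt(abs(trans - fx$oracle_value), 3 * se)
    expect_equal(fx$oracle_value, exp(-p[1] * p[2]))
  }
  # thin-slab limit
  expect_gt(make_pure_absorber_slab(1, 1e-6)$oracle_value, 0.999999)
})

test_that("semi-infinite albedo-0.9 reflectance matches the frozen brute-force oracle", {
  fx <- make_semiinfinite_medium(0.9, g = 0,
                                 oracle_value = FROZEN_ALBEDO09_REFLECTANCE)
  res <- run_simulation(fx$model, full_surface_geometry(),
                        transport_config(n_photons = 2e5, seed = 7))
  refl <- res$detected_weight / res$incident_weight
  tol <- 3 * sqrt(detected_fraction_se(res)^2 + FROZEN_ALBEDO09_SE^2)
  expect_lt(abs(refl - fx$oracle_value), tol)
})

test_that("forward-peaked scattering reflects less than isotropic", {
  # paired comparison at reduced photon counts, live brute-force oracle
  or0 <- albedo_reflectance_bruteforce(0.9, g = 0, n_photons = 3e4, seed = 11)
  or9 <- albedo_reflectance_bruteforce(0.9, g = 0.9, n_photons = 3e4, seed = 11)
  expect_lt(or9$value + 3 * or9$se, or0$value - 3 * or0$se)

  fx9 <- make_semiinfinite_medium(0.9, g = 0.9)
  res9 <- run_simulation(fx9$model, full_surface_geometry(),
                         transport_config(n_photons = 5e4, seed = 7))
  refl9 <- res9$detected_weight / res9$incident_weight
  tol <- 3 * sqrt(detected_fraction_se(res9)^2 + or9$se^2)
  expect_lt(abs(refl9 - or9$value), tol)
})

test_that("energy is conserved exactly with roulette disabled", {
  m <- build_finger_model(tab, 1684, 2)
  res <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 5e3, seed = 3,
                                         weight_threshold = 0))
  expect_equal(res$n_capped, 0)
  balance <- res$detected_weight + res$absorbed_weight +
    res$escaped_other_weight + res$cap_lost_weight
  expect_lt(abs(balance - res$launched_weight) / res$launched_weight, 1e-9)
  # launched weight is the incident weight minus the specular loss
  expect_equal(res$launched_weight + res$specular_weight,
               res$incident_weight, tolerance = 1e-9)
})

test_that("energy is conserved in expectation with roulette enabled", {
  # boosted survivors already flow into the detected/absorbed/escaped
  # budgets, so those three balance the launched weight in expectation;
  # the kill ledger is diagnostic only
  m <- build_finger_model(tab, 1920, 2)
  imbalance <- vapply(1:20, function(s) {
    r <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 2e3, seed = s))
    (r$detected_weight + r$absorbed_weight + r$escaped_other_weight +
       r$cap_lost_weight - r$launched_weight) / r$launched_weight
  }, numeric(1))
  expect_lt(abs(mean(imbalance)), 3 * sd(imbalance) / sqrt(20))
})

test_that("identical seeds give bit-identical results; different seeds differ", {
  m <- build_finger_model(tab, 1684, 2)
  g <- sensor_geometry(separation = 1)
  cfg <- transport_config(n_photons = 2e4, seed = 99)
  r1 <- run_simulation(m, g, cfg)
  r2 <- run_simulation(m, g, cfg)
  expect_identical(r1$detected_weight, r2$detected_weight)
  expect_identical(r1$exit_weights, r2$exit_weights)
  expect_identical(r1$max_depths, r2$max_depths)
  expect_identical(r1$path_lengths, r2$path_lengths)
  cfg$seed <- 100L
  r3 <- run_simulation(m, g, cfg)
  expect_false(identical(r1$detected_weight, r3$detected_weight))
})

test_that("chunked runs are reproducible and conserve energy per aggregate", {
  m <- build_finger_model(tab, 1684, 2)
  g <- sensor_geometry(separation = 1)
  c4 <- transport_config(n_photons = 2e4, seed = 5, n_chunks = 4,
                         weight_threshold = 0)
  r1 <- run_simulation(m, g, c4)
  r2 <- run_simulation(m, g, c4)
  expect_identical(r1$detected_weight, r2$detected_weight)
  balance <- r1$detected_weight + r1$absorbed_weight +
    r1$escaped_other_weight
  expect_lt(abs(balance - r1$launched_weight) / r1$launched_weight, 1e-9)
})

test_that("doubling absorption strictly decreases detected weight", {
  m <- build_finger_model(tab, 1684, 2)
  m2 <- m
  m2$layers$mu_a <- 2 * m$layers$mu_a
  g <- sensor_geometry(separation = 1)
  cfg <- transport_config(n_photons = 1e5, seed = 21)
  expect_lt(run_simulation(m2, g, cfg)$detected_weight,
            run_simulation(m, g, cfg)$detected_weight)
})

test_that("detected power falls with source-detector separation", {
  cfg <- transport_config(n_photons = 2e5, seed = 31)
  for (wl in c(1684, 1920)) {
    m <- build_finger_model(tab, wl, 2)
    p_near <- run_simulation(m, sensor_geometry(separation = 0.7),
                             cfg)$detected_weight
    p_far <- run_simulation(m, sensor_geometry(separation = 1.5),
                            cfg)$detected_weight
    expect_lt(p_far, p_near)
  }
})

test_that("degenerate media and event maps behave as documented", {
  layers <- data.frame(name = "void", z_top = 0, z_bottom = 1,
                       mu_a = 0, mu_s = 0)
  void <- tissue_model(layers, g = 0, n_tissue = 1, n_external = 1)
  expect_error(run_simulation(void, sensor_geometry(),
                              transport_config(n_photons = 10)),
               "degenerate")

  m <- build_finger_model(tab, 1684, 2)
  res <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 2e4, seed = 8,
                                         record_map = TRUE,
                                         map_voxel_mm = 0.05))
  expect_false(is.null(res$event_map))
  expect_equal(length(dim(res$event_map)), 3L)
  expect_gt(sum(res$event_map), 0)
  # detected-photon-only map: total events bounded by detected event counts
  expect_lte(sum(res$event_map), sum(res$n_events))
  # all-photon map accumulates strictly more events
  res_all <- run_simulation(m, sensor_geometry(separation = 1),
                            transport_config(n_photons = 2e4, seed = 8,
                                             record_map = TRUE,
                                             map_voxel_mm = 0.05,
                                             map_all_photons = TRUE))
  expect_gt(sum(res_all$event_map), sum(res$event_map))
})

test_that("per-layer pathlengths are consistent with detection depth", {
  m <- build_finger_model(tab, 1684, 2)
  res <- run_simulation(m, sensor_geometry(separation = 1),
                        transport_config(n_photons = 5e4, seed = 13))
  pl <- res$path_lengths
  expect_equal(ncol(pl), 7L)
  expect_true(all(pl >= 0))
  # every detected photon crossed the full stratum corneum at least twice
  expect_true(all(pl[, 1] >= 2 * 0.02 - 1e-9))
  # a photon's deepest layer must have non-zero pathlength
  deepest <- layer_at_depth(m, pmin(res$max_depths, m$total_depth))
  expect_true(all(pl[cbind(seq_len(nrow(pl)), deepest)] > 0))
})
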