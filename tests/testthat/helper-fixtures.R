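# Shared fixtures and frozen oracle values.

# Total diffuse reflectance of a semi-infinite isotropic albedo-0.9 medium
# with matched boundaries (normal-incidence pencil beam). Computed with the
# independent unweighted brute-force sampler (1e6 photons) before the engine
# was built, and cross-checked against the H-function closed form
# 1 - H(1) * sqrt(1 - albedo) = 0.41506 (H(1) = 1.84969 at albedo 0.9).
FROZEN_ALBEDO09_REFLECTANCE <- 0.415066
FROZEN_ALBEDO09_SE <- 4.93e-4

# full-surface capture geometry: ring of radius 0 with a huge half-width
full_surface_geometry <- function(radius = 1e7) {
  sensor_geometry(detector_radius = radius, separation = 0)
}

# weight-based standard error of a detected fraction
detected_fraction_se <- function(result) {
  n <- result$n_photons
  m <- result$detected_weight / n
  sqrt(max(sum(result$exit_weights^2) / n - m^2, 0) / n)
}

# weighted mean depth and its (effective-sample-size) standard error
weighted_depth_se <- function(result) {
  w <- result$exit_weights / sum(result$exit_weights)
  m <- sum(w * result$max_depths)
  sqrt(sum(w^2 * (result$max_depths - m)^2))
}
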