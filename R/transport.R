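#' Transport configuration
#'
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer RNG seed for the engine's own generator (independent of
#'   R's RNG state).
#' @param weight_threshold Packet weight below which Russian roulette is
#'   played; set to 0 to disable roulette (exact energy bookkeeping).
#' @param roulette_survival Survival probability of the roulette; survivors
#'   have their weight divided by it, keeping termination unbiased.
#' @param max_events Safety cap on interaction events per packet; packets
#'   reaching it are terminated and their residual weight pooled separately.
#'   A warning is raised when more than 0.1\% of packets hit the cap.
#' @param record_map Record the 3-D interaction-event map.
#' @param map_voxel_mm Event-map voxel edge, mm.
#' @param map_bounds Event-map bounds, list with \code{lo} and \code{hi}
#'   numeric length-3 vectors (x, y, z in mm). \code{NULL} chooses a region
#'   covering the source-detector span and the superficial 2 mm of tissue.
#' @param map_all_photons Accumulate events from every packet instead of
#'   detected packets only.
#' @param beam_profile \code{"gaussian"} (1/e^2 radius, truncated at two
#'   radii) or \code{"flat"} (uniform disk).
#' @param n_chunks Number of independent worker streams; photons are split
#'   across chunks with seeds derived from \code{seed}. Results are
#'   reproducible for a fixed chunk count.
#' @return A list of class \code{"transport_config"}.
#' @export
transport_config <- function(n_photons = 1e5, seed = 1L,
                             weight_threshold = 1e-4, roulette_survival = 0.1,
                             max_events = 1e5, record_map = FALSE,
                             map_voxel_mm = 0.02, map_bounds = NULL,
                             map_all_photons = FALSE,
                             beam_profile = c("gaussian", "flat"),
                             n_chunks = 1L) {
  beam_profile <- match.arg(beam_profile)
  stopifnot(n_photons >= 1, weight_threshold >= 0, weight_threshold < 1,
            roulette_survival > 0, roulette_survival <= 1,
            max_events >= 1, map_voxel_mm > 0, n_chunks >= 1)
  cfg <- list(n_photons = n_photons, seed = as.integer(seed),
              weight_threshold = weight_threshold,
              roulette_survival = roulette_survival,
              max_events = max_events, record_map = record_map,
              map_voxel_mm = map_voxel_mm, map_bounds = map_bounds,
              map_all_photons = map_all_photons,
              beam_profile = beam_profile, n_chunks = as.integer(n_chunks))
  class(cfg) <- "transport_config"
  cfg
}

#' Run the weighted-photon Monte Carlo simulation
#'
#' Propagates photon packets through the layered model under implicit
#' capture: each interaction deposits the fraction \code{mu_a / (mu_a + mu_s)}
#' of the packet weight and redirects the remainder by Henyey-Greenstein
#' scattering. Sampled steps are clipped at layer interfaces and continue
#' with the remaining dimensionless optical path, so layer-dependent
#' interaction coefficients are handled exactly. The air-tissue surface
#' refracts/reflects by the unpolarized Fresnel equations (total internal
#' reflection beyond the critical angle); internal interfaces are
#' index-matched. Packets exiting through the lateral faces or the bottom are
#' pooled into the escaped budget.
#'
#' @param model A \code{"layered_tissue_model"}.
#' @param geometry A [sensor_geometry()].
#' @param config A [transport_config()].
#' @return A list of class \code{"simulation_result"} with weight budgets
#'   (\code{incident_weight}, \code{launched_weight}, \code{detected_weight},
#'   \code{absorbed_weight}, \code{escaped_*}, \code{roulette_lost_weight},
#'   \code{cap_lost_weight}), per-detected-packet records (\code{exit_x},
#'   \code{exit_y}, \code{exit_weights}, \code{max_depths}, \code{n_events}),
#'   the optional \code{event_map} with its \code{map_info}, and a
#'   \code{config_echo}.
#' @export
run_simulation <- function(model, geometry, config = transport_config()) {
  stopifnot(inherits(model, "layered_tissue_model"),
            inherits(geometry, "sensor_geometry"),
            inherits(config, "transport_config"))
  L <- model$layers
  if (any(L$mu_a + L$mu_s <= 0))
    stop("degenerate medium: layer with mu_a + mu_s = 0 cannot transport photons")
  bounds <- config$map_bounds
  if (is.null(bounds))
    bounds <- list(lo = c(-1.5, -1, 0),
                   hi = c(geometry$separation + 1.5, 1, 2))
  raw <- .mc_run_cpp(
    L$z_top, L$z_bottom, L$mu_a, L$mu_s,
    model$g, model$n_tissue, model$n_external,
    model$lateral_mm / 2, model$total_depth,
    geometry$source_radius, geometry$detector_radius, geometry$separation,
    identical(geometry$detector_shape, "ring"),
    geometry$beam_center[1], geometry$beam_center[2],
    config$beam_profile == "flat",
    config$n_photons, config$seed, config$n_chunks,
    config$weight_threshold, config$roulette_survival, config$max_events,
    config$record_map, config$map_all_photons,
    bounds$lo, bounds$hi, config$map_voxel_mm)
  raw$escaped_other_weight <- raw$escaped_surface_weight +
    raw$escaped_lateral_weight + raw$escaped_bottom_weight
  raw$path_lengths <- matrix(raw$path_lengths, ncol = nrow(L), byrow = TRUE,
                             dimnames = list(NULL, L$name))
  if (raw$n_capped > 0.001 * config$n_photons)
    warning(sprintf("event cap reached by %.2f%% of packets",
                    100 * raw$n_capped / config$n_photons))
  raw$map_info <- if (config$record_map)
    list(lo = bounds$lo, hi = bounds$hi, voxel = config$map_voxel_mm)
  raw$config_echo <- list(config = config, geometry = geometry,
                          model_summary = list(
                            wavelength = model$wavelength,
                            c_lactate = model$c_lactate,
                            n_layers = nrow(L),
                            total_depth = model$total_depth))
  class(raw) <- "simulation_result"
  raw
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation: %g packets, %g detected\n  detected %.4g / absorbed %.4g / escaped %.4g of incident weight\n",
    x$n_photons, x$n_detected, x$detected_weight / x$incident_weight,
    x$absorbed_weight / x$incident_weight,
    x$escaped_other_weight / x$incident_weight))
  invisible(x)
}

# ---- Reference step physics (pure R, used for unit-level validation) -------

#' Sample launch positions and initial weight of the source beam
#'
#' Positions are drawn from a circular Gaussian whose 1/e^2 intensity radius
#' equals \code{source_radius}, truncated at two radii; incidence is normal.
#' The initial packet weight is reduced by the normal-incidence specular
#' reflectance \code{((n_tissue - n_external) / (n_tissue + n_external))^2}.
#' Uses R's RNG (these reference functions validate the physics of the
#' compiled engine, which carries its own generator).
#'
#' @param n Number of samples.
#' @param geometry A [sensor_geometry()].
#' @param n_tissue,n_external Refractive indices.
#' @param profile \code{"gaussian"} or \code{"flat"}.
#' @return List with matrix \code{position} (n x 2), \code{direction}
#'   (0, 0, 1) and scalar \code{weight}.
#' @export
sample_launch <- function(n, geometry = sensor_geometry(),
                          n_tissue = 1.4, n_external = 1.0,
                          profile = c("gaussian", "flat")) {
  profile <- match.arg(profile)
  r0 <- geometry$source_radius
  if (profile == "flat") {
    r <- r0 * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    xy <- cbind(r * cos(a), r * sin(a))
  } else {
    sigma <- r0 / 2
    xy <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    while (length(need)) {
      cand <- matrix(stats::rnorm(2 * length(need), sd = sigma), ncol = 2)
      ok <- rowSums(cand^2) <= (2 * r0)^2
      take <- which(ok)
      if (length(take)) {
        xy[need[seq_along(take)], ] <- cand[take, , drop = FALSE]
        need <- need[-seq_along(take)]
      }
    }
  }
  xy <- sweep(xy, 2, geometry$beam_center, "+")
  r_spec <- ((n_tissue - n_external) / (n_tissue + n_external))^2
  list(position = xy, direction = c(0, 0, 1), weight = 1 - r_spec)
}

#' Sample exponential free path lengths
#'
#' Inverse-CDF sampling \code{-log(xi) / mu_t} with \code{xi} uniform(0, 1].
#'
#' @param n Number of draws.
#' @param mu_t Total interaction coefficient, mm^-1 (> 0).
#' @param xi Optional uniform variates (for the inverse-CDF identity checks).
#' @return Step lengths, mm.
#' @export
free_path <- function(n, mu_t, xi = NULL) {
  if (mu_t <= 0) stop("degenerate medium: mu_t must be positive")
  if (is.null(xi)) xi <- stats::runif(n)
  -log(xi) / mu_t
}

#' Implicit-capture weight deposit
#'
#' @param weight Packet weight(s).
#' @param mu_a,mu_s Layer coefficients, mm^-1, with \code{mu_a + mu_s > 0}.
#' @return List with \code{weight} (after deposit) and \code{deposited}.
#' @export
deposit_weight <- function(weight, mu_a, mu_s) {
  if (any(mu_a + mu_s <= 0)) stop("mu_a + mu_s must be positive")
  dep <- weight * mu_a / (mu_a + mu_s)
  list(weight = weight - dep, deposited = dep)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' @param n Number of draws.
#' @param g Anisotropy, |g| < 1. \code{g = 0} gives isotropic cosines.
#' @return Deflection cosines in [-1, 1].
#' @export
sample_hg_cosine <- function(n, g) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  u <- stats::runif(n)
  if (g == 0) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Scatter directions by the Henyey-Greenstein phase function
#'
#' @param n Number of draws.
#' @param g Anisotropy, |g| < 1.
#' @param direction Unit incoming direction (length 3).
#' @return An n x 3 matrix of unit outgoing directions.
#' @export
scatter_hg <- function(n, g, direction = c(0, 0, 1)) {
  direction <- direction / sqrt(sum(direction^2))
  ct <- sample_hg_cosine(n, g)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- stats::runif(n, 0, 2 * pi)
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  out <- matrix(NA_real_, n, 3)
  if (abs(uz) > 0.99999) {
    out[, 1] <- st * cos(phi)
    out[, 2] <- st * sin(phi)
    out[, 3] <- ct * sign(uz)
  } else {
    den <- sqrt(1 - uz^2)
    out[, 1] <- st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct
    out[, 2] <- st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct
    out[, 3] <- -den * st * cos(phi) + uz * ct
  }
  out / sqrt(rowSums(out^2))
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' @param cos_theta Cosine(s) of the incidence angle in medium 1.
#' @param n1,n2 Refractive indices of the incidence and transmission media.
#' @return Reflectance in [0, 1]; 1 beyond the critical angle.
#' @export
fresnel_reflectance <- function(cos_theta, n1, n2) {
  sini <- sqrt(pmax(0, 1 - cos_theta^2))
  sint <- n1 / n2 * sini
  tir <- sint >= 1
  cost <- sqrt(pmax(0, 1 - pmin(sint, 1)^2))
  rs <- (n1 * cos_theta - n2 * cost) / (n1 * cos_theta + n2 * cost)
  rp <- (n1 * cost - n2 * cos_theta) / (n1 * cost + n2 * cos_theta)
  out <- 0.5 * (rs^2 + rp^2)
  out[tir] <- 1
  out
}

#' Sample surface escape of an upward packet at the air-tissue interface
#'
#' Beyond the critical angle the packet is always internally reflected;
#' otherwise it transmits with probability \code{1 - R_Fresnel} and leaves
#' with its full current weight.
#'
#' @param n Number of trials.
#' @param cos_theta Cosine of the incidence angle (upward z-component).
#' @param n_tissue,n_external Refractive indices.
#' @return Logical vector: \code{TRUE} if transmitted.
#' @export
surface_escape <- function(n, cos_theta, n_tissue = 1.4, n_external = 1.0) {
  R <- fresnel_reflectance(cos_theta, n_tissue, n_external)
  stats::runif(n) >= R
}

#' Detector hit test
#'
#' Boundary inclusive: an exit on the detector rim is detected. Follows the
#' geometry's \code{detector_shape} (ring by default; the disk form tests
#' \code{(x - d)^2 + y^2 <= detector_radius^2}).
#'
#' @param x,y Exit coordinates, mm.
#' @param geometry A [sensor_geometry()].
#' @return Logical vector.
#' @export
detect_exit <- function(x, y, geometry) {
  if (identical(geometry$detector_shape, "disk"))
    (x - geometry$separation)^2 + y^2 <= geometry$detector_radius^2
  else
    abs(sqrt(x^2 + y^2) - geometry$separation) <= geometry$detector_radius
}

#' Russian roulette of a low-weight packet
#'
#' With probability \code{survival} the packet survives with weight divided
#' by \code{survival}; otherwise its weight is set to zero. Unbiased in
#' expectation.
#'
#' @param weight Packet weight(s), assumed below the roulette threshold.
#' @param survival Survival probability in (0, 1].
#' @return Updated weight(s).
#' @export
roulette_weight <- function(weight, survival = 0.1) {
  stopifnot(survival > 0, survival <= 1)
  n <- length(weight)
  ifelse(stats::runif(n) < survival, weight / survival, 0)
}
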