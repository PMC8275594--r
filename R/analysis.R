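#' Mean penetration depth of detected photons
#'
#' The mean over detected photons of the maximum z-coordinate reached along
#' each photon's path. The default weights each detected packet by its exit
#' weight: under implicit capture a packet of weight w stands for w analog
#' (unweighted) photons, so the weight-averaged mean is the per-photon mean
#' an analog simulation would report. \code{weighted = FALSE} gives one vote
#' per detected packet instead.
#'
#' @param result A \code{"simulation_result"} (or any list carrying
#'   \code{max_depths} and \code{exit_weights}).
#' @param weighted Weight the mean by exit weights (default).
#' @return Depth in mm.
#' @export
mean_penetration_depth <- function(result, weighted = TRUE) {
  d <- result$max_depths
  if (length(d) == 0L)
    stop("insufficient statistics: 0 detected photons; increase n_photons")
  if (weighted) stats::weighted.mean(d, result$exit_weights) else mean(d)
}

#' Relative detected power
#'
#' Percentage of the incident (pre-specular) source power reaching the
#' detector. Equivalently, the mean detected intensity over the detector disk
#' times the detector area, divided by the input power; both formulations are
#' evaluated and asserted identical.
#'
#' @param result A \code{"simulation_result"}.
#' @return Percentage in [0, 100].
#' @export
relative_power <- function(result) {
  if (result$incident_weight <= 0) stop("no launched weight")
  direct <- result$detected_weight / result$incident_weight
  area <- pi * result$config_echo$geometry$detector_radius^2
  mean_intensity <- result$detected_weight / area
  via_intensity <- mean_intensity * area / result$incident_weight
  stopifnot(abs(direct - via_intensity) <= 1e-12 * max(direct, 1e-300))
  100 * direct
}

#' Weight-based standard error of the relative power
#'
#' Treats each launched packet's detected contribution (its exit weight, or
#' zero) as an i.i.d. draw.
#'
#' @param result A \code{"simulation_result"}.
#' @return Standard error of the relative power, percentage points.
#' @export
relative_power_se <- function(result) {
  n <- result$n_photons
  m <- result$detected_weight / n
  v <- sum(result$exit_weights^2) / n - m^2
  100 * sqrt(max(v, 0) / n)
}

#' Simulated absorbance
#'
#' \code{-log10(detected / incident)} in absorbance units. A simulation with
#' zero detected weight returns \code{Inf} with a diagnostic warning.
#'
#' @param result A \code{"simulation_result"}.
#' @return Absorbance, a.u.
#' @export
absorbance <- function(result) {
  frac <- result$detected_weight / result$incident_weight
  if (frac <= 0) {
    warning("zero detected weight: absorbance is infinite; increase n_photons")
    return(Inf)
  }
  -log10(frac)
}

#' Reweight a simulation result to perturbed absorption coefficients
#'
#' Exact likelihood-ratio reweighting for absorption-only perturbations:
#' because scattering coefficients do not depend on lactate, a path sampled
#' under the reference model remains a valid path under any lactate
#' concentration, and its detected weight transforms by
#' \code{exp(-sum_l delta_mua_l * L_l)} with \code{L_l} the packet's total
#' pathlength in layer l. This shares every path across concentrations, so
#' the tiny lactate-driven absorbance differences carry no extra Monte Carlo
#' noise at all.
#'
#' @param result A \code{"simulation_result"} run on the reference model.
#' @param delta_mua Per-layer absorption change (perturbed minus reference),
#'   mm^-1, length equal to the number of layers.
#' @return The result with \code{exit_weights} and \code{detected_weight}
#'   replaced by their reweighted values.
#' @export
reweight_result <- function(result, delta_mua) {
  stopifnot(length(delta_mua) == ncol(result$path_lengths))
  w <- result$exit_weights * exp(-drop(result$path_lengths %*% delta_mua))
  result$exit_weights <- w
  result$detected_weight <- sum(w)
  result
}

#' Sweep lactate concentration at fixed wavelength and separation
#'
#' One row per concentration. Two estimators are available.
#' \code{"perturbation"} (default) runs the engine once at the first
#' concentration and maps the detected packets to every other concentration
#' by the exact absorption reweighting of [reweight_result()] -- the
#' strongest form of common random numbers, with paths shared outright.
#' \code{"rerun"} launches an independent simulation per concentration with
#' a common engine seed, so paths stay paired (scattering is
#' lactate-independent) but slowly decorrelate as absorption perturbs the
#' sampled step lengths.
#'
#' @param table An \code{optical_property_table}.
#' @param wavelength Wavelength, nm.
#' @param separation Source-detector separation, mm.
#' @param c_list Lactate concentrations, mmol/L.
#' @param config A [transport_config()]; its seed is shared by every
#'   concentration.
#' @param geometry A [sensor_geometry()]; its separation is overridden by
#'   \code{separation}.
#' @param method \code{"perturbation"} or \code{"rerun"}.
#' @param ... Further arguments to [build_finger_model()].
#' @return A data frame with one row per concentration: \code{wavelength},
#'   \code{separation_d}, \code{c_lactate}, \code{relative_power_pct},
#'   \code{mean_penetration_depth}, \code{absorbance}, \code{n_detected},
#'   \code{se_power}.
#' @export
concentration_sweep <- function(table, wavelength, separation, c_list,
                                config = transport_config(),
                                geometry = sensor_geometry(),
                                method = c("perturbation", "rerun"), ...) {
  if (!length(c_list)) stop("c_list must be non-empty")
  method <- match.arg(method)
  geometry$separation <- separation
  if (method == "rerun") {
    rows <- lapply(c_list, function(cc) {
      model <- build_finger_model(table, wavelength, cc, ...)
      sweep_row(run_simulation(model, geometry, config))
    })
    return(do.call(rbind, rows))
  }
  ref <- build_finger_model(table, wavelength, c_list[1], ...)
  res <- run_simulation(ref, geometry, config)
  rows <- lapply(c_list, function(cc) {
    model <- build_finger_model(table, wavelength, cc, ...)
    r <- reweight_result(res, model$layers$mu_a - ref$layers$mu_a)
    r$config_echo$model_summary$c_lactate <- cc
    sweep_row(r)
  })
  do.call(rbind, rows)
}

sweep_row <- function(res) {
  s <- res$config_echo$model_summary
  data.frame(
    wavelength = s$wavelength,
    separation_d = res$config_echo$geometry$separation,
    c_lactate = s$c_lactate,
    relative_power_pct = relative_power(res),
    mean_penetration_depth = if (res$n_detected > 0)
      mean_penetration_depth(res) else NA_real_,
    absorbance = suppressWarnings(absorbance(res)),
    n_detected = res$n_detected,
    se_power = relative_power_se(res))
}

#' Sweep the wavelength-by-separation study grid
#'
#' One simulation per (wavelength, separation) cell at a fixed lactate
#' concentration. Cells receive independent seeds derived from
#' \code{config$seed}; within a later [concentration_sweep()] the seed is
#' common across concentrations instead.
#'
#' @param table An \code{optical_property_table}.
#' @param wavelengths,separations Grid axes (nm, mm); defaults are the full
#'   study grid (all table wavelengths at 0.7, 1 and 1.5 mm).
#' @param c_lactate Lactate concentration, mmol/L.
#' @param config A [transport_config()].
#' @param geometry A [sensor_geometry()] providing radii.
#' @param ... Further arguments to [build_finger_model()].
#' @return A data frame of sweep rows (see [concentration_sweep()]).
#' @export
grid_sweep <- function(table, wavelengths = NULL,
                       separations = c(0.7, 1.0, 1.5), c_lactate = 2,
                       config = transport_config(),
                       geometry = sensor_geometry(), ...) {
  if (is.null(wavelengths)) wavelengths <- table$wavelength_nm
  cells <- expand.grid(wavelength = wavelengths, separation = separations)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    geom <- geometry
    geom$separation <- cells$separation[i]
    model <- build_finger_model(table, cells$wavelength[i], c_lactate, ...)
    sweep_row(run_simulation(model, geom, cfg))
  })
  do.call(rbind, rows)
}

# deterministic 31-bit stream seeds for grid cells
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1000003) %% 2147483647)
}

#' Min-max normalization of an absorbance curve
#'
#' @param a Absorbances over a concentration range (length >= 2).
#' @return Values rescaled to [0, 1]; a constant curve returns all zeros (the
#'   flat-curve sentinel).
#' @export
normalize_absorbance <- function(a) {
  if (length(a) < 2L) stop("need at least two concentrations to normalize")
  rng <- range(a)
  if (diff(rng) == 0) return(rep(0, length(a)))
  (a - rng[1]) / diff(rng)
}

#' Write sweep rows and a run manifest
#'
#' The rows go to comma-separated text; a JSON manifest alongside echoes the
#' configuration and seeds.
#'
#' @param rows A sweep data frame.
#' @param path Output CSV path; the manifest is written next to it with
#'   extension \code{.manifest.json}.
#' @param config The [transport_config()] used.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(rows, path, config = NULL) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  manifest <- list(created = format(Sys.time(), tz = "UTC"),
                   n_rows = nrow(rows),
                   config = config)
  jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Write a simulation result as portable text datasets
#'
#' Writes per-photon records (\code{max_depths.csv}, \code{exit_weights.csv}
#' combined into \code{records.csv}), the non-zero voxels of the event map
#' (\code{event_map.csv} with integer voxel indices and counts), and a JSON
#' manifest echoing the configuration and weight budgets.
#'
#' @param result A \code{"simulation_result"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(exit_x = result$exit_x, exit_y = result$exit_y,
               exit_weight = result$exit_weights,
               max_depth = result$max_depths, n_events = result$n_events),
    file.path(dir, "records.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(result$event_map)) {
    nz <- which(result$event_map > 0, arr.ind = TRUE)
    utils::write.csv(
      data.frame(ix = nz[, 1], iy = nz[, 2], iz = nz[, 3],
                 count = result$event_map[nz]),
      file.path(dir, "event_map.csv"), row.names = FALSE, quote = FALSE)
  }
  budgets <- result[c("n_photons", "incident_weight", "launched_weight",
                      "detected_weight", "absorbed_weight",
                      "escaped_surface_weight", "escaped_lateral_weight",
                      "escaped_bottom_weight", "roulette_lost_weight",
                      "cap_lost_weight", "n_detected")]
  jsonlite::write_json(
    list(budgets = budgets, map_info = result$map_info,
         config = result$config_echo),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  invisible(dir)
}
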