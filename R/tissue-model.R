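#' Default finger layer specification
#'
#' The layered finger model: two bloodless superficial layers (stratum
#' corneum, epidermis), four dermal sublayers that differ in blood and water
#' content, and hypodermal fat filling the slab down to the full tissue depth.
#' Papillary-dermis sublayer thicknesses and blood/water fractions follow the
#' standard multilayer skin model; the stratum corneum (0.02 mm) and epidermis
#' (0.25 mm) thicknesses place the papillary dermis at 0.27--0.37 mm depth.
#' The hypodermis is assigned 5% blood and 70% water, the usual values for
#' subcutaneous fat in multilayer skin models. All entries are overridable.
#'
#' @return A data frame with columns \code{name}, \code{thickness_mm}
#'   (\code{NA} for the terminal layer, which extends to the model depth),
#'   \code{v_blood}, \code{v_water}, \code{v_melanin}, \code{scatter_class}.
#' @export
finger_layer_spec <- function() {
  data.frame(
    name = c("stratum_corneum", "epidermis", "papillary_dermis",
             "upper_blood_net_dermis", "reticular_dermis",
             "deep_blood_net_dermis", "hypodermal_fat"),
    thickness_mm = c(0.02, 0.25, 0.10, 0.08, 0.20, 0.30, NA),
    v_blood      = c(0.00, 0.00, 0.04, 0.30, 0.04, 0.10, 0.05),
    v_water      = c(0.05, 0.20, 0.50, 0.60, 0.70, 0.70, 0.70),
    v_melanin    = c(0.00, 0.02, 0.00, 0.00, 0.00, 0.00, 0.00),
    scatter_class = c("skin", "skin", "skin", "skin", "skin", "skin", "fat")
  )
}

#' Sensor geometry in reflectance mode
#'
#' A Gaussian source beam centered at the origin pointing into the tissue and
#' a detector on the surface at center-to-center separation \code{d} along
#' +x. Radii in mm; the source radius is the 1/e^2 intensity radius.
#'
#' Detection comes in two shapes. \code{"ring"} (the default) collects every
#' exit whose radial distance from the beam axis lies within
#' \code{detector_radius} of \code{separation} -- the azimuthally integrated
#' scoring natural to this cylindrically symmetric geometry, and the one
#' under which the detected powers are on the scale of the study's reported
#' values. \code{"disk"} restricts collection to the physical detector disk
#' centered at \code{(separation, 0)}; it measures the same mean intensity
#' but collects the azimuthal fraction \code{area_disk / area_ring} of the
#' ring's power. Both are boundary inclusive.
#'
#' @param source_radius Beam 1/e^2 radius, mm.
#' @param detector_radius Detector radius (ring half-width), mm.
#' @param separation Center-to-center source-detector separation, mm.
#' @param detector_shape \code{"ring"} or \code{"disk"}.
#' @param beam_center Beam center (x, y), mm; non-zero values are used by the
#'   symmetry fixtures.
#' @return A list of class \code{"sensor_geometry"}.
#' @export
sensor_geometry <- function(source_radius = 0.1, detector_radius = 0.2,
                            separation = 1.0,
                            detector_shape = c("ring", "disk"),
                            beam_center = c(0, 0)) {
  detector_shape <- match.arg(detector_shape)
  stopifnot(source_radius > 0, detector_radius > 0, separation >= 0,
            length(beam_center) == 2L)
  g <- list(source_radius = source_radius, detector_radius = detector_radius,
            separation = separation, detector_shape = detector_shape,
            beam_center = as.numeric(beam_center))
  class(g) <- "sensor_geometry"
  g
}

#' Low-level layered tissue model constructor
#'
#' Builds a model from a layer table with resolved optical coefficients.
#' [build_finger_model()] is the high-level entry point; this constructor is
#' also used directly by the degenerate validation fixtures, which need
#' non-anatomical slabs (e.g. matched-boundary pure absorbers).
#'
#' @param layers Data frame with columns \code{name}, \code{z_top},
#'   \code{z_bottom}, \code{mu_a}, \code{mu_s} (mm and mm^-1).
#' @param g Scattering anisotropy, in (-1, 1), uniform across layers.
#' @param n_tissue,n_external Refractive indices of tissue and the external
#'   medium; equal values give matched (non-refracting) boundaries.
#' @param lateral_mm Lateral extent (width = thickness) of the slab, mm.
#' @param wavelength,c_lactate Optional metadata echoed in results.
#' @return A list of class \code{"layered_tissue_model"}.
#' @export
tissue_model <- function(layers, g = 0.9, n_tissue = 1.4, n_external = 1.0,
                         lateral_mm = 13, wavelength = NA_real_,
                         c_lactate = NA_real_) {
  stopifnot(is.data.frame(layers),
            all(c("name", "z_top", "z_bottom", "mu_a", "mu_s") %in% names(layers)))
  if (any(layers$mu_a < 0) || any(layers$mu_s < 0))
    stop("mu_a and mu_s must be non-negative")
  if (any(layers$z_bottom <= layers$z_top))
    stop("layer thicknesses must be positive")
  if (nrow(layers) > 1L &&
      any(abs(layers$z_top[-1L] - layers$z_bottom[-nrow(layers)]) > 1e-12))
    stop("layer intervals must partition the depth without gaps")
  if (abs(layers$z_top[1L]) > 1e-12) stop("first layer must start at z = 0")
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  if (n_tissue < 1 || n_external < 1) stop("refractive indices must be >= 1")
  m <- list(layers = layers, g = g, n_tissue = n_tissue,
            n_external = n_external, lateral_mm = lateral_mm,
            total_depth = layers$z_bottom[nrow(layers)],
            wavelength = wavelength, c_lactate = c_lactate)
  class(m) <- "layered_tissue_model"
  m
}

#' Build the layered finger model at a wavelength and lactate concentration
#'
#' Resolves each layer's absorption coefficient from its chromophore volume
#' fractions via [layer_absorption()] and its scattering coefficient from the
#' skin or fat column of the property table. The air-tissue surface is the
#' only refracting interface; internal interfaces are index-matched.
#'
#' @param table An \code{optical_property_table}.
#' @param wavelength Wavelength in nm; must be present in the table.
#' @param c_lactate Blood-lactate concentration, mmol/L.
#' @param layers Layer specification as from [finger_layer_spec()]; override
#'   rows to change anatomy.
#' @param v_lipid_blood Lipid volume fraction in blood (default 0.01).
#' @param c_ref Lactate reference concentration, mmol/L (default 100).
#' @param g,n_tissue,n_external Optical constants applied to every layer.
#' @param total_depth_mm,lateral_mm Slab depth and lateral extent, mm.
#' @param baseline_constant,baseline_exponent Passed to
#'   [baseline_absorption()].
#' @param interpolate Passed to [property_record()].
#' @return A \code{"layered_tissue_model"}.
#' @examples
#' m <- build_finger_model(swir_property_table(), 1684, 2)
#' m$layers$mu_s[m$layers$name == "papillary_dermis"]  # 3.14
#' @export
build_finger_model <- function(table, wavelength, c_lactate,
                               layers = finger_layer_spec(),
                               v_lipid_blood = 0.01, c_ref = 100,
                               g = 0.9, n_tissue = 1.4, n_external = 1.0,
                               total_depth_mm = 13, lateral_mm = 13,
                               baseline_constant = 7.84e8,
                               baseline_exponent = -3.255,
                               interpolate = FALSE) {
  if (c_lactate < 0) stop("c_lactate must be non-negative")
  rec <- property_record(table, wavelength, interpolate = interpolate)
  v_lact <- lactate_volume_fraction(c_lactate, c_ref)
  if (v_lact > 1) stop("c_lactate exceeds the reference concentration")
  base <- baseline_absorption(rec$wavelength_nm, baseline_constant,
                              baseline_exponent)
  if (!all(layers$scatter_class %in% c("skin", "fat")))
    stop("scatter_class must be 'skin' or 'fat'")
  if (anyNA(layers$thickness_mm[-nrow(layers)]) || sum(is.na(layers$thickness_mm)) > 1L)
    stop("only the terminal layer may have NA thickness")

  thick <- layers$thickness_mm
  finite_sum <- sum(thick, na.rm = TRUE)
  if (is.na(thick[length(thick)])) {
    if (finite_sum >= total_depth_mm)
      stop("finite layer thicknesses exceed the total model depth")
    thick[length(thick)] <- total_depth_mm - finite_sum
  } else if (abs(finite_sum - total_depth_mm) > 1e-9) {
    stop("layer thicknesses must sum to the total model depth")
  }
  z_bottom <- cumsum(thick)
  z_top <- c(0, z_bottom[-length(z_bottom)])

  mu_a <- vapply(seq_len(nrow(layers)), function(i) {
    fr <- chromophore_fractions(
      v_blood = layers$v_blood[i], v_water = layers$v_water[i],
      v_melanin = layers$v_melanin[i], v_lipid_blood = v_lipid_blood,
      v_lactate = v_lact)
    layer_absorption(fr, rec, baseline = base)
  }, numeric(1))
  mu_s <- ifelse(layers$scatter_class == "fat", rec$mus_fat, rec$mus_skin)

  resolved <- data.frame(
    name = layers$name, z_top = z_top, z_bottom = z_bottom,
    thickness_mm = thick, v_blood = layers$v_blood, v_water = layers$v_water,
    v_melanin = layers$v_melanin, scatter_class = layers$scatter_class,
    mu_a = mu_a, mu_s = mu_s)
  tissue_model(resolved, g = g, n_tissue = n_tissue, n_external = n_external,
               lateral_mm = lateral_mm, wavelength = rec$wavelength_nm,
               c_lactate = c_lactate)
}

#' Index of the layer containing a depth
#'
#' Layer intervals are half-open \code{[z_top, z_bottom)}; the model's bottom
#' depth maps to the terminal layer.
#'
#' @param model A \code{"layered_tissue_model"}.
#' @param z Depth(s) in mm, each in \code{[0, total_depth]}.
#' @return Integer layer indices (1-based).
#' @export
layer_at_depth <- function(model, z) {
  if (any(z < 0 | z > model$total_depth))
    stop("depth outside the tissue slab [0, ", model$total_depth, "] mm")
  idx <- findInterval(z, c(model$layers$z_top, model$total_depth),
                      rightmost.closed = TRUE)
  pmin(idx, nrow(model$layers))
}

#' @export
print.layered_tissue_model <- function(x, ...) {
  cat(sprintf(
    "Layered tissue model: %d layers, depth %g mm, lateral %g mm\n",
    nrow(x$layers), x$total_depth, x$lateral_mm))
  if (!is.na(x$wavelength))
    cat(sprintf("  wavelength %g nm, C_lact %g mmol/L\n", x$wavelength, x$c_lactate))
  cat(sprintf("  g = %g, n_tissue = %g, n_external = %g\n",
              x$g, x$n_tissue, x$n_external))
  print(x$layers[, c("name", "z_top", "z_bottom", "mu_a", "mu_s")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read or write a tissue model configuration
#'
#' YAML with per-layer blocks (\code{name}, \code{thickness_mm},
#' \code{v_blood}, \code{v_water}, \code{v_melanin}, \code{scatter_class})
#' and a \code{global} block (\code{g}, \code{n_tissue}, \code{n_external},
#' \code{total_depth_mm}, \code{lateral_mm}). The packaged default
#' (\code{inst/extdata/finger_model.yaml}) encodes the study's finger stack.
#'
#' @param path File path.
#' @param layers Layer specification data frame.
#' @param global Named list of global entries.
#' @return \code{read_model_config} returns
#'   \code{list(layers = <data frame>, global = <list>)}.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- do.call(rbind, lapply(cfg$layers, function(l) {
    data.frame(name = l$name,
               thickness_mm = if (is.null(l$thickness_mm)) NA_real_ else l$thickness_mm,
               v_blood = l$v_blood, v_water = l$v_water,
               v_melanin = if (is.null(l$v_melanin)) 0 else l$v_melanin,
               scatter_class = l$scatter_class)
  }))
  list(layers = layers, global = cfg$global)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(layers, global, path) {
  layer_list <- lapply(seq_len(nrow(layers)), function(i) {
    l <- as.list(layers[i, ])
    if (is.na(l$thickness_mm)) l$thickness_mm <- NULL
    l
  })
  yaml::write_yaml(list(layers = layer_list, global = global), path)
  invisible(path)
}
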