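# Degenerate media with known transport answers. Every oracle value here is
# produced by closed form or by the unweighted brute-force sampler below --
# never by the compiled engine these fixtures exist to validate.

#' Pure-absorber slab fixture
#'
#' A single matched-boundary layer with no scattering. Photons travel
#' ballistically, so the fraction leaving the bottom is the Beer-Lambert
#' transmittance \code{exp(-mu_a * thickness)} -- the closed-form oracle.
#'
#' @param mu_a Absorption coefficient, mm^-1 (> 0).
#' @param thickness Slab thickness, mm.
#' @return List of class \code{"analytic_fixture"} with the degenerate
#'   \code{model}, \code{oracle_kind = "beer_lambert"}, \code{oracle_value}
#'   and \code{tolerance_policy}.
#' @export
make_pure_absorber_slab <- function(mu_a, thickness) {
  stopifnot(mu_a > 0, thickness > 0)
  layers <- data.frame(name = "absorber", z_top = 0, z_bottom = thickness,
                       mu_a = mu_a, mu_s = 0)
  model <- tissue_model(layers, g = 0, n_tissue = 1, n_external = 1,
                        lateral_mm = 1e6)
  structure(list(model = model, oracle_kind = "beer_lambert",
                 oracle_value = exp(-mu_a * thickness),
                 tolerance_policy = "3 MC standard errors"),
            class = "analytic_fixture")
}

#' Semi-infinite homogeneous medium fixture
#'
#' One effectively infinite matched-boundary layer with single-scattering
#' albedo \code{mu_s / (mu_a + mu_s)}. The oracle is the total diffuse
#' reflectance from the independent unweighted sampler
#' [albedo_reflectance_bruteforce()]; for the standard isotropic albedo-0.9
#' case the frozen value is 0.41507 (which agrees with the H-function closed
#' form \code{1 - H(1) * sqrt(1 - albedo)} to five decimals).
#'
#' @param albedo Single-scattering albedo in (0, 1).
#' @param g Anisotropy.
#' @param mu_t Total interaction coefficient, mm^-1 (sets the length scale
#'   only).
#' @param oracle_value Frozen oracle reflectance; \code{NULL} leaves it unset
#'   for the caller to compute with the brute-force sampler.
#' @return An \code{"analytic_fixture"}.
#' @export
make_semiinfinite_medium <- function(albedo, g = 0, mu_t = 1,
                                     oracle_value = NULL) {
  stopifnot(albedo > 0, albedo < 1, mu_t > 0)
  depth <- 2000 / (mu_t * (1 - albedo))  # thousands of absorption lengths
  layers <- data.frame(name = "bulk", z_top = 0, z_bottom = depth,
                       mu_a = (1 - albedo) * mu_t, mu_s = albedo * mu_t)
  model <- tissue_model(layers, g = g, n_tissue = 1, n_external = 1,
                        lateral_mm = 2 * depth)
  structure(list(model = model, oracle_kind = "semi_infinite_albedo",
                 oracle_value = oracle_value,
                 tolerance_policy = "combined 3 SE of oracle and engine runs"),
            class = "analytic_fixture")
}

#' Independent unweighted brute-force reflectance sampler
#'
#' Analog (unweighted) Monte Carlo for a semi-infinite homogeneous medium
#' with matched boundaries and a normally incident pencil beam: every
#' interaction absorbs the photon with probability \code{1 - albedo},
#' otherwise redirects it by the Henyey-Greenstein phase function
#' (isotropically for \code{g = 0}). Implemented in vectorized R on R's own
#' RNG -- fully independent of the compiled weighted engine, for which it
#' serves as the reference.
#'
#' @param albedo Single-scattering albedo in (0, 1).
#' @param g Anisotropy.
#' @param n_photons Number of photons.
#' @param seed R RNG seed.
#' @return List with the reflectance estimate \code{value} and its binomial
#'   \code{se}.
#' @export
albedo_reflectance_bruteforce <- function(albedo, g = 0, n_photons = 1e5,
                                          seed = 1) {
  stopifnot(albedo > 0, albedo < 1)
  set.seed(seed)
  z <- numeric(n_photons)
  uz <- rep(1, n_photons)
  alive <- rep(TRUE, n_photons)
  refl <- 0L
  while (any(alive)) {
    idx <- which(alive)
    s <- stats::rexp(length(idx))  # mu_t = 1 units
    znew <- z[idx] + uz[idx] * s
    esc <- znew < 0
    refl <- refl + sum(esc)
    alive[idx[esc]] <- FALSE
    surv <- idx[!esc]
    z[surv] <- znew[!esc]
    dead <- stats::runif(length(surv)) > albedo
    alive[surv[dead]] <- FALSE
    sc <- surv[!dead]
    if (length(sc)) {
      ct <- sample_hg_cosine(length(sc), g)
      if (g == 0) {
        uz[sc] <- ct
      } else {
        # rotate each direction cosine; azimuth affects only x/y, so track
        # the polar cosine with a uniform-azimuth composition rule
        phi <- stats::runif(length(sc), 0, 2 * pi)
        st_old <- sqrt(pmax(0, 1 - uz[sc]^2))
        uz[sc] <- -st_old * sqrt(pmax(0, 1 - ct^2)) * cos(phi) + uz[sc] * ct
      }
    }
  }
  value <- refl / n_photons
  list(value = value, se = sqrt(value * (1 - value) / n_photons))
}

#' Azimuthal-symmetry fixture
#'
#' A centered normal-incidence beam on a laterally homogeneous layered slab
#' produces azimuthally uniform exit positions; exits falling in an annulus
#' of the source-detector radius are binned into sectors and tested against
#' uniformity by a chi-square test. Decentering the beam is the negative
#' control.
#'
#' @param table,wavelength,c_lactate Passed to [build_finger_model()].
#' @param ring_radius Annulus center radius, mm.
#' @param ring_halfwidth Annulus half-width, mm.
#' @param n_sectors Number of azimuthal sectors.
#' @return List of class \code{"analytic_fixture"} describing the check.
#' @export
symmetry_fixture <- function(table = swir_property_table(),
                             wavelength = 1684, c_lactate = 2,
                             ring_radius = 1.0, ring_halfwidth = 0.2,
                             n_sectors = 12) {
  model <- build_finger_model(table, wavelength, c_lactate)
  structure(list(model = model, oracle_kind = "symmetry",
                 oracle_value = NA_real_,
                 ring_radius = ring_radius, ring_halfwidth = ring_halfwidth,
                 n_sectors = n_sectors,
                 tolerance_policy = "chi-square uniformity, alpha = 0.01"),
            class = "analytic_fixture")
}

#' Run the azimuthal-symmetry check
#'
#' Captures every surface exit (full-surface detector), selects exits in the
#' fixture's annulus and chi-square-tests the sector counts for uniformity.
#'
#' @param fixture A [symmetry_fixture()].
#' @param n_photons Packets to launch.
#' @param seed Engine seed.
#' @param beam_offset Beam-center offset (x, y) in mm; non-zero values are
#'   the deliberate negative control.
#' @return List with \code{p_value}, sector \code{counts} and \code{n_ring}.
#' @export
run_symmetry_check <- function(fixture, n_photons = 1e5, seed = 1,
                               beam_offset = c(0, 0)) {
  geom <- sensor_geometry(detector_radius = fixture$model$lateral_mm,
                          separation = 0, beam_center = beam_offset)
  cfg <- transport_config(n_photons = n_photons, seed = seed)
  res <- run_simulation(fixture$model, geom, cfg)
  r <- sqrt(res$exit_x^2 + res$exit_y^2)
  in_ring <- abs(r - fixture$ring_radius) <= fixture$ring_halfwidth
  theta <- atan2(res$exit_y[in_ring], res$exit_x[in_ring])
  sector <- cut(theta, breaks = seq(-pi, pi, length.out = fixture$n_sectors + 1),
                include.lowest = TRUE)
  counts <- table(sector)
  test <- stats::chisq.test(as.numeric(counts))
  list(p_value = test$p.value, counts = as.numeric(counts),
       n_ring = sum(in_ring))
}
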