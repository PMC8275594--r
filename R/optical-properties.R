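#' Default SWIR optical property table
#'
#' Absorption coefficients of the four tissue chromophores (water, lactate,
#' lipid, melanin) and scattering coefficients of skin collagen and hypodermal
#' fat at the ten characterizing SWIR wavelengths used throughout the package.
#' The lactate coefficient \code{mua_lactate} is that of a 100 mmol/L aqueous
#' lactate solution at unit volume fraction, which fixes the reference
#' concentration used by [lactate_volume_fraction()].
#'
#' All coefficients are in mm^-1; wavelengths in nm, strictly increasing.
#'
#' @return A data frame of class \code{"optical_property_table"} with columns
#'   \code{wavelength_nm}, \code{mua_water}, \code{mua_lactate},
#'   \code{mua_lipid}, \code{mua_melanin}, \code{mus_skin}, \code{mus_fat}.
#' @examples
#' tab <- swir_property_table()
#' property_record(tab, 1684)$mua_water  # 0.45
#' @export
swir_property_table <- function() {
  tab <- data.frame(
    wavelength_nm = c(1310, 1550, 1650, 1684, 1730, 1752, 1920, 2129, 2259, 2299),
    mua_water     = c(0.12, 1.07, 0.48, 0.45, 0.61, 0.71, 11.45, 2.20, 1.72, 2.24),
    mua_lactate   = c(0.29, 0.33, 0.35, 0.37, 0.37, 0.35, 0.33, 0.43, 0.54, 0.58),
    mua_lipid     = c(0.18, 0.17, 0.15, 0.21, 0.42, 0.33, 0.50, 0.29, 0.29, 0.68),
    mua_melanin   = c(2.75, 1.57, 1.27, 1.19, 1.09, 1.04, 0.77, 0.54, 0.45, 0.42),
    mus_skin      = c(4.90, 3.62, 3.25, 3.14, 3.00, 2.94, 2.52, 2.13, 1.94, 1.88),
    mus_fat       = c(10.57, 9.63, 9.47, 9.76, 13.74, 11.89, 14.63, 11.79, 15.69, 22.56)
  )
  validate_property_table(tab)
}

property_table_columns <- function() {
  c("wavelength_nm", "mua_water", "mua_lactate", "mua_lipid",
    "mua_melanin", "mus_skin", "mus_fat")
}

validate_property_table <- function(tab) {
  cols <- property_table_columns()
  if (!all(cols %in% names(tab)))
    stop("property table must have columns: ", paste(cols, collapse = ", "))
  tab <- as.data.frame(tab)[cols]
  if (anyNA(tab)) stop("property table contains missing values")
  if (any(tab < 0)) stop("optical coefficients must be non-negative")
  wl <- tab$wavelength_nm
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelengths must be strictly increasing with no duplicates")
  class(tab) <- c("optical_property_table", "data.frame")
  tab
}

#' Read or write an optical property table
#'
#' Comma-separated text with the exact header
#' \code{wavelength_nm,mua_water,mua_lactate,mua_lipid,mua_melanin,mus_skin,mus_fat}.
#' The file shipped in \code{inst/extdata/swir_optical_properties.csv}
#' round-trips to [swir_property_table()].
#'
#' @param path File path.
#' @param table An \code{optical_property_table}.
#' @return \code{read_property_table} returns a validated table;
#'   \code{write_property_table} returns \code{path} invisibly.
#' @export
read_property_table <- function(path) {
  tab <- utils::read.csv(path, check.names = TRUE)
  validate_property_table(tab)
}

#' @rdname read_property_table
#' @export
write_property_table <- function(table, path) {
  table <- validate_property_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the coefficient record at one wavelength
#'
#' Exact-match lookup by default: the study is defined at ten discrete
#' wavelengths and no spectral interpolation is implied between them. For
#' synthetic tables a linear interpolation mode is available.
#'
#' @param table An \code{optical_property_table}.
#' @param wavelength Wavelength in nm.
#' @param interpolate If \code{TRUE}, linearly interpolate coefficients
#'   between bracketing rows (within the table range only). Default
#'   \code{FALSE}.
#' @return A one-row list-like record with the table's columns.
#' @examples
#' property_record(swir_property_table(), 1920)$mua_water  # 11.45
#' @export
property_record <- function(table, wavelength, interpolate = FALSE) {
  table <- validate_property_table(table)
  stopifnot(length(wavelength) == 1L, is.finite(wavelength))
  wl <- table$wavelength_nm
  i <- match(wavelength, wl)
  if (!is.na(i)) return(as.list(table[i, ]))
  if (!interpolate) {
    near <- wl[order(abs(wl - wavelength))][seq_len(min(2L, length(wl)))]
    stop(sprintf(
      "wavelength %g nm not in table; nearest available rows: %s nm",
      wavelength, paste(sort(near), collapse = ", ")))
  }
  if (wavelength < min(wl) || wavelength > max(wl))
    stop(sprintf("wavelength %g nm outside table range [%g, %g] nm",
                 wavelength, min(wl), max(wl)))
  out <- lapply(property_table_columns()[-1], function(col)
    stats::approx(wl, table[[col]], xout = wavelength)$y)
  names(out) <- property_table_columns()[-1]
  c(list(wavelength_nm = wavelength), out)
}

#' Baseline absorption of absorber-free tissue
#'
#' Power-law absorption of the tissue scaffold with no water, blood or other
#' chromophores: \code{constant * lambda^exponent}, with the wavelength in nm
#' and the result in mm^-1 (consistent with the units of the property table).
#' The constant and exponent are overridable.
#'
#' @param wavelength Wavelength in nm (vectorized, must be > 0).
#' @param constant,exponent Power-law parameters; defaults 7.84e8 and -3.255.
#' @return Baseline absorption coefficient(s), mm^-1.
#' @examples
#' baseline_absorption(1310)  # ~0.0559
#' @export
baseline_absorption <- function(wavelength, constant = 7.84e8, exponent = -3.255) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelength must be positive")
  constant * wavelength^exponent
}

#' Chromophore volume fractions of a tissue layer
#'
#' @param v_blood Blood volume fraction of the layer.
#' @param v_water Water volume fraction of the layer.
#' @param v_melanin Melanin volume fraction (non-zero only in the epidermis).
#' @param v_lipid_blood Lipid volume fraction within blood.
#' @param v_lactate Lactate volume fraction within blood (see
#'   [lactate_volume_fraction()]).
#' @return A list of class \code{"chromophore_fractions"}.
#' @export
chromophore_fractions <- function(v_blood = 0, v_water = 0, v_melanin = 0,
                                  v_lipid_blood = 0, v_lactate = 0) {
  f <- list(v_blood = v_blood, v_water = v_water, v_melanin = v_melanin,
            v_lipid_blood = v_lipid_blood, v_lactate = v_lactate)
  for (nm in names(f)) {
    v <- f[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(nm, " must be a single value in [0, 1]")
  }
  if (f$v_blood + f$v_water + f$v_melanin > 1)
    stop("v_blood + v_water + v_melanin exceeds 1; the baseline residual would be negative")
  class(f) <- "chromophore_fractions"
  f
}

#' Cumulative absorption coefficient of blood
#'
#' Blood absorption is composed from its lactate and lipid content:
#' \code{v_lactate * mua_lactate + v_lipid * mua_lipid}.
#'
#' @param v_lactate,v_lipid Volume fractions in blood, each in [0, 1].
#' @param record A record from [property_record()].
#' @return Absorption coefficient, mm^-1.
#' @examples
#' rec <- property_record(swir_property_table(), 2259)
#' blood_absorption(0.02, 0.01, rec)  # 0.0137
#' @export
blood_absorption <- function(v_lactate, v_lipid, record) {
  if (any(v_lactate < 0 | v_lactate > 1) || any(v_lipid < 0 | v_lipid > 1))
    stop("blood volume fractions must lie in [0, 1]")
  v_lactate * record$mua_lactate + v_lipid * record$mua_lipid
}

#' Cumulative absorption coefficient of a tissue layer
#'
#' Volume-fraction mixture of blood, water and the absorber-free baseline:
#' \deqn{\mu_{aT} = V_b \mu_{ab} + V_w \mu_{aw} + V_{mel}\mu_{amel}
#'       + [1 - (V_b + V_w + V_{mel})] \mu_{at}}
#' where \eqn{\mu_{ab}} comes from [blood_absorption()] and \eqn{\mu_{at}}
#' from [baseline_absorption()]. The melanin term applies only where
#' \code{v_melanin > 0} (the epidermis) and is charged against the baseline
#' residual so fractions never double-count volume.
#'
#' @param fractions A [chromophore_fractions()] object.
#' @param record A record from [property_record()].
#' @param baseline Baseline absorption at the record's wavelength; computed
#'   from [baseline_absorption()] by default.
#' @return Absorption coefficient, mm^-1.
#' @export
layer_absorption <- function(fractions, record,
                             baseline = baseline_absorption(record$wavelength_nm)) {
  if (!inherits(fractions, "chromophore_fractions"))
    fractions <- do.call(chromophore_fractions, fractions)
  f <- fractions
  mu_ab <- blood_absorption(f$v_lactate, f$v_lipid_blood, record)
  residual <- 1 - (f$v_blood + f$v_water + f$v_melanin)
  f$v_blood * mu_ab + f$v_water * record$mua_water +
    f$v_melanin * record$mua_melanin + residual * baseline
}

#' Convert a blood-lactate concentration to a volume fraction
#'
#' The lactate absorption coefficient in the property table is calibrated on a
#' 100 mmol/L in-vitro solution, so a physiological concentration maps
#' linearly onto the volume fraction \code{c_lactate / c_ref}.
#'
#' @param c_lactate Blood-lactate concentration, mmol/L (vectorized, >= 0).
#' @param c_ref Reference concentration of the calibration solution, mmol/L.
#' @return Dimensionless volume fraction.
#' @examples
#' lactate_volume_fraction(2)  # 0.02
#' @export
lactate_volume_fraction <- function(c_lactate, c_ref = 100) {
  if (any(!is.finite(c_lactate)) || any(c_lactate < 0))
    stop("c_lactate must be non-negative")
  if (c_ref <= 0) stop("c_ref must be positive")
  c_lactate / c_ref
}

#' Perturb a property table with multiplicative log-normal noise
#'
#' Generates synthetic tables with the spectral structure of the default one:
#' every coefficient is multiplied by an independent log-normal factor with
#' unit mean and the given coefficient of variation. Positivity and wavelength
#' ordering are preserved by construction.
#'
#' @param table An \code{optical_property_table}.
#' @param relative_noise Coefficient of variation of the factors, in [0, 0.5].
#' @param seed Integer RNG seed.
#' @return A perturbed \code{optical_property_table}.
#' @export
perturb_property_table <- function(table, relative_noise, seed) {
  table <- validate_property_table(table)
  if (relative_noise < 0 || relative_noise > 0.5)
    stop("relative_noise must lie in [0, 0.5]")
  if (relative_noise == 0) return(table)
  sdlog <- sqrt(log(1 + relative_noise^2))
  meanlog <- -sdlog^2 / 2  # unit-mean factors
  out <- table
  set.seed(seed)
  for (col in property_table_columns()[-1]) {
    n <- nrow(out)
    out[[col]] <- out[[col]] * stats::rlnorm(n, meanlog, sdlog)
  }
  validate_property_table(out)
}
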