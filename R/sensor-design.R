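#' Wavelength categories of the study grid
#'
#' The ten study wavelengths partition into lactate-peak, water-peak and
#' non-peak sets according to the in-vitro difference spectra.
#'
#' @return Named list of wavelength vectors (nm).
#' @export
wavelength_categories <- function() {
  list(lactate_peak = c(1684, 1730, 1752, 2129, 2259, 2299),
       water_peak = 1920,
       non_peak = c(1310, 1550, 1650))
}

#' Least-squares sensitivity slope of absorbance versus concentration
#'
#' Ordinary least squares from the closed-form normal equations (computed
#' from first principles rather than a fitting routine): slope
#' \code{Sxy / Sxx} and coefficient of determination \code{Sxy^2 / (Sxx Syy)}.
#' A constant response has slope 0 and, by convention, r^2 = 0.
#'
#' @param c_lactate Concentrations, mmol/L (length >= 3).
#' @param a Absorbances, a.u.
#' @return List with \code{slope} (a.u. per mmol/L) and \code{r2}.
#' @examples
#' sensitivity_slope(1:4, c(1, 2, 2, 3))  # slope 0.6, r2 0.9
#' @export
sensitivity_slope <- function(c_lactate, a) {
  if (length(c_lactate) < 3L || length(a) != length(c_lactate))
    stop("need at least 3 (concentration, absorbance) pairs")
  cx <- c_lactate - mean(c_lactate)
  cy <- a - mean(a)
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  if (sxx == 0) stop("concentrations are all equal")
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else sxy^2 / (sxx * syy)
  list(slope = slope, r2 = r2)
}

#' Score every (wavelength, separation) cell on the three design criteria
#'
#' A lactate sensor cell must (1) collect light that has sampled the
#' vascularized dermis rather than only the bloodless superficial layers
#' (\code{noise_ok}: mean penetration depth beyond the epidermis bottom),
#' (2) respond to concentration changes (\code{sensitivity}: absolute OLS
#' slope of absorbance versus concentration, with normalized absorbance
#' optional), and (3) return enough power to detect (\code{power_ok}:
#' relative power at least \code{power_threshold_pct}).
#'
#' @param rows Sweep rows covering at least 3 concentrations per
#'   (wavelength, separation) cell, as from [concentration_sweep()].
#' @param noise_depth_mm Depth of the bloodless-layer bottom, mm.
#' @param power_threshold_pct Minimum acceptable relative power, %.
#' @param use_normalized Fit the min-max-normalized absorbance instead of the
#'   raw curve.
#' @return Data frame with one row per cell: \code{wavelength},
#'   \code{separation_d}, \code{mean_depth_mm}, \code{mean_power_pct},
#'   \code{sensitivity}, \code{linearity_r2}, \code{noise_ok},
#'   \code{power_ok}. Cells with fewer than 3 concentrations are dropped
#'   with a partial-grid warning.
#' @export
score_design <- function(rows, noise_depth_mm = 0.27,
                         power_threshold_pct = 0.1, use_normalized = FALSE) {
  stopifnot(power_threshold_pct > 0)
  key <- interaction(rows$wavelength, rows$separation_d, drop = TRUE)
  cells <- split(rows, key)
  short <- vapply(cells, function(d) nrow(d) < 3L, logical(1))
  if (any(short)) {
    warning(sprintf("partial grid: %d cell(s) with < 3 concentrations dropped",
                    sum(short)))
    cells <- cells[!short]
  }
  if (!length(cells)) stop("no scoreable cells")
  out <- lapply(cells, function(d) {
    d <- d[order(d$c_lactate), ]
    a <- if (use_normalized) normalize_absorbance(d$absorbance) else d$absorbance
    fit <- sensitivity_slope(d$c_lactate, a)
    data.frame(
      wavelength = d$wavelength[1], separation_d = d$separation_d[1],
      mean_depth_mm = mean(d$mean_penetration_depth),
      mean_power_pct = mean(d$relative_power_pct),
      sensitivity = abs(fit$slope), linearity_r2 = fit$r2,
      noise_ok = mean(d$mean_penetration_depth) > noise_depth_mm,
      power_ok = mean(d$relative_power_pct) >= power_threshold_pct)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$wavelength, out$separation_d), ]
}

#' Select the optimal sensor design
#'
#' Among cells passing both boolean criteria (\code{noise_ok} and
#' \code{power_ok}), returns the cell with maximal sensitivity;
#' ties break to the larger wavelength, then the smaller separation. This is
#' one concrete formalization of a qualitative multi-criteria choice.
#'
#' @param scored Output of [score_design()].
#' @return List with \code{wavelength}, \code{separation_d} and the winning
#'   row as \code{cell}.
#' @export
select_optimal <- function(scored) {
  feasible <- scored[scored$noise_ok & scored$power_ok, ]
  if (nrow(feasible) == 0L) {
    fail <- scored[!(scored$noise_ok & scored$power_ok),
                   c("wavelength", "separation_d", "noise_ok", "power_ok")]
    stop("infeasible design: no cell passes both criteria\n",
         paste(utils::capture.output(print(fail, row.names = FALSE)),
               collapse = "\n"))
  }
  o <- order(-feasible$sensitivity, -feasible$wavelength,
             feasible$separation_d)
  best <- feasible[o[1L], ]
  list(wavelength = best$wavelength, separation_d = best$separation_d,
       cell = best)
}
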