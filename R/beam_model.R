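#' Calibration curve (piecewise-linear, invertible)
#'
#' A monotone piecewise-linear mapping defined by breakpoints, used for the
#' Hall-reading to magnet-current and magnet-current to lateral-position
#' calibrations.  Inputs must be strictly increasing and outputs strictly
#' monotone so the curve is invertible.  Evaluation outside the calibrated
#' domain is an error (out-of-range sensor readings are data errors, not
#' extrapolation candidates).
#'
#' @param x,y Numeric breakpoint vectors (length >= 2).
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("calibration curve inputs must be strictly increasing")
  d <- diff(y)
  if (!(all(d > 0) || all(d < 0))) {
    stop("calibration curve outputs must be strictly monotone")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "calibration_curve")
}

eval_curve <- function(curve, v) {
  rng <- range(curve$x)
  if (any(v < rng[1] - 1e-12 | v > rng[2] + 1e-12)) {
    stop(sprintf("value %.6g outside calibrated domain [%.6g, %.6g]",
                 v[which(v < rng[1] - 1e-12 | v > rng[2] + 1e-12)[1]], rng[1], rng[2]))
  }
  approx(curve$x, curve$y, xout = pmin(pmax(v, rng[1]), rng[2]), ties = "ordered")$y
}

invert_curve <- function(curve, v) {
  ord <- order(curve$y)
  inv <- calibration_curve(curve$y[ord], curve$x[ord])
  eval_curve(inv, v)
}

#' Beam model: calibration bundle for one machine
#'
#' Bundles every calibration needed to interpret a delivery log: per-axis
#' Hall-reading to magnet-current and current to isocenter-plane position
#' curves, commissioning beam widths per gantry angle (with an optional
#' bounded per-position variation), the spot dose-area calibration, and the
#' UHDR monitor recombination factor.
#'
#' @param hall_to_current_U,hall_to_current_T [calibration_curve()],
#'   sensor units to ampere.
#' @param current_to_pos_U,current_to_pos_T [calibration_curve()], ampere to
#'   mm at the isocenter plane.
#' @param sigma_table Data frame with columns `angle` (degrees), `sigma_u`,
#'   `sigma_t` (mm): mean commissioning beam widths per gantry angle.
#' @param dose_cal Spot integral dose-area calibration, Gy.mm^2 per MU at
#'   the 2 cm measurement depth; a spot's point dose is
#'   `MU * dose_cal * N(x; mu, sigma)` with `N` the unit-integral bivariate
#'   Gaussian density.
#' @param recomb_factor Dimensionless monitor recombination correction
#'   (>= 1) applied to UHDR deliveries; determined daily against a
#'   recombination-free reference detector.
#' @param sigma_variation Optional list `(u_slope, t_slope)` (per mm): a
#'   linear per-position multiplicative variation of the beam widths,
#'   clamped to +/-10% (commissioning shows beam-size variations up to 10%
#'   across the spot map).  `NULL` for the angle-invariant model.
#' @return Object of class `beam_model`.
#' @export
beam_model <- function(hall_to_current_U, hall_to_current_T,
                       current_to_pos_U, current_to_pos_T,
                       sigma_table, dose_cal, recomb_factor = 1.0,
                       sigma_variation = NULL) {
  stopifnot(inherits(hall_to_current_U, "calibration_curve"),
            inherits(hall_to_current_T, "calibration_curve"),
            inherits(current_to_pos_U, "calibration_curve"),
            inherits(current_to_pos_T, "calibration_curve"),
            is.data.frame(sigma_table),
            all(c("angle", "sigma_u", "sigma_t") %in% names(sigma_table)))
  if (any(sigma_table$sigma_u <= 0) || any(sigma_table$sigma_t <= 0)) {
    stop("beam widths must be positive")
  }
  if (dose_cal <= 0) stop("dose_cal must be positive")
  if (recomb_factor < 1) stop("recomb_factor must be >= 1")
  structure(list(hall_to_current_U = hall_to_current_U,
                 hall_to_current_T = hall_to_current_T,
                 current_to_pos_U = current_to_pos_U,
                 current_to_pos_T = current_to_pos_T,
                 sigma_table = sigma_table,
                 dose_cal = dose_cal,
                 recomb_factor = recomb_factor,
                 sigma_variation = sigma_variation),
            class = "beam_model")
}

#' Convert a raw Hall-sensor reading to a lateral position
#'
#' Composes the Hall-to-current and current-to-position calibration curves
#' for the requested scanning axis.  Monotone and continuous in the raw
#' reading; readings outside the calibrated domain raise a range error.
#'
#' @param raw Raw Hall reading(s), sensor units.
#' @param axis `"U"` (horizontal) or `"T"` (vertical).
#' @param model A [beam_model()].
#' @return Position(s) in mm at the isocenter plane.
#' @export
hall_to_position <- function(raw, axis = c("U", "T"), model) {
  axis <- match.arg(axis)
  if (axis == "U") {
    eval_curve(model$current_to_pos_U, eval_curve(model$hall_to_current_U, raw))
  } else {
    eval_curve(model$current_to_pos_T, eval_curve(model$hall_to_current_T, raw))
  }
}

#' Convert a lateral position to the corresponding raw Hall reading
#'
#' Inverse of [hall_to_position()]; the simulator uses it to synthesize
#' Hall traces for planned spot positions, and it converts mm-equivalent
#' noise levels to sensor units.
#'
#' @inheritParams hall_to_position
#' @param pos Position(s) in mm at the isocenter plane.
#' @return Raw Hall reading(s), sensor units.
#' @export
position_to_hall <- function(pos, axis = c("U", "T"), model) {
  axis <- match.arg(axis)
  if (axis == "U") {
    invert_curve(model$hall_to_current_U, invert_curve(model$current_to_pos_U, pos))
  } else {
    invert_curve(model$hall_to_current_T, invert_curve(model$current_to_pos_T, pos))
  }
}

#' Convert monitor counts to dose-area (and optionally point dose)
#'
#' CONV deliveries convert counts with the dose-area calibration alone; UHDR
#' deliveries additionally apply the monitor recombination factor (the
#' monitor under-responds at ultra-high dose rates).
#'
#' @param delta_counts Monitor counts (MU), >= 0.
#' @param model A [beam_model()].
#' @param arm `"CONV"` or `"UHDR"`.
#' @param geometry_factor Optional reference-geometry factor in 1/mm^2; when
#'   given, the result is a point dose in Gy instead of a dose-area.
#' @return Dose-area in Gy.mm^2, or dose in Gy if `geometry_factor` is given.
#' @export
counts_to_dose <- function(delta_counts, model, arm = c("CONV", "UHDR"),
                           geometry_factor = NULL) {
  arm <- match.arg(arm)
  if (any(delta_counts < 0)) stop("monitor counts must be non-negative")
  out <- delta_counts * model$dose_cal
  if (arm == "UHDR") out <- out * model$recomb_factor
  if (!is.null(geometry_factor)) out <- out * geometry_factor
  out
}

#' Determine the monitor recombination factor
#'
#' The factor is the ratio of the dose measured by a recombination-free
#' reference detector to the (recombination-affected) monitor-derived dose.
#' Factors above 1.25 are outside the regime observed on the machine
#' (roughly 20% charge loss at 600 nA) and trigger a warning.
#'
#' @param monitor_dose Monitor-derived dose, Gy (> 0).
#' @param reference_dose Reference-detector dose, Gy (> 0).
#' @return The dimensionless recombination factor.
#' @export
fit_recombination_factor <- function(monitor_dose, reference_dose) {
  if (monitor_dose <= 0 || reference_dose <= 0) {
    stop("doses must be positive")
  }
  factor <- reference_dose / monitor_dose
  if (factor > 1.25) {
    warning(sprintf("recombination factor %.4f exceeds the expected regime (> 1.25)",
                    factor))
  }
  factor
}

#' Look up commissioning beam widths for a gantry angle
#'
#' Returns the mean commissioning widths for the nearest tabulated gantry
#' angle (within 5 degrees).  When the model carries a per-position
#' variation field and a position is supplied, a multiplicative factor
#' (clamped to +/-10%) is applied.
#'
#' @param gantry_angle Gantry angle, degrees.
#' @param model A [beam_model()].
#' @param position Optional `c(u, t)` position in mm.
#' @return Named numeric `c(sigma_u, sigma_t)` in mm.
#' @export
sigma_lookup <- function(gantry_angle, model, position = NULL) {
  tab <- model$sigma_table
  if (nrow(tab) == 0) stop("sigma table is empty")
  d <- abs(tab$angle - gantry_angle)
  # angles wrap at 360
  d <- pmin(d, 360 - d)
  i <- which.min(d)
  if (d[i] > 5) {
    stop(sprintf("no beam-width table entry within 5 degrees of gantry angle %g", gantry_angle))
  }
  s <- c(sigma_u = tab$sigma_u[i], sigma_t = tab$sigma_t[i])
  if (!is.null(position) && !is.null(model$sigma_variation)) {
    f <- 1 + model$sigma_variation$u_slope * position[1] +
      model$sigma_variation$t_slope * position[2]
    f <- pmin(pmax(f, 0.9), 1.1)
    s <- s * f
  }
  s
}

curve_to_list <- function(curve) list(x = curve$x, y = curve$y)

#' Write a beam model to JSON
#' @param model A [beam_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_beam_model <- function(model, path) {
  obj <- list(
    hall_to_current_U = curve_to_list(model$hall_to_current_U),
    hall_to_current_T = curve_to_list(model$hall_to_current_T),
    current_to_pos_U = curve_to_list(model$current_to_pos_U),
    current_to_pos_T = curve_to_list(model$current_to_pos_T),
    sigma_table = model$sigma_table,
    dose_cal = model$dose_cal,
    recomb_factor = model$recomb_factor,
    sigma_variation = model$sigma_variation
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a beam model from JSON
#' @param path Path to a model JSON file.
#' @return A [beam_model()].
#' @export
read_beam_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beam_model(
    hall_to_current_U = calibration_curve(obj$hall_to_current_U$x, obj$hall_to_current_U$y),
    hall_to_current_T = calibration_curve(obj$hall_to_current_T$x, obj$hall_to_current_T$y),
    current_to_pos_U = calibration_curve(obj$current_to_pos_U$x, obj$current_to_pos_U$y),
    current_to_pos_T = calibration_curve(obj$current_to_pos_T$x, obj$current_to_pos_T$y),
    sigma_table = as.data.frame(obj$sigma_table),
    dose_cal = obj$dose_cal,
    recomb_factor = obj$recomb_factor,
    sigma_variation = obj$sigma_variation
  )
}

#' A simple default beam model
#'
#' Linear calibrations mapping Hall readings in \[-1, 1\] to magnet currents
#' in \[-50, 50\] A and on to positions in \[-100, 100\] mm on both axes,
#' 3.5 mm commissioning beam widths at gantry angles 0/90/180/270, and a
#' dose-area calibration of 0.02 Gy.mm^2/MU.  Convenient for examples,
#' simulations and tests; real deployments load a measured model with
#' [read_beam_model()].
#'
#' @param sigma_u,sigma_t Beam widths in mm.
#' @param dose_cal Gy.mm^2 per MU.
#' @param recomb_factor UHDR recombination correction (>= 1).
#' @param sigma_variation Optional variation field, see [beam_model()].
#' @return A [beam_model()].
#' @export
default_beam_model <- function(sigma_u = 3.5, sigma_t = 3.5, dose_cal = 0.02,
                               recomb_factor = 1.0, sigma_variation = NULL) {
  beam_model(
    hall_to_current_U = calibration_curve(c(-1, 1), c(-50, 50)),
    hall_to_current_T = calibration_curve(c(-1, 1), c(-50, 50)),
    current_to_pos_U = calibration_curve(c(-50, 50), c(-100, 100)),
    current_to_pos_T = calibration_curve(c(-50, 50), c(-100, 100)),
    sigma_table = data.frame(angle = c(0, 90, 180, 270),
                             sigma_u = sigma_u, sigma_t = sigma_t),
    dose_cal = dose_cal, recomb_factor = recomb_factor,
    sigma_variation = sigma_variation
  )
}
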