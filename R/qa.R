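#' Fit an axis-aligned 2D Gaussian to a dose image
#'
#' Least-squares fit of `bg + A * exp(-(u-u0)^2/(2 sU^2) - (t-t0)^2/(2 sT^2))`
#' (Levenberg-Marquardt, up to 200 iterations) with moment-based starting
#' values; used for beam-size/position QA of single spots.
#'
#' @param image A [dose_grid()] containing a single dominant peak.
#' @param init Optional named list of starting values
#'   (`u0`, `t0`, `sigma_u`, `sigma_t`, `amplitude`, `background`).
#' @return List: `center` (mm), `sigma` (mm), `amplitude`, `background`,
#'   `rss_rms` (residual RMS).
#' @export
fit_spot_2d_gaussian <- function(image, init = NULL) {
  v <- image$values
  if (max(v) - min(v) <= 0) stop("flat image: no peak to fit")
  ax <- grid_axes(image)
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  if (pk[1] %in% c(1, nrow(v)) || pk[2] %in% c(1, ncol(v))) {
    stop("peak lies on the image border; enlarge the crop window")
  }
  pts <- expand.grid(u = ax$u, t = ax$t)
  z <- as.vector(v)
  bg0 <- init$background %||% min(z)
  w <- pmax(z - bg0, 0)
  u0 <- init$u0 %||% (sum(w * pts$u) / sum(w))
  t0 <- init$t0 %||% (sum(w * pts$t) / sum(w))
  su0 <- init$sigma_u %||% sqrt(sum(w * (pts$u - u0)^2) / sum(w))
  st0 <- init$sigma_t %||% sqrt(sum(w * (pts$t - t0)^2) / sum(w))
  a0 <- init$amplitude %||% (max(z) - bg0)
  # Levenberg-Marquardt with the analytic Jacobian (finite differences are
  # unreliable when the moment-based start is already near-exact)
  model_fn <- function(p) {
    p["bg"] + p["A"] * exp(-(pts$u - p["u0"])^2 / (2 * p["su"]^2) -
                             (pts$t - p["t0"])^2 / (2 * p["st"]^2))
  }
  jac_fn <- function(p) {
    eu <- (pts$u - p["u0"]) / p["su"]
    et <- (pts$t - p["t0"]) / p["st"]
    E <- exp(-eu^2 / 2 - et^2 / 2)
    cbind(bg = 1, A = E,
          u0 = p["A"] * E * eu / p["su"],
          t0 = p["A"] * E * et / p["st"],
          su = p["A"] * E * eu^2 / p["su"],
          st = p["A"] * E * et^2 / p["st"])
  }
  start <- c(bg = bg0, A = a0, u0 = u0, t0 = t0,
             su = max(su0, image$spacing), st = max(st0, image$spacing))
  fit <- minpack.lm::nls.lm(par = start,
                            fn = function(p) model_fn(p) - z,
                            jac = jac_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4)) {
    stop("2D Gaussian fit did not converge: ", fit$message)
  }
  p <- fit$par
  list(center = c(u = unname(p["u0"]), t = unname(p["t0"])),
       sigma = c(u = abs(unname(p["su"])), t = abs(unname(p["st"]))),
       amplitude = unname(p["A"]), background = unname(p["bg"]),
       rss_rms = sqrt(mean(fit$fvec^2)))
}

#' Default five-spot QA pattern
#'
#' Center spot plus four spots at `(+-arm_mm, 0)` and `(0, +-arm_mm)`.
#' @param arm_mm Arm length in mm (default 40).
#' @return Data frame with columns `u`, `t`.
#' @export
five_spot_nominal <- function(arm_mm = 40) {
  data.frame(u = c(0, arm_mm, -arm_mm, 0, 0),
             t = c(0, 0, 0, arm_mm, -arm_mm))
}

#' Analyze a five-spot QA image
#'
#' Fits each spot independently (2D Gaussian on a crop window around its
#' nominal position), compares positions and sizes against the
#' commissioning values, and suggests the global offset correction — the
#' translation that undoes the mean systematic shift (the negative of the
#' mean per-spot offset).
#'
#' @param image A [dose_grid()] with five separable peaks.
#' @param nominal Data frame `u`, `t` of nominal positions (default
#'   [five_spot_nominal()]).
#' @param reference_sizes `c(sigma_u, sigma_t)` commissioning widths, mm.
#' @param pos_tol Position tolerance, mm (default 2).
#' @param size_tol Size tolerance, % (default 10).
#' @param window Half-width of the crop window, mm (default half the
#'   smallest nominal spot separation).
#' @return Object of class `five_spot_result`: per-spot table (`offsets`,
#'   fitted sizes, deviations, pass flags), `suggested_correction` (mm),
#'   `position_pass`, `size_pass`, `pass`.
#' @export
analyze_five_spot <- function(image, nominal = five_spot_nominal(),
                              reference_sizes, pos_tol = 2, size_tol = 10,
                              window = NULL) {
  n <- nrow(nominal)
  if (is.null(window)) {
    dd <- as.matrix(dist(nominal))
    window <- min(dd[dd > 0]) / 2
  }
  ax <- grid_axes(image)
  fits <- lapply(seq_len(n), function(i) {
    iu <- which(abs(ax$u - nominal$u[i]) <= window)
    it <- which(abs(ax$t - nominal$t[i]) <= window)
    if (length(iu) < 5 || length(it) < 5) {
      stop(sprintf("crop window around nominal spot %d falls outside the image", i))
    }
    sub <- dose_grid(image$values[iu, it, drop = FALSE],
                     origin = c(ax$u[iu[1]], ax$t[it[1]]), image$spacing)
    tryCatch(fit_spot_2d_gaussian(sub),
             error = function(e) stop(sprintf("spot %d not resolvable: %s",
                                              i, conditionMessage(e))))
  })
  tab <- data.frame(
    nominal_u = nominal$u, nominal_t = nominal$t,
    fitted_u = vapply(fits, function(f) f$center[["u"]], numeric(1)),
    fitted_t = vapply(fits, function(f) f$center[["t"]], numeric(1)),
    sigma_u = vapply(fits, function(f) f$sigma[["u"]], numeric(1)),
    sigma_t = vapply(fits, function(f) f$sigma[["t"]], numeric(1)),
    amplitude = vapply(fits, function(f) f$amplitude, numeric(1))
  )
  tab$offset_u <- tab$fitted_u - tab$nominal_u
  tab$offset_t <- tab$fitted_t - tab$nominal_t
  tab$size_dev_u <- (tab$sigma_u / reference_sizes[1] - 1) * 100
  tab$size_dev_t <- (tab$sigma_t / reference_sizes[2] - 1) * 100
  tab$position_pass <- abs(tab$offset_u) <= pos_tol & abs(tab$offset_t) <= pos_tol
  tab$size_pass <- abs(tab$size_dev_u) <= size_tol & abs(tab$size_dev_t) <= size_tol
  structure(list(
    spots = tab,
    suggested_correction = c(u = -mean(tab$offset_u), t = -mean(tab$offset_t)),
    position_pass = all(tab$position_pass),
    size_pass = all(tab$size_pass),
    pass = all(tab$position_pass) && all(tab$size_pass),
    pos_tol = pos_tol, size_tol = size_tol
  ), class = "five_spot_result")
}

#' Central dose check
#'
#' The ratio of measured to planned dose at the field center must be within
#' `tol` of unity; if not, the field dose is scaled by `1/ratio`.
#'
#' @param measured_dose,planned_dose Gy; `planned_dose > 0`.
#' @param tol Relative tolerance (default 0.05).
#' @return List: `ratio`, `scaling` (`NULL` when within tolerance),
#'   `within_tolerance`.
#' @export
central_dose_check <- function(measured_dose, planned_dose, tol = 0.05) {
  if (planned_dose <= 0) stop("planned dose must be positive")
  ratio <- measured_dose / planned_dose
  within <- abs(ratio - 1) <= tol
  list(ratio = ratio, scaling = if (within) NULL else 1 / ratio,
       within_tolerance = within)
}

#' Mean-deviation / boosting check
#'
#' Mean signed relative deviation of test vs reference over the analysis
#' mask (reference >= `mask_level` of its maximum); if its magnitude
#' exceeds `threshold` percent, a boosting factor `1/(1 + dev/100)` is
#' returned and the delivery is to be repeated with it.
#'
#' @param reference,test [dose_grid()]s on common geometry.
#' @param mask_level Fraction of the reference maximum (default 0.9).
#' @param threshold Percent (default 3).
#' @return List: `mean_deviation` (%), `boosting` (`NULL` when within
#'   threshold).
#' @export
boosting_check <- function(reference, test, mask_level = 0.9, threshold = 3) {
  if (!same_geometry(reference, test)) stop("grids differ in geometry")
  mask <- reference$values >= mask_level * max(reference$values)
  if (!any(mask)) stop("empty analysis mask")
  dev <- mean((test$values[mask] - reference$values[mask]) /
                reference$values[mask]) * 100
  list(mean_deviation = dev,
       boosting = if (abs(dev) > threshold) 1 / (1 + dev / 100) else NULL)
}

#' UHDR dose-rate floor check
#'
#' Local dose rates sampled at different positions within the field must
#' all be strictly above the floor (40 Gy/s) for a UHDR delivery.
#'
#' @param rates Dose rates, Gy/s (>= 1 value).
#' @param floor Gy/s (default 40).
#' @return List: `pass`, `failing_positions` (indices with rate <= floor).
#' @export
uhdr_dose_rate_check <- function(rates, floor = 40) {
  if (length(rates) == 0) stop("no dose-rate samples")
  failing <- which(rates <= floor)
  list(pass = length(failing) == 0, failing_positions = failing,
       floor = floor)
}

# field center of a rectangular-grid plan
plan_center <- function(plan) {
  c(plan$u_start + (plan$nu - 1) / 2 * plan$du,
    plan$t_start + (plan$nt - 1) / 2 * plan$dt)
}

qa_status <- function(five_spot, gamma, boost, rate_check, corrected) {
  if (!is.null(five_spot) && !five_spot$pass) return("fail")
  if (!is.null(rate_check) && !rate_check$pass) return("fail")
  if (gamma$pass_fraction <= 90) return("clinical-review")
  if (corrected) "pass-with-correction" else "pass"
}

run_qa_pipeline <- function(kind, reference, measured, model,
                            five_spot_image, five_spot_ref_sizes,
                            center, gamma_args, dose_rate_samples,
                            laser_alignment_ok, notes = character()) {
  offset <- c(u = 0, t = 0)
  fs <- NULL
  corrected_map <- measured
  applied <- FALSE
  if (!is.null(five_spot_image)) {
    fs <- analyze_five_spot(five_spot_image, reference_sizes = five_spot_ref_sizes)
    if (any(abs(fs$suggested_correction) > 0.1)) {
      offset <- fs$suggested_correction
      corrected_map <- translate_grid(corrected_map, offset[["u"]], offset[["t"]])
      applied <- TRUE
      notes <- c(notes, sprintf("offset correction applied: (%.2f, %.2f) mm",
                                offset[["u"]], offset[["t"]]))
    }
  }
  planned_center <- dose_at(reference, center[1], center[2])
  measured_center <- dose_at(corrected_map, center[1], center[2])
  cd <- central_dose_check(measured_center, planned_center)
  scaling <- 1.0
  if (!is.null(cd$scaling)) {
    scaling <- cd$scaling
    corrected_map <- dose_grid(corrected_map$values * scaling,
                               corrected_map$origin, corrected_map$spacing)
    applied <- TRUE
    notes <- c(notes, sprintf("dose scaling applied: %.4f", scaling))
  }
  bc <- boosting_check(reference, corrected_map)
  if (!is.null(bc$boosting)) {
    # model the boosted repeat delivery before the spatial comparison
    corrected_map <- dose_grid(corrected_map$values * bc$boosting,
                               corrected_map$origin, corrected_map$spacing)
    applied <- TRUE
    notes <- c(notes, sprintf("boosting factor %.4f applied: repeat delivery",
                              bc$boosting))
  }
  gm <- do.call(gamma_index_map, c(list(reference = reference,
                                        test = corrected_map), gamma_args))
  rc <- if (!is.null(dose_rate_samples)) uhdr_dose_rate_check(dose_rate_samples) else NULL
  if (!laser_alignment_ok) notes <- c(notes, "laser/isocenter alignment failed")
  status <- qa_status(fs, gm, bc, rc, applied)
  if (!laser_alignment_ok) status <- "fail"
  structure(list(
    kind = kind, laser_alignment_ok = laser_alignment_ok,
    five_spot = fs, offset_applied = offset,
    central_dose = cd, scaling_factor = scaling,
    boosting = bc, gamma = gm, dose_rate_check = rc,
    corrected_map = corrected_map, status = status, notes = notes
  ), class = "qa_decision")
}

#' Run the patient-specific QA (PSQA) pipeline
#'
#' Executes the PSQA steps on a measured (or simulated) field: the
#' laser-alignment result is recorded (it is a physical measurement, not
#' computed); the five-spot image yields the systematic offset correction;
#' the central dose check yields the dose scaling; the corrected map is
#' compared to the TPS reference with the 3%/3 mm gamma analysis and the
#' 3% mean-deviation (boosting) check; optional local dose-rate samples are
#' checked against the 40 Gy/s UHDR floor.
#'
#' @param plan The [simple_plan()] under QA.
#' @param measured Measured/reconstructed [dose_grid()].
#' @param model A [beam_model()].
#' @param reference Optional reference [dose_grid()]; default is
#'   [tps_dose_map()] of the plan on the measured geometry (the TPS
#'   recalculation in water).
#' @param five_spot_image Optional five-spot [dose_grid()].
#' @param dose_rate_samples Optional numeric vector of local dose rates,
#'   Gy/s (UHDR floor check).
#' @param laser_alignment_ok Externally supplied laser/isocenter alignment
#'   result (2 mm tolerance), default `TRUE`.
#' @param gamma_args List of overrides passed to [gamma_index_map()].
#' @return A `qa_decision`: corrections, gamma result, overall `status`
#'   (`pass`, `pass-with-correction`, `fail`, or `clinical-review` — the
#'   latter whenever the gamma pass fraction is at or below 90% after
#'   corrections).
#' @export
run_psqa <- function(plan, measured, model, reference = NULL,
                     five_spot_image = NULL, dose_rate_samples = NULL,
                     laser_alignment_ok = TRUE, gamma_args = list()) {
  if (is.null(reference)) reference <- tps_dose_map(plan, measured)
  run_qa_pipeline("PSQA", reference, measured, model,
                  five_spot_image, plan$mean_sigma,
                  plan_center(plan), gamma_args, dose_rate_samples,
                  laser_alignment_ok)
}

#' Run the daily QA (DQA) pipeline
#'
#' Identical pipeline and tolerances to [run_psqa()], but the reference is
#' the dose distribution delivered on the day of the PSQA rather than the
#' TPS recalculation.  For a UHDR delivery, the daily monitor recombination
#' factor (from [fit_recombination_factor()] when `monitor_dose` and
#' `reference_dose` are given) is applied to the daily map first, and an
#' interruption found in the daily delivery log marks the patient as
#' recommended for exclusion from the UHDR arm.
#'
#' @param psqa_reference [dose_grid()] measured on the PSQA day.
#' @param daily Daily measured/reconstructed [dose_grid()].
#' @param model A [beam_model()].
#' @param arm `"CONV"` or `"UHDR"`.
#' @param center `c(u, t)` field reference point, mm.
#' @param monitor_dose,reference_dose Optional daily recombination
#'   cross-calibration pair, Gy (UHDR).
#' @param log Optional daily [delivery_log()]; scanned for interruptions.
#' @inheritParams run_psqa
#' @return A `qa_decision` with an `exclusion_recommended` field.
#' @export
run_dqa <- function(psqa_reference, daily, model, arm = "CONV",
                    center = c(0, 0), monitor_dose = NULL,
                    reference_dose = NULL, log = NULL,
                    five_spot_image = NULL, five_spot_ref_sizes = NULL,
                    dose_rate_samples = NULL, laser_alignment_ok = TRUE,
                    gamma_args = list()) {
  notes <- character()
  if (arm == "UHDR" && !is.null(monitor_dose) && !is.null(reference_dose)) {
    rf <- fit_recombination_factor(monitor_dose, reference_dose)
    daily <- dose_grid(daily$values * rf, daily$origin, daily$spacing)
    notes <- c(notes, sprintf("daily recombination factor %.4f applied", rf))
  }
  excl <- FALSE
  if (!is.null(log)) {
    pd <- detect_pauses(log)
    if (pd$exclusion_recommended) {
      excl <- TRUE
      notes <- c(notes, "interruption during UHDR delivery: exclusion from UHDR arm recommended")
    }
  }
  dec <- run_qa_pipeline("DQA", psqa_reference, daily, model,
                         five_spot_image,
                         five_spot_ref_sizes %||% c(1, 1),
                         center, gamma_args, dose_rate_samples,
                         laser_alignment_ok, notes = notes)
  dec$exclusion_recommended <- excl
  dec
}

#' @export
print.qa_decision <- function(x, ...) {
  cat(sprintf("<qa_decision> %s: %s\n", x$kind, toupper(x$status)))
  cat(sprintf("  central dose ratio %.4f%s\n", x$central_dose$ratio,
              if (x$scaling_factor != 1) sprintf(" (scaling %.4f)", x$scaling_factor) else ""))
  cat(sprintf("  gamma pass %.1f%%, mean deviation %.2f%%\n",
              x$gamma$pass_fraction, x$gamma$mean_dev))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
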