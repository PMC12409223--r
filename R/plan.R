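#' Simplified treatment-plan description
#'
#' The simplified plan the TPS-side calculation works with: equally weighted
#' spots on a rectangular grid, a single (angle-averaged) beam width, a
#' constant beam intensity, and constant spot-changing dead times — 4 ms for
#' a U step within a row, 11 ms for a T row change.
#'
#' @param field_id Field identifier.
#' @param gantry_angle,couch_angle Degrees.
#' @param u_start,t_start Position of the first spot, mm.
#' @param du,dt Spot spacing along U and T, mm (> 0).
#' @param nu,nt Number of spots along U and T (>= 1).
#' @param mu_per_spot Monitor units per spot (equal weights).
#' @param mean_sigma `c(sigma_u, sigma_t)` angle-averaged beam widths, mm.
#' @param dose_cal Gy.mm^2 per MU.
#' @param intensity Beam intensity, MU/s (> 0).
#' @param dead_time_u,dead_time_t Spot-changing times, ms.
#' @param fractions Number of fractions (>= 1).
#' @param fraction_dose Physical dose per fraction, Gy.
#' @param arm Delivery arm label, `"CONV"` or `"UHDR"`.
#' @return Object of class `simple_plan`.
#' @export
simple_plan <- function(field_id = "F1", gantry_angle = 90, couch_angle = 0,
                        u_start = 0, t_start = 0, du = 2.5, dt = 2.5,
                        nu = 1L, nt = 1L, mu_per_spot = 100,
                        mean_sigma = c(3.5, 3.5), dose_cal = 0.02,
                        intensity = 1e4, dead_time_u = DEAD_TIME_U_MS,
                        dead_time_t = DEAD_TIME_T_MS,
                        fractions = 3L, fraction_dose = 11,
                        arm = c("CONV", "UHDR")) {
  arm <- match.arg(arm)
  stopifnot(nu >= 1, nt >= 1, du > 0, dt > 0, mu_per_spot > 0,
            dead_time_u >= 0, dead_time_t >= 0)
  if (intensity <= 0) stop("intensity must be positive")
  structure(list(field_id = field_id, gantry_angle = gantry_angle,
                 couch_angle = couch_angle, u_start = u_start,
                 t_start = t_start, du = du, dt = dt,
                 nu = as.integer(nu), nt = as.integer(nt),
                 mu_per_spot = mu_per_spot, mean_sigma = mean_sigma,
                 dose_cal = dose_cal, intensity = intensity,
                 dead_time_u = dead_time_u, dead_time_t = dead_time_t,
                 fractions = as.integer(fractions),
                 fraction_dose = fraction_dose, arm = arm),
            class = "simple_plan")
}

#' Spot positions of a plan in delivery order
#'
#' Raster scan with U as the fast axis and boustrophedon row traversal
#' (alternate rows scanned in opposite U direction to minimize magnet ramp
#' distance).
#'
#' @param plan A [simple_plan()].
#' @return Data frame with columns `u`, `t` (mm), one row per spot.
#' @export
plan_spot_positions <- function(plan) {
  u_axis <- plan$u_start + (seq_len(plan$nu) - 1) * plan$du
  t_axis <- plan$t_start + (seq_len(plan$nt) - 1) * plan$dt
  rows <- lapply(seq_len(plan$nt), function(j) {
    u <- if (j %% 2 == 1) u_axis else rev(u_axis)
    data.frame(u = u, t = t_axis[j])
  })
  do.call(rbind, rows)
}

#' Delivery timeline of a plan
#'
#' Each spot's beam-on interval: beam-on duration is `mu_per_spot /
#' intensity`, with the U dead time between spots within a row and the T
#' dead time between rows.  Deterministic.
#'
#' @param plan A [simple_plan()].
#' @return Data frame with columns `t_start`, `t_end` (ms), one row per
#'   spot, in delivery order.
#' @export
tps_delivery_timeline <- function(plan) {
  n <- plan$nu * plan$nt
  dur <- plan$mu_per_spot / plan$intensity * 1000  # ms
  # dead time before spot k (none before the first)
  spot_in_row <- rep(seq_len(plan$nu), plan$nt)
  dead <- ifelse(spot_in_row == 1, plan$dead_time_t, plan$dead_time_u)
  dead[1] <- 0
  t_start <- cumsum(dead) + (seq_len(n) - 1) * dur
  data.frame(t_start = t_start, t_end = t_start + dur)
}

#' Total prescription dose of a plan
#'
#' @param plan A [simple_plan()] with `fractions >= 1`.
#' @return Total physical dose in Gy (`fractions * fraction_dose`).
#' @export
plan_total_dose <- function(plan) {
  if (plan$fractions < 1) stop("fractions must be >= 1")
  plan$fractions * plan$fraction_dose
}

#' Write a plan to JSON
#' @param plan A [simple_plan()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plan from JSON
#' @param path Path to a plan JSON file.
#' @return A [simple_plan()].
#' @export
read_plan <- function(path) {
  obj <- jsonlite::fromJSON(path)
  do.call(simple_plan, obj)
}
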