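#' Simulate a PBS field delivery
#'
#' Produces the 1 kHz delivery log a real field would generate, plus the
#' ground truth it was generated from.  The timing model matches the
#' simplified TPS delivery model: constant beam intensity during beam-on,
#' constant spot-changing dead times (4 ms for a U step, 11 ms for a T row
#' change), boustrophedon raster order.  During dead times the monitor
#' channels are flat and the Hall channels ramp linearly from the old to the
#' new spot value over the full dead time (the magnets' ramping and settling
#' time).  Sampling runs from field load (t = 0) to 10 ms past the last spot
#' end.
#'
#' The cumulative monitor channel is evaluated analytically at each sample
#' time, so the sum of increments equals the plan's total MU exactly.
#' Optional Gaussian noise is added per sample to the Hall channels (sensor
#' units) and to the beam-on monitor increments (MU, clamped so the
#' cumulative channel stays monotone; beam-off samples stay exactly flat).
#'
#' @param plan A [simple_plan()] with >= 1 spot.
#' @param model A [beam_model()] (used to synthesize Hall traces and the
#'   true beam widths).
#' @param noise List with elements `hall_sd` (sensor units) and `monitor_sd`
#'   (MU per beam-on sample increment); both default 0.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements `log` (a [delivery_log()]) and `truth`
#'   (a `ground_truth`: `spots` data frame with true `u`, `t`, `sigma_u`,
#'   `sigma_t`, `mu`, `t_start`, `t_end`; `pauses`; `total_mu`;
#'   `intensity`).
#' @export
simulate_delivery <- function(plan, model, noise = list(hall_sd = 0, monitor_sd = 0),
                              seed = 1L) {
  stopifnot(inherits(plan, "simple_plan"), inherits(model, "beam_model"))
  if (plan$nu * plan$nt < 1) stop("plan must contain at least one spot")
  if (plan$intensity <= 0) stop("intensity must be positive")
  hall_sd <- noise$hall_sd %||% 0
  monitor_sd <- noise$monitor_sd %||% 0
  set.seed(as.integer(seed))

  pos <- plan_spot_positions(plan)
  tl <- tps_delivery_timeline(plan)
  n_spots <- nrow(pos)
  period <- 1.0  # ms, 1 kHz

  t_ms <- seq(0, ceiling(tl$t_end[n_spots]) + 10, by = period)
  t_ms <- round(t_ms / TIME_QUANTUM_MS) * TIME_QUANTUM_MS

  # analytic cumulative MU: each spot contributes linearly over its interval
  dur <- tl$t_end - tl$t_start
  mon <- rowSums(vapply(seq_len(n_spots), function(i) {
    plan$mu_per_spot * pmin(pmax((t_ms - tl$t_start[i]) / dur[i], 0), 1)
  }, numeric(length(t_ms))))

  # Hall traces: constant at the spot value during beam-on, linear ramp
  # across dead times; held before the first and after the last spot.
  hall_u_spot <- position_to_hall(pos$u, "U", model)
  hall_t_spot <- position_to_hall(pos$t, "T", model)
  bp_t <- as.vector(rbind(tl$t_start, tl$t_end))
  hall_trace <- function(h) {
    bp_h <- rep(h, each = 2)
    approx(bp_t, bp_h, xout = t_ms, rule = 2, ties = "ordered")$y
  }
  hallU <- hall_trace(hall_u_spot)
  hallT <- hall_trace(hall_t_spot)

  noisy_monitor <- function(mon) {
    if (monitor_sd <= 0) return(mon)
    inc <- c(mon[1], diff(mon))
    on <- inc > 0
    inc[on] <- pmax(inc[on] + rnorm(sum(on), 0, monitor_sd), 0)
    cumsum(inc)
  }
  mon1 <- noisy_monitor(mon)
  mon2 <- noisy_monitor(mon)
  if (hall_sd > 0) {
    hallU <- hallU + rnorm(length(t_ms), 0, hall_sd)
    hallT <- hallT + rnorm(length(t_ms), 0, hall_sd)
  }

  log <- delivery_log(
    field_id = plan$field_id, gantry_angle = plan$gantry_angle,
    couch_angle = plan$couch_angle, arm = plan$arm,
    samples = data.frame(t_ms = t_ms, mon1 = mon1, mon2 = mon2,
                         hallU = hallU, hallT = hallT),
    sample_period = period
  )

  sig <- t(vapply(seq_len(n_spots), function(i) {
    sigma_lookup(plan$gantry_angle, model, position = c(pos$u[i], pos$t[i]))
  }, numeric(2)))
  truth <- structure(list(
    spots = data.frame(index = seq_len(n_spots), u = pos$u, t = pos$t,
                       sigma_u = sig[, 1], sigma_t = sig[, 2],
                       mu = plan$mu_per_spot,
                       t_start = tl$t_start, t_end = tl$t_end),
    pauses = data.frame(t_start = numeric(), duration = numeric(),
                        cause = character()),
    total_mu = plan$mu_per_spot * n_spots,
    intensity = plan$intensity
  ), class = "ground_truth")

  list(log = log, truth = truth)
}

#' Inject a delivery pause into a simulated log
#'
#' Freezes both monitor channels (and the Hall channels) for `duration` ms
#' starting at `at`, shifting all later samples; models an interlock-driven
#' beam interruption.  Total MU is unchanged; the pause is appended to the
#' ground truth and affected spot intervals are stretched.
#'
#' @param log A [delivery_log()] from [simulate_delivery()].
#' @param truth The matching `ground_truth`.
#' @param at Pause start, ms; must fall strictly inside a beam-on interval.
#' @param duration Pause length, ms (positive multiple of the sample
#'   period).
#' @param cause Free-text cause label recorded in the ground truth and the
#'   log annotations.
#' @return List with updated `log` and `truth`.
#' @export
inject_pause <- function(log, truth, at, duration, cause = "interlock") {
  stopifnot(inherits(log, "delivery_log"))
  sp <- truth$spots
  if (!any(sp$t_start < at & at < sp$t_end)) {
    stop(sprintf("pause at %g ms does not fall within any beam-on interval", at))
  }
  period <- log$sample_period
  n_pause <- round(duration / period)
  if (n_pause < 1 || abs(n_pause * period - duration) > 1e-9) {
    stop("duration must be a positive multiple of the sample period")
  }
  s <- log$samples
  i0 <- which(s$t_ms >= at)[1]
  if (is.na(i0) || i0 < 2) stop("pause start outside the sampled record")
  frozen <- s[i0 - 1, ]
  pause_rows <- data.frame(
    t_ms = s$t_ms[i0] + (seq_len(n_pause) - 1) * period,
    mon1 = frozen$mon1, mon2 = frozen$mon2,
    hallU = frozen$hallU, hallT = frozen$hallT
  )
  shifted <- s[i0:nrow(s), ]
  shifted$t_ms <- shifted$t_ms + n_pause * period
  samples <- rbind(s[seq_len(i0 - 1), ], pause_rows, shifted)
  samples$t_ms <- round(samples$t_ms / TIME_QUANTUM_MS) * TIME_QUANTUM_MS
  row.names(samples) <- NULL

  new_log <- delivery_log(
    field_id = log$field_id, gantry_angle = log$gantry_angle,
    couch_angle = log$couch_angle, arm = log$arm, samples = samples,
    sample_period = period,
    annotations = c(log$annotations,
                    sprintf("pause %g ms at t=%g ms (%s)", duration, at, cause))
  )
  sp$t_end <- ifelse(sp$t_end > at, sp$t_end + duration, sp$t_end)
  sp$t_start <- ifelse(sp$t_start >= at, sp$t_start + duration, sp$t_start)
  truth$spots <- sp
  truth$pauses <- rbind(truth$pauses,
                        data.frame(t_start = at, duration = duration,
                                   cause = cause))
  list(log = new_log, truth = truth)
}
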