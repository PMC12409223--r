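#' Segment a delivery log into reconstructed spots
#'
#' Beam-on samples are those whose monitor increment exceeds the beam-on
#' threshold; maximal runs of beam-on samples form spots.  Each spot's MU is
#' taken from the cumulative monitor channel between the quiet plateaus
#' surrounding the run (robust to partial increments at run edges); its mean
#' position is the increment-weighted mean of the Hall-derived positions
#' over the run's interior samples (the first and last sample of a run may
#' catch magnet ramping and are excluded when the run is long enough);
#' widths come from the commissioning table at the log's gantry angle and
#' the spot position.
#'
#' A beam-off gap longer than `max_dead_time` between runs whose positions
#' agree within `pause_pos_tol` is an interruption inside a single spot: the
#' runs are merged into one record with `contains_pause = TRUE`.
#'
#' @param log A validated [delivery_log()].
#' @param model A [beam_model()].
#' @param beam_on_threshold MU per sample; default half the median positive
#'   increment (separates quantization noise from beam-on without
#'   configuration).
#' @param max_dead_time ms; gaps up to this are ordinary spot changes
#'   (default 11 ms row change + 2 samples margin).
#' @param pause_pos_tol mm; position agreement bound used to merge
#'   interrupted spots.
#' @return Data frame of class `spot_records` with columns `index`,
#'   `t_start`, `t_end` (ms), `u`, `t` (mm), `sigma_u`, `sigma_t` (mm),
#'   `mu` (MU), `dose_area` (Gy.mm^2), `contains_pause`.  Empty if the log
#'   has no beam-on samples.
#' @export
segment_spots <- function(log, model, beam_on_threshold = NULL,
                          max_dead_time = DEAD_TIME_T_MS + 2,
                          pause_pos_tol = 1.0) {
  s <- log$samples
  empty <- data.frame(index = integer(), t_start = numeric(), t_end = numeric(),
                      u = numeric(), t = numeric(), sigma_u = numeric(),
                      sigma_t = numeric(), mu = numeric(), dose_area = numeric(),
                      contains_pause = logical())
  class(empty) <- c("spot_records", "data.frame")
  if (nrow(s) == 0) return(empty)
  inc <- monitor_increments(log)
  pos_inc <- inc[inc > 0]
  if (length(pos_inc) == 0) return(empty)
  thr <- beam_on_threshold %||% (0.5 * median(pos_inc))
  on <- inc > thr
  if (!any(on)) return(empty)

  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  f <- starts[r$values]  # first sample of each beam-on run
  l <- ends[r$values]    # last sample of each beam-on run
  n_runs <- length(f)

  run_pos <- function(i) {
    idx <- f[i]:l[i]
    if (length(idx) > 2) idx <- idx[-c(1, length(idx))]
    w <- inc[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    c(sum(w * hall_to_position(s$hallU[idx], "U", model)) / sum(w),
      sum(w * hall_to_position(s$hallT[idx], "T", model)) / sum(w))
  }
  pos <- t(vapply(seq_len(n_runs), run_pos, numeric(2)))

  # group runs: merge across long gaps when the position is unchanged
  group <- integer(n_runs)
  group[1] <- 1L
  if (n_runs > 1) {
    for (i in 2:n_runs) {
      gap <- s$t_ms[f[i]] - s$t_ms[l[i - 1]]
      same_pos <- all(abs(pos[i, ] - pos[i - 1, ]) <= pause_pos_tol)
      group[i] <- if (gap > max_dead_time && same_pos) group[i - 1] else group[i - 1] + 1L
    }
  }
  n_spots <- max(group)

  # Extend runs over adjacent contiguous positive (sub-threshold) increments:
  # partial accrual in the boundary samples belongs to the run's own spot.
  n_samp <- nrow(s)
  f_ext <- vapply(f, function(i) {
    while (i > 1 && inc[i - 1] > 0) i <- i - 1L
    i
  }, integer(1))
  l_ext <- vapply(l, function(i) {
    while (i < n_samp && inc[i + 1] > 0) i <- i + 1L
    i
  }, integer(1))
  run_mu <- vapply(seq_len(n_runs), function(i) {
    base <- if (f_ext[i] > 1) s$mon1[f_ext[i] - 1L] else 0
    s$mon1[l_ext[i]] - base
  }, numeric(1))

  period <- log$sample_period
  out <- lapply(seq_len(n_spots), function(g) {
    runs <- which(group == g)
    idx <- unlist(lapply(runs, function(i) {
      ii <- f[i]:l[i]
      if (length(ii) > 2) ii <- ii[-c(1, length(ii))]
      ii
    }))
    w <- inc[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    mu_u <- sum(w * hall_to_position(s$hallU[idx], "U", model)) / sum(w)
    mu_t <- sum(w * hall_to_position(s$hallT[idx], "T", model)) / sum(w)
    first_on <- f_ext[min(runs)]
    data.frame(
      t_start = max(s$t_ms[first_on] - period, s$t_ms[1]),
      t_end = s$t_ms[l[max(runs)]],
      u = mu_u, t = mu_t, mu = sum(run_mu[runs]),
      contains_pause = length(runs) > 1
    )
  })
  out <- do.call(rbind, out)
  sig <- t(vapply(seq_len(nrow(out)), function(i) {
    sigma_lookup(log$gantry_angle, model, position = c(out$u[i], out$t[i]))
  }, numeric(2)))
  recomb <- if (log$arm == "UHDR") model$recomb_factor else 1.0
  res <- data.frame(index = seq_len(nrow(out)),
                    t_start = out$t_start, t_end = out$t_end,
                    u = out$u, t = out$t,
                    sigma_u = sig[, 1], sigma_t = sig[, 2],
                    mu = out$mu,
                    dose_area = out$mu * model$dose_cal * recomb,
                    contains_pause = out$contains_pause)
  class(res) <- c("spot_records", "data.frame")
  res
}

# Sum of weighted bivariate Gaussian densities on a grid.
# weights: Gy.mm^2 per spot; result in Gy at voxel centers.
# cutoff: elliptical truncation radius in units of sigma (Inf = none).
gaussian_sum <- function(u, t, sigma_u, sigma_t, weights, grid, cutoff = Inf) {
  ax <- grid_axes(grid)
  vals <- matrix(0, length(ax$u), length(ax$t))
  for (i in seq_along(u)) {
    du <- dnorm(ax$u, u[i], sigma_u[i])
    dt <- dnorm(ax$t, t[i], sigma_t[i])
    contrib <- weights[i] * outer(du, dt)
    if (is.finite(cutoff)) {
      ru <- (ax$u - u[i]) / sigma_u[i]
      rt <- (ax$t - t[i]) / sigma_t[i]
      contrib[outer(ru^2, rt^2, "+") > cutoff^2] <- 0
    }
    vals <- vals + contrib
  }
  vals
}

spot_weights <- function(spots, model, arm) {
  if (!is.null(spots$dose_area)) return(spots$dose_area)
  recomb <- if (arm == "UHDR") model$recomb_factor else 1.0
  spots$mu * model$dose_cal * recomb
}

#' Reconstruct the 2D dose map from spots
#'
#' Sums each spot's weighted bivariate Gaussian (unit-integral density times
#' the spot's dose-area) across the entire grid, with no tail cutoff.  The
#' grid integral (sum of values times spacing squared) equals the total
#' dose-area up to the Gaussian mass falling outside the grid.
#'
#' @param spots A `spot_records` data frame (from [segment_spots()] or a
#'   ground truth).
#' @param grid A [dose_grid()] supplying the geometry (values ignored).
#' @param model A [beam_model()] (used when `spots` lacks a `dose_area`
#'   column).
#' @param arm `"CONV"` or `"UHDR"` (idem).
#' @return A [dose_grid()] of the reconstructed dose in Gy.
#' @export
reconstruct_dose_map <- function(spots, grid, model, arm = "CONV") {
  if (grid$spacing <= 0) stop("grid spacing must be positive")
  if (nrow(spots) > 0 && grid$spacing > min(spots$sigma_u, spots$sigma_t) / 2) {
    warning("grid spacing exceeds half the smallest beam width; map may be undersampled")
  }
  w <- spot_weights(spots, model, arm)
  vals <- gaussian_sum(spots$u, spots$t, spots$sigma_u, spots$sigma_t, w, grid)
  dose_grid(vals, grid$origin, grid$spacing)
}

#' Per-voxel cumulative dose over time
#'
#' Builds the temporal evolution of the 2D dose map.  In the default
#' `"spot-termination"` mode each spot's full dose accrues as a single step
#' at the spot's termination time; in `"sample-resolved"` mode (requires the
#' log) each spot's dose accrues in proportion to its per-sample monitor
#' increments, giving a piecewise-linear cumulative curve.  The final value
#' equals [reconstruct_dose_map()] at every voxel.
#'
#' @param spots A `spot_records` data frame.
#' @param grid A [dose_grid()] geometry.
#' @param model A [beam_model()].
#' @param mode `"spot-termination"` or `"sample-resolved"`.
#' @param log The source [delivery_log()]; required for sample-resolved
#'   mode.
#' @param arm `"CONV"` or `"UHDR"` (used when `spots` lacks `dose_area`).
#' @return Object of class `cumulative_dose`: breakpoint `times` (ms), the
#'   per-spot accrual-fraction matrix, per-spot dose maps, and the final
#'   [dose_grid()].  Query it with [cumulative_dose_at()] or feed it to
#'   [pbs_average_dose_rate_map()].
#' @export
cumulative_dose <- function(spots, grid, model,
                            mode = c("spot-termination", "sample-resolved"),
                            log = NULL, arm = "CONV") {
  mode <- match.arg(mode)
  if (mode == "sample-resolved" && is.null(log)) {
    stop("sample-resolved mode requires the delivery log")
  }
  if (nrow(spots) == 0) stop("no spots to accumulate")
  if (!is.null(log)) arm <- log$arm
  w <- spot_weights(spots, model, arm)
  ax <- grid_axes(grid)
  n_vox <- length(ax$u) * length(ax$t)
  S <- matrix(0, nrow(spots), n_vox)
  for (i in seq_len(nrow(spots))) {
    S[i, ] <- as.vector(gaussian_sum(spots$u[i], spots$t[i], spots$sigma_u[i],
                                     spots$sigma_t[i], w[i], grid))
  }
  if (mode == "spot-termination") {
    times <- c(min(spots$t_start), sort(unique(spots$t_end)))
    F <- vapply(seq_len(nrow(spots)),
                function(i) as.numeric(spots$t_end[i] <= times),
                numeric(length(times)))
  } else {
    s <- log$samples
    lo <- max(1L, which(s$t_ms >= min(spots$t_start))[1] - 1L)
    hi <- min(nrow(s), which(s$t_ms >= max(spots$t_end))[1] + 1L)
    if (is.na(hi)) hi <- nrow(s)
    times <- s$t_ms[lo:hi]
    mon <- s$mon1[lo:hi]
    F <- vapply(seq_len(nrow(spots)), function(i) {
      k <- which(s$t_ms <= spots$t_start[i])
      m0 <- if (length(k) > 0) s$mon1[max(k)] else 0
      pmin(pmax((mon - m0) / spots$mu[i], 0), 1)
    }, numeric(length(times)))
  }
  F <- matrix(F, nrow = length(times))
  final <- dose_grid(matrix(colSums(S), length(ax$u), length(ax$t)),
                     grid$origin, grid$spacing)
  structure(list(times = times, frac = F, spot_maps = S, final = final,
                 mode = mode, origin = grid$origin, spacing = grid$spacing,
                 dim = dim(final$values)),
            class = "cumulative_dose")
}

#' Cumulative dose map at a time point
#' @param cum A [cumulative_dose()] structure.
#' @param t Time in ms.
#' @return A [dose_grid()] of the dose accrued by time `t`.
#' @export
cumulative_dose_at <- function(cum, t) {
  f <- vapply(seq_len(ncol(cum$frac)), function(i) {
    if (cum$mode == "spot-termination") {
      # right-continuous step: full dose at and after the termination time
      if (t < cum$times[1]) 0 else
        cum$frac[max(which(cum$times <= t)), i]
    } else {
      approx(cum$times, cum$frac[, i], xout = t, rule = 2, ties = "ordered")$y
    }
  }, numeric(1))
  vals <- as.vector(t(f) %*% cum$spot_maps)
  dose_grid(matrix(pmax(vals, 0), cum$dim[1], cum$dim[2]), cum$origin, cum$spacing)
}

# First times at which the non-decreasing columns of C reach thresholds thr.
# C: n_times x n_vox; thr: length n_vox. Returns times (ms).
first_crossing <- function(times, C, thr, interpolate) {
  n <- length(times)
  below <- sweep(C, 2, thr, "<")
  k <- colSums(below) + 1L
  k[k > n] <- n
  t_cross <- times[k]
  if (interpolate) {
    kk <- which(k > 1)
    if (length(kk) > 0) {
      i <- k[kk]
      c_hi <- C[cbind(i, kk)]
      c_lo <- C[cbind(i - 1L, kk)]
      denom <- c_hi - c_lo
      frac <- ifelse(denom > 0, (thr[kk] - c_lo) / denom, 0)
      t_cross[kk] <- times[i - 1L] + frac * (times[i] - times[i - 1L])
    }
  }
  t_cross
}

#' PBS-average (Folkerts) dose-rate map
#'
#' For each voxel with final dose above the dose floor, finds the times at
#' which the cumulative dose first reaches `lower_frac` and `upper_frac` of
#' the voxel's total dose and reports
#' `(upper_frac - lower_frac) * D_v / (t_hi - t_lo)`.
#'
#' The default `"sample-crossing"` threshold mode takes the stored event or
#' sample times without interpolation, which reproduces the sharp
#' neighbouring-voxel variation seen in log-file dose-rate maps when a
#' threshold falls just before or after a beam-off plateau.
#' `"interpolated"` mode locates the crossings by linear interpolation on
#' the cumulative curve and is the numerically stable alternative.
#'
#' @param cum A [cumulative_dose()] structure.
#' @param lower_frac,upper_frac Dose-level fractions (defaults 0.05, 0.95).
#' @param threshold_mode `"sample-crossing"` or `"interpolated"`.
#' @param dose_floor Validity floor as a fraction of the map maximum
#'   (default 0.01): Gaussian-tail voxels below it carry no meaningful
#'   rate.
#' @return A [dose_rate_grid()]; degenerate voxels (zero-length window) are
#'   marked invalid with a reason rather than raising.
#' @export
pbs_average_dose_rate_map <- function(cum, lower_frac = 0.05, upper_frac = 0.95,
                                      threshold_mode = c("sample-crossing",
                                                         "interpolated"),
                                      dose_floor = 0.01) {
  threshold_mode <- match.arg(threshold_mode)
  interp <- threshold_mode == "interpolated"
  D <- as.vector(cum$final$values)
  if (max(D) <= 0) stop("cumulative structure carries no dose")
  floor_gy <- dose_floor * max(D)
  valid <- D >= floor_gy
  if (!any(valid)) stop("no voxel above the dose floor")

  n_vox <- length(D)
  t_lo <- t_hi <- rep(NA_real_, n_vox)
  idx_valid <- which(valid)
  block <- 2000L
  for (b in split(idx_valid, ceiling(seq_along(idx_valid) / block))) {
    C <- cum$frac %*% cum$spot_maps[, b, drop = FALSE]
    t_lo[b] <- first_crossing(cum$times, C, lower_frac * D[b], interp)
    t_hi[b] <- first_crossing(cum$times, C, upper_frac * D[b], interp)
  }
  dt_s <- (t_hi - t_lo) / 1000
  rate <- rep(NA_real_, n_vox)
  reason <- matrix("", cum$dim[1], cum$dim[2])
  reason[!valid] <- "below dose floor"
  degenerate <- valid & !is.na(dt_s) & dt_s <= 0
  reason[degenerate] <- "degenerate time window"
  ok <- valid & !degenerate
  rate[ok] <- (upper_frac - lower_frac) * D[ok] / dt_s[ok]
  dose_rate_grid(matrix(rate, cum$dim[1], cum$dim[2]), cum$origin, cum$spacing,
                 valid_mask = matrix(ok, cum$dim[1], cum$dim[2]),
                 invalid_reason = reason)
}

#' Point dose and PBS-average dose rate from a detector current trace
#'
#' Converts a 1 kHz detector current readout to accumulated charge
#' (rectangle rule), then to dose, and computes the PBS-average dose rate
#' between the 5% and 95% cumulative-dose levels (interpolated crossings).
#'
#' @param t_ms Sample times, ms.
#' @param current Detector current, A (non-negative).
#' @param charge_to_dose Calibration, Gy per coulomb.
#' @param lower_frac,upper_frac Dose-level fractions.
#' @return List with `dose` (Gy), `dose_rate` (Gy/s, `NA` if undefined) and
#'   `valid`.
#' @export
point_dose_rate_from_trace <- function(t_ms, current, charge_to_dose,
                                       lower_frac = 0.05, upper_frac = 0.95) {
  if (length(t_ms) == 0) stop("empty trace")
  if (any(current < 0)) stop("currents must be non-negative")
  dt_ms <- if (length(t_ms) > 1) median(diff(t_ms)) else 1.0
  cum <- cumsum(current * dt_ms / 1000) * charge_to_dose  # A*s*Gy/C = Gy
  dose <- cum[length(cum)]
  if (dose <= 0) {
    return(list(dose = 0, dose_rate = NA_real_, valid = FALSE))
  }
  times <- c(t_ms[1] - dt_ms, t_ms)
  C <- matrix(c(0, cum), ncol = 1)
  t_lo <- first_crossing(times, C, lower_frac * dose, TRUE)
  t_hi <- first_crossing(times, C, upper_frac * dose, TRUE)
  if (t_hi <= t_lo) {
    return(list(dose = dose, dose_rate = NA_real_, valid = FALSE))
  }
  list(dose = dose,
       dose_rate = (upper_frac - lower_frac) * dose / ((t_hi - t_lo) / 1000),
       valid = TRUE)
}

#' Detect delivery pauses in a log
#'
#' Classifies beam-off runs inside the beam-on envelope: runs no longer
#' than `max_dead_time` are ordinary spot changes; longer runs are
#' interruptions (documented interlocks).  Leading and trailing idle time is
#' ignored.  For a UHDR delivery any interruption sets the
#' exclusion-recommended flag (trial protocol: an interlock during a UHDR
#' treatment excludes the patient from that arm).
#'
#' @param log A validated [delivery_log()].
#' @param max_dead_time ms (default 11 ms row change + 2 samples margin).
#' @param beam_on_threshold MU per sample; default as in [segment_spots()].
#' @return List with `events` (data frame: `t_start`, `duration`,
#'   `during_beam`, `classification`) and `exclusion_recommended`.
#' @export
detect_pauses <- function(log, max_dead_time = DEAD_TIME_T_MS + 2,
                          beam_on_threshold = NULL) {
  s <- log$samples
  empty <- data.frame(t_start = numeric(), duration = numeric(),
                      during_beam = logical(), classification = character())
  inc <- monitor_increments(log)
  pos_inc <- inc[inc > 0]
  if (length(pos_inc) == 0) {
    return(list(events = empty, exclusion_recommended = FALSE))
  }
  thr <- beam_on_threshold %||% (0.5 * median(pos_inc))
  on <- inc > thr
  on_idx <- which(on)
  first_on <- on_idx[1]
  last_on <- on_idx[length(on_idx)]
  r <- rle(on[first_on:last_on])
  ends <- cumsum(r$lengths) + first_on - 1L
  starts <- ends - r$lengths + 1L
  off <- !r$values
  if (!any(off)) {
    return(list(events = empty, exclusion_recommended = FALSE))
  }
  period <- log$sample_period
  events <- data.frame(
    t_start = s$t_ms[starts[off]] - period,
    duration = r$lengths[off] * period,
    during_beam = TRUE,
    classification = ifelse(r$lengths[off] * period <= max_dead_time,
                            "spot-change", "interruption")
  )
  excl <- log$arm == "UHDR" && any(events$classification == "interruption")
  list(events = events, exclusion_recommended = excl)
}
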