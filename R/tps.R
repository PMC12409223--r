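# Spot records implied by a simplified plan: constant (angle-averaged)
# widths, equal MU, timeline from the constant-intensity delivery model.
tps_spots <- function(plan) {
  pos <- plan_spot_positions(plan)
  tl <- tps_delivery_timeline(plan)
  res <- data.frame(index = seq_len(nrow(pos)),
                    t_start = tl$t_start, t_end = tl$t_end,
                    u = pos$u, t = pos$t,
                    sigma_u = plan$mean_sigma[1], sigma_t = plan$mean_sigma[2],
                    mu = plan$mu_per_spot,
                    dose_area = plan$mu_per_spot * plan$dose_cal,
                    contains_pause = FALSE)
  class(res) <- c("spot_records", "data.frame")
  res
}

#' TPS dose map of a simplified plan
#'
#' Same Gaussian-sum model as [reconstruct_dose_map()], but with the plan's
#' constant beam width and spot weight, and with each spot's tails truncated
#' at `cutoff * sigma` (the TPS uses a beam-spread cutoff to bound
#' computation; at the default 4 sigma the truncated mass is exp(-8), below
#' 0.04% per spot).
#'
#' @param plan A [simple_plan()].
#' @param grid A [dose_grid()] geometry.
#' @param cutoff Truncation radius in units of sigma (default 4).
#' @return A [dose_grid()] in Gy.
#' @export
tps_dose_map <- function(plan, grid, cutoff = 4) {
  if (grid$spacing <= 0) stop("grid spacing must be positive")
  sp <- tps_spots(plan)
  vals <- gaussian_sum(sp$u, sp$t, sp$sigma_u, sp$sigma_t, sp$dose_area,
                       grid, cutoff = cutoff)
  dose_grid(vals, grid$origin, grid$spacing)
}

# Piecewise-linear cumulative-dose structure for a plan: each spot's dose
# accrues uniformly during its beam-on interval and is flat during dead
# times.  Nodes at every spot start/end make per-voxel interpolation exact.
tps_cumulative <- function(plan, grid, cutoff = 4) {
  sp <- tps_spots(plan)
  ax <- grid_axes(grid)
  n_vox <- length(ax$u) * length(ax$t)
  S <- matrix(0, nrow(sp), n_vox)
  for (i in seq_len(nrow(sp))) {
    S[i, ] <- as.vector(gaussian_sum(sp$u[i], sp$t[i], sp$sigma_u[i],
                                     sp$sigma_t[i], sp$dose_area[i], grid,
                                     cutoff = cutoff))
  }
  times <- sort(unique(c(sp$t_start, sp$t_end)))
  dur <- sp$t_end - sp$t_start
  F <- vapply(seq_len(nrow(sp)), function(i) {
    pmin(pmax((times - sp$t_start[i]) / dur[i], 0), 1)
  }, numeric(length(times)))
  F <- matrix(F, nrow = length(times))
  final <- dose_grid(matrix(colSums(S), length(ax$u), length(ax$t)),
                     grid$origin, grid$spacing)
  structure(list(times = times, frac = F, spot_maps = S, final = final,
                 mode = "sample-resolved", origin = grid$origin,
                 spacing = grid$spacing, dim = dim(final$values)),
            class = "cumulative_dose")
}

#' TPS-side PBS-average dose-rate map
#'
#' Cumulative dose per voxel accrues linearly during each spot's beam-on
#' interval and is flat during dead times; the 5%/95% crossing times are
#' located by exact linear interpolation on this piecewise-linear curve, so
#' the resulting map is smooth across neighbouring voxels (no
#' sample-crossing artifact).
#'
#' @param plan A [simple_plan()].
#' @param grid A [dose_grid()] geometry.
#' @param cutoff Beam-spread truncation in sigma units.
#' @param lower_frac,upper_frac Dose-level fractions.
#' @param dose_floor Validity floor, fraction of map maximum.
#' @return A [dose_rate_grid()] in Gy/s.
#' @export
tps_pbs_dose_rate_map <- function(plan, grid, cutoff = 4,
                                  lower_frac = 0.05, upper_frac = 0.95,
                                  dose_floor = 0.01) {
  cum <- tps_cumulative(plan, grid, cutoff)
  pbs_average_dose_rate_map(cum, lower_frac, upper_frac,
                            threshold_mode = "interpolated",
                            dose_floor = dose_floor)
}

#' Dose-averaged dose-rate map of a plan
#'
#' Per voxel, the dose-weighted mean of the instantaneous spot dose rates:
#' `DADR_v = sum_i d_iv * r_i / sum_i d_iv`, with `r_i = d_iv / (beam-on
#' duration of spot i)`.  Unlike the PBS-average rate it depends only on
#' beam-on durations, so dead times and pauses leave it unchanged.
#'
#' @inheritParams tps_pbs_dose_rate_map
#' @return A [dose_rate_grid()] in Gy/s.
#' @export
dose_averaged_dose_rate_map <- function(plan, grid, cutoff = 4,
                                        dose_floor = 0.01) {
  sp <- tps_spots(plan)
  ax <- grid_axes(grid)
  n_vox <- length(ax$u) * length(ax$t)
  num <- den <- numeric(n_vox)
  dur_s <- (sp$t_end - sp$t_start) / 1000
  for (i in seq_len(nrow(sp))) {
    d <- as.vector(gaussian_sum(sp$u[i], sp$t[i], sp$sigma_u[i], sp$sigma_t[i],
                                sp$dose_area[i], grid, cutoff = cutoff))
    num <- num + d^2 / dur_s[i]
    den <- den + d
  }
  valid <- den >= dose_floor * max(den)
  vals <- rep(NA_real_, n_vox)
  vals[valid] <- num[valid] / den[valid]
  reason <- matrix("", length(ax$u), length(ax$t))
  reason[!valid] <- "below dose floor"
  dose_rate_grid(matrix(vals, length(ax$u), length(ax$t)), grid$origin,
                 grid$spacing, valid_mask = matrix(valid, length(ax$u),
                                                   length(ax$t)),
                 invalid_reason = reason)
}
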