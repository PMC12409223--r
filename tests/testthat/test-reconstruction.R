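spot_df <- function(u, t, sigma_u = 3.5, sigma_t = 3.5, mu = 1,
                    t_start = 0, t_end = 10) {
  df <- data.frame(index = seq_along(u), t_start = t_start, t_end = t_end,
                   u = u, t = t, sigma_u = sigma_u, sigma_t = sigma_t,
                   mu = mu, contains_pause = FALSE)
  class(df) <- c("spot_records", "data.frame")
  df
}

test_that("dose map matches the bivariate Gaussian closed form and is linear", {
  model <- default_beam_model(sigma_u = 3, sigma_t = 3, dose_cal = 1)
  grid <- empty_grid(c(-15, 15), c(-15, 15), 0.5)
  one <- spot_df(0, 0, sigma_u = 3, sigma_t = 3, mu = 1)
  m1 <- reconstruct_dose_map(one, grid, model)
  expect_equal(max(m1$values), 1 / (2 * pi * 9), tolerance = 1e-12)

  two <- spot_df(c(0, 0), c(0, 0), sigma_u = 3, sigma_t = 3, mu = 1)
  m2 <- reconstruct_dose_map(two, grid, model)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)

  a <- spot_df(c(-5, 0), c(0, 2), sigma_u = 3, sigma_t = 3, mu = c(2, 1))
  b <- spot_df(c(4, 1), c(-3, 0), sigma_u = 3, sigma_t = 3, mu = c(1, 3))
  ab <- rbind(a, b); ab$index <- seq_len(4)
  class(ab) <- c("spot_records", "data.frame")
  expect_equal(reconstruct_dose_map(ab, grid, model)$values,
               reconstruct_dose_map(a, grid, model)$values +
                 reconstruct_dose_map(b, grid, model)$values,
               tolerance = 1e-12)
})

test_that("grid integral conserves total dose-area within 0.5% at 4-sigma margins", {
  model <- default_beam_model()
  pos <- expand.grid(u = seq(-10, 10, by = 5), t = seq(-10, 10, by = 5))
  spots <- spot_df(pos$u, pos$t, mu = 100)
  grid <- empty_grid(c(-30, 30), c(-30, 30), 1)  # >= 4 sigma beyond the spots
  dmap <- reconstruct_dose_map(spots, grid, model)
  integral <- sum(dmap$values) * dmap$spacing^2
  total <- sum(spots$mu) * model$dose_cal
  expect_lt(abs(integral - total) / total, 0.005)
})

test_that("cumulative dose steps at spot termination and matches the static map", {
  model <- default_beam_model(dose_cal = 1)
  grid <- empty_grid(c(-10, 10), c(-10, 10), 1)
  spots <- spot_df(c(0, 0), c(0, 0), mu = 1, t_start = c(0, 20),
                   t_end = c(10, 30))
  cum <- cumulative_dose(spots, grid, model)
  static <- reconstruct_dose_map(spots, grid, model)
  expect_equal(cumulative_dose_at(cum, 1e6)$values, static$values,
               tolerance = 1e-12)
  # single step at t_end; halfway between the two ends -> exactly 50%
  expect_equal(cumulative_dose_at(cum, 9.9)$values,
               matrix(0, 21, 21))
  expect_equal(cumulative_dose_at(cum, 20)$values, static$values / 2,
               tolerance = 1e-12)

  # sample-resolved final agrees too
  plan <- simple_plan(nu = 2, nt = 2, mu_per_spot = 100, intensity = 1e4,
                      u_start = -5, t_start = -5, du = 10, dt = 10)
  sim <- simulate_delivery(plan, default_beam_model(), seed = 1)
  sp <- segment_spots(sim$log, default_beam_model())
  cum2 <- cumulative_dose(sp, grid, default_beam_model(),
                          mode = "sample-resolved", log = sim$log)
  expect_equal(cum2$final$values,
               reconstruct_dose_map(sp, grid, default_beam_model())$values,
               tolerance = 1e-12)
  expect_error(cumulative_dose(sp, grid, model, mode = "sample-resolved"),
               "requires the delivery log")
})

test_that("constant-rate delivery yields PBS-average rate equal to dose/time", {
  model <- default_beam_model()
  plan <- simple_plan(nu = 1, nt = 1, mu_per_spot = 100, intensity = 1e4)
  sim <- simulate_delivery(plan, model, seed = 1)
  sp <- segment_spots(sim$log, model)
  grid <- empty_grid(c(-10, 10), c(-10, 10), 1)
  cum <- cumulative_dose(sp, grid, model, mode = "sample-resolved", log = sim$log)
  rate <- pbs_average_dose_rate_map(cum, threshold_mode = "interpolated")
  D <- cum$final$values
  T_s <- 100 / 1e4  # 10 ms beam-on
  expect_equal(rate$values[rate$valid_mask],
               (D / T_s)[rate$valid_mask], tolerance = 1e-9)
})

test_that("point trace dose/rate closed forms hold", {
  # constant 2 nA for 500 ms at 10 Gy/nC
  res <- point_dose_rate_from_trace(1:500, rep(2e-9, 500), 1e10)
  expect_equal(res$dose, 10.0, tolerance = 1e-12)
  expect_equal(res$dose_rate, 20.0, tolerance = 1e-9)

  # 5 Gy in 50 ms, 100 ms pause, 5 Gy in 50 ms -> 9 Gy / 190 ms
  cur <- c(rep(1e-9, 50), rep(0, 100), rep(1e-9, 50))
  res2 <- point_dose_rate_from_trace(1:200, cur, 1e11)
  expect_equal(res2$dose, 10.0, tolerance = 1e-12)
  expect_equal(res2$dose_rate, 9 / 0.190, tolerance = 1e-9)

  expect_equal(point_dose_rate_from_trace(1:100, rep(0, 100), 1e10)$valid, FALSE)
  expect_error(point_dose_rate_from_trace(numeric(), numeric(), 1), "empty")
})

test_that("point trace agrees with the voxel-wise sample-resolved rate", {
  model <- default_beam_model()
  plan <- random_plan(8)
  sim <- simulate_delivery(plan, model, seed = 8)
  sp <- segment_spots(sim$log, model)
  grid <- empty_grid(c(-6, 6), c(-6, 6), 2)
  cum <- cumulative_dose(sp, grid, model, mode = "sample-resolved", log = sim$log)
  rate <- pbs_average_dose_rate_map(cum, threshold_mode = "interpolated")
  # voxel at the grid center
  v <- which(as.vector(row(rate$values) == 4 & col(rate$values) == 4))
  cumv <- as.vector(cum$frac %*% cum$spot_maps[, v])
  dt_s <- diff(cum$times[1:2]) / 1000
  inc <- diff(c(0, cumv))
  res <- point_dose_rate_from_trace(cum$times, inc / dt_s, 1)
  expect_equal(res$dose_rate, rate$values[4, 4], tolerance = 1e-9)
})

test_that("interpolated rates equal a brute-force cumulative-series scan", {
  model <- default_beam_model()
  for (seed in 1:10) {
    plan <- random_plan(seed)
    sim <- simulate_delivery(plan, model, seed = seed + 100)
    sp <- segment_spots(sim$log, model)
    grid <- empty_grid(c(-8, 8), c(-8, 8), 4)
    cum <- cumulative_dose(sp, grid, model, mode = "sample-resolved",
                           log = sim$log)
    rate <- pbs_average_dose_rate_map(cum, threshold_mode = "interpolated")
    C <- cum$frac %*% cum$spot_maps
    for (v in which(as.vector(rate$valid_mask))) {
      expect_equal(rate$values[v], oracle_pbs_rate(cum$times, C[, v]),
                   tolerance = 1e-9)
    }
  }
})

test_that("pauses never increase any voxel's PBS-average dose rate", {
  model <- default_beam_model()
  plan <- random_plan(4)
  sim <- simulate_delivery(plan, model, seed = 4)
  grid <- empty_grid(c(-12, 12), c(-12, 12), 2)
  rate_of <- function(log) {
    sp <- segment_spots(log, model)
    cum <- cumulative_dose(sp, grid, model, mode = "sample-resolved", log = log)
    pbs_average_dose_rate_map(cum, threshold_mode = "interpolated")
  }
  base <- rate_of(sim$log)
  for (at in quantile(sim$truth$spots$t_start + 2, c(0.2, 0.6, 0.9))) {
    sp_ok <- any(sim$truth$spots$t_start < at & at < sim$truth$spots$t_end)
    if (!sp_ok) next
    paused <- inject_pause(sim$log, sim$truth, at = at, duration = 40)
    pr <- rate_of(paused$log)
    # the dose map itself is unchanged
    expect_equal(pr$values[pr$valid_mask & base$valid_mask] <=
                   base$values[pr$valid_mask & base$valid_mask] + 1e-9,
                 rep(TRUE, sum(pr$valid_mask & base$valid_mask)))
  }
})

test_that("a pause leaves the reconstructed dose map unchanged", {
  model <- default_beam_model()
  plan <- random_plan(6)
  sim <- simulate_delivery(plan, model, seed = 6)
  grid <- empty_grid(c(-15, 15), c(-15, 15), 1)
  mid <- mean(unlist(sim$truth$spots[2, c("t_start", "t_end")]))
  paused <- inject_pause(sim$log, sim$truth, at = mid, duration = 50)
  m0 <- reconstruct_dose_map(segment_spots(sim$log, model), grid, model)
  m1 <- reconstruct_dose_map(segment_spots(paused$log, model), grid, model)
  expect_equal(m1$values, m0$values, tolerance = 1e-12)
})

test_that("spot segmentation flags mid-spot pauses and handles empty logs", {
  model <- default_beam_model()
  plan <- random_plan(9)
  sim <- simulate_delivery(plan, model, seed = 9)
  mid <- mean(unlist(sim$truth$spots[5, c("t_start", "t_end")]))
  paused <- inject_pause(sim$log, sim$truth, at = mid, duration = 50)
  sp <- segment_spots(paused$log, model)
  expect_equal(nrow(sp), nrow(sim$truth$spots))
  expect_equal(which(sp$contains_pause), 5L)
  expect_equal(sp$mu, sim$truth$spots$mu, tolerance = 1e-9)

  empty <- delivery_log("E", 90, 0, "CONV",
                        data.frame(t_ms = 0:9, mon1 = 0, mon2 = 0,
                                   hallU = 0, hallT = 0))
  expect_equal(nrow(segment_spots(empty, model)), 0)
})

test_that("pause detection classifies dead times vs interruptions", {
  model <- default_beam_model()
  plan <- random_plan(2, arm = "UHDR")
  sim <- simulate_delivery(plan, model, seed = 2)
  clean <- detect_pauses(sim$log)
  expect_true(all(clean$events$classification == "spot-change"))
  expect_false(clean$exclusion_recommended)

  mid <- mean(unlist(sim$truth$spots[3, c("t_start", "t_end")]))
  paused <- inject_pause(sim$log, sim$truth, at = mid, duration = 50)
  det <- detect_pauses(paused$log)
  ints <- det$events[det$events$classification == "interruption", ]
  expect_equal(nrow(ints), 1)
  expect_equal(ints$duration, 50)
  expect_lt(abs(ints$t_start - mid), 2)
  expect_true(det$exclusion_recommended)  # UHDR arm

  conv <- sim$log; conv$arm <- "CONV"
  paused_conv <- inject_pause(conv, sim$truth, at = mid, duration = 50)
  expect_false(detect_pauses(paused_conv$log)$exclusion_recommended)
})

test_that("degenerate single-step voxels are marked invalid, not infinite", {
  model <- default_beam_model(dose_cal = 1)
  grid <- empty_grid(c(-5, 5), c(-5, 5), 1)
  one <- spot_df(0, 0, mu = 1, t_start = 0, t_end = 10)
  cum <- cumulative_dose(one, grid, model)  # spot-termination: single step
  rate <- pbs_average_dose_rate_map(cum, threshold_mode = "sample-crossing")
  expect_false(any(rate$valid_mask))
  expect_true(all(rate$invalid_reason[rate$invalid_reason != "below dose floor"] ==
                    "degenerate time window"))
})
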