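five_spot_image <- function(offsets_u = 0, offsets_t = 0, sigma = c(3.0, 3.2),
                            sigma_scale = 1, amp = 1, noise_sd = 0, seed = NULL) {
  nom <- five_spot_nominal()
  grid <- empty_grid(c(-55, 55), c(-55, 55), 1)
  centers <- data.frame(u = nom$u + offsets_u, t = nom$t + offsets_t)
  img <- gaussian_image(centers,
                        matrix(rep(sigma * sigma_scale, each = 5), ncol = 2),
                        rep(amp, 5), grid)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- img$values + rnorm(length(img$values), 0, noise_sd * amp)
    img <- dose_grid(pmax(v, 0), img$origin, img$spacing)
  }
  img
}

test_that("2D Gaussian fit recovers exact and noisy synthetic spots", {
  grid <- empty_grid(c(-15, 25), c(-25, 15), 0.5)
  img <- gaussian_image(data.frame(u = 5, t = -5),
                        matrix(c(3.0, 3.2), 1), 2.5, grid, background = 0.1)
  fit <- fit_spot_2d_gaussian(img)
  expect_equal(unname(fit$center), c(5, -5), tolerance = 1e-6)
  expect_equal(unname(fit$sigma), c(3.0, 3.2), tolerance = 1e-6)
  expect_equal(fit$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(fit$background, 0.1, tolerance = 1e-6)

  # 1% amplitude Gaussian noise: center recovered within 0.05 mm (sd)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    v <- img$values + rnorm(length(img$values), 0, 0.01 * 2.5)
    f <- fit_spot_2d_gaussian(dose_grid(pmax(v, 0), img$origin, img$spacing))
    unname(f$center[1]) - 5
  }, numeric(1))
  expect_lt(sd(errs), 0.05)
  expect_lt(abs(mean(errs)), 0.02)

  expect_error(fit_spot_2d_gaussian(dose_grid(matrix(1, 10, 10), c(0, 0), 1)),
               "flat")
  edge <- gaussian_image(data.frame(u = -15, t = 0),
                         matrix(c(3, 3), 1), 1, grid)
  expect_error(fit_spot_2d_gaussian(edge), "border")
})

test_that("five-spot analysis flags offsets and size drifts per tolerance", {
  ref_sizes <- c(3.0, 3.2)

  shifted <- analyze_five_spot(five_spot_image(offsets_u = 1.5),
                               reference_sizes = ref_sizes)
  expect_true(shifted$pass)
  expect_equal(unname(shifted$suggested_correction), c(-1.5, 0),
               tolerance = 1e-4)

  one_off <- five_spot_image()
  img2 <- five_spot_image(offsets_u = c(2.5, 0, 0, 0, 0))
  res2 <- analyze_five_spot(img2, reference_sizes = ref_sizes)
  expect_false(res2$position_pass)
  expect_false(res2$pass)
  expect_equal(which(!res2$spots$position_pass), 1L)

  res3 <- analyze_five_spot(five_spot_image(sigma_scale = 1.12),
                            reference_sizes = ref_sizes)
  expect_true(res3$position_pass)
  expect_false(res3$size_pass)

  # +8% size drift stays within the 10% tolerance
  res4 <- analyze_five_spot(five_spot_image(sigma_scale = 1.08),
                            reference_sizes = ref_sizes)
  expect_true(res4$pass)
})

test_that("applying the suggested five-spot correction is idempotent", {
  img <- five_spot_image(offsets_u = 1.2, offsets_t = -0.8)
  res <- analyze_five_spot(img, reference_sizes = c(3.0, 3.2))
  corrected <- translate_grid(img, res$suggested_correction[["u"]],
                              res$suggested_correction[["t"]])
  res2 <- analyze_five_spot(corrected, reference_sizes = c(3.0, 3.2))
  expect_lt(max(abs(res2$suggested_correction)), 0.02)
})

test_that("central dose check scales only outside the 5% window", {
  r <- central_dose_check(11.0, 11.0)
  expect_equal(r$ratio, 1.0)
  expect_null(r$scaling)

  r2 <- central_dose_check(10.3, 11.0)
  expect_equal(r2$ratio, 0.9364, tolerance = 1e-4)
  expect_equal(r2$scaling, 1.0680, tolerance = 1e-4)

  r3 <- central_dose_check(10.7, 11.0)
  expect_null(r3$scaling)
  expect_error(central_dose_check(10, 0), "positive")

  # re-check after scaling passes exactly
  for (m in c(7.3, 10.3, 12.9)) {
    cd <- central_dose_check(m, 11.0)
    if (!is.null(cd$scaling)) {
      expect_equal(central_dose_check(m * cd$scaling, 11.0)$ratio, 1.0,
                   tolerance = 1e-12)
    }
  }
})

test_that("boosting factor appears only beyond 3% mean deviation", {
  ref <- five_spot_image()
  mk <- function(f) dose_grid(ref$values * f, ref$origin, ref$spacing)
  b1 <- boosting_check(ref, mk(0.96))
  expect_equal(b1$mean_deviation, -4, tolerance = 1e-9)
  expect_equal(b1$boosting, 1 / 0.96, tolerance = 1e-9)
  expect_null(boosting_check(ref, mk(0.98))$boosting)
  b3 <- boosting_check(ref, ref)
  expect_equal(b3$mean_deviation, 0)
  expect_null(b3$boosting)
})

test_that("UHDR dose-rate floor is strict", {
  expect_true(uhdr_dose_rate_check(c(55.6, 47.4, 52.0))$pass)
  r <- uhdr_dose_rate_check(c(45.0, 38.0))
  expect_false(r$pass)
  expect_equal(r$failing_positions, 2L)
  expect_false(uhdr_dose_rate_check(40.0)$pass)  # "above" means strictly
  expect_error(uhdr_dose_rate_check(numeric()), "no dose-rate")
})

psqa_setup <- function(seed, model = default_beam_model(), plan = NULL) {
  plan <- plan %||% simple_plan(nu = 8, nt = 8, u_start = -8.75, t_start = -8.75,
                                mu_per_spot = 100, intensity = 1e4,
                                mean_sigma = c(3.5, 3.5), dose_cal = 0.02)
  sim <- simulate_delivery(plan, model, seed = seed)
  spots <- segment_spots(sim$log, model)
  grid <- empty_grid(c(-24, 24), c(-24, 24), 1)
  list(plan = plan,
       measured = reconstruct_dose_map(spots, grid, model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("PSQA on an unperturbed delivery passes without corrections", {
  s <- psqa_setup(1)
  dec <- run_psqa(s$plan, s$measured, default_beam_model(),
                  five_spot_image = five_spot_image(sigma = c(3.5, 3.5)))
  expect_equal(dec$status, "pass")
  expect_equal(unname(dec$offset_applied), c(0, 0))
  expect_equal(dec$scaling_factor, 1.0)
  expect_gt(dec$gamma$pass_fraction, 99)
})

test_that("PSQA self-consistency holds across random plans (property)", {
  model <- default_beam_model()
  for (seed in 1:20) {
    plan <- random_plan(seed)
    sim <- simulate_delivery(plan, model, seed = seed)
    spots <- segment_spots(sim$log, model)
    grid <- grid_for(spots, spacing = 1)
    measured <- reconstruct_dose_map(spots, grid, model)
    dec <- run_psqa(plan, measured, model)
    expect_equal(dec$status, "pass", info = paste("seed", seed))
  }
})

test_that("a global -4% output error yields pass-with-correction and boosting", {
  model_lo <- default_beam_model(dose_cal = 0.02 * 0.96)
  s <- psqa_setup(3, model = model_lo)
  dec <- run_psqa(s$plan, s$measured, default_beam_model())
  # -4% is within the 5% central-dose window but beyond the 3% mean deviation
  expect_equal(dec$status, "pass-with-correction")
  expect_equal(dec$boosting$boosting, 1 / 0.96, tolerance = 0.005)
})

test_that("a gross field shift drives the decision to clinical review", {
  model <- default_beam_model()
  plan <- simple_plan(nu = 8, nt = 8, u_start = -8.75, t_start = -8.75,
                      mu_per_spot = 100, intensity = 1e4)
  shifted_plan <- plan; shifted_plan$u_start <- plan$u_start + 5
  sim <- simulate_delivery(shifted_plan, model, seed = 5)
  spots <- segment_spots(sim$log, model)
  grid <- empty_grid(c(-24, 24), c(-24, 24), 1)
  measured <- reconstruct_dose_map(spots, grid, model)
  dec <- run_psqa(plan, measured, model)  # no five-spot image: shift uncorrected
  expect_lt(dec$gamma$pass_fraction, 90)
  expect_equal(dec$status, "clinical-review")
})

test_that("DQA compares against the PSQA-day measurement and flags UHDR interruptions", {
  model <- default_beam_model()
  s <- psqa_setup(7)
  dec <- run_dqa(s$measured, s$measured, model, center = c(0, 0))
  expect_equal(dec$status, "pass")
  expect_equal(dec$gamma$pass_fraction, 100)

  # small beam-size drift within spot tolerance: gamma may dip but passes
  drift_model <- default_beam_model(sigma_u = 3.5 * 1.08, sigma_t = 3.5 * 1.08)
  s8 <- psqa_setup(7, model = drift_model)
  dec8 <- run_dqa(s$measured, s8$measured, model, center = c(0, 0))
  expect_gt(dec8$gamma$pass_fraction, 90)
  expect_true(dec8$status %in% c("pass", "pass-with-correction"))

  # interrupted UHDR daily delivery propagates the exclusion recommendation
  plan <- random_plan(11, arm = "UHDR")
  sim <- simulate_delivery(plan, model, seed = 11)
  mid <- mean(unlist(sim$truth$spots[4, c("t_start", "t_end")]))
  paused <- inject_pause(sim$log, sim$truth, at = mid, duration = 60)
  spots <- segment_spots(paused$log, model)
  grid <- grid_for(spots, 1)
  daily <- reconstruct_dose_map(spots, grid, model, arm = "UHDR")
  ref <- reconstruct_dose_map(segment_spots(sim$log, model), grid, model,
                              arm = "UHDR")
  dec_u <- run_dqa(ref, daily, model, arm = "UHDR", log = paused$log,
                   monitor_dose = 10.0, reference_dose = 10.5)
  expect_true(dec_u$exclusion_recommended)
  expect_true(any(grepl("exclusion", dec_u$notes)))
})
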