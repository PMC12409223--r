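# Shared fixtures: all synthetic, generated in code at test time.

# small hand-valid log: linear monitor ramp, fixed Hall values
tiny_log <- function(n = 5, arm = "CONV") {
  delivery_log(
    field_id = "T1", gantry_angle = 90, couch_angle = 0, arm = arm,
    samples = data.frame(t_ms = seq(0, by = 1, length.out = n),
                         mon1 = seq(0, by = 0.5, length.out = n),
                         mon2 = seq(0, by = 0.5, length.out = n),
                         hallU = 0.1, hallT = -0.2)
  )
}

random_valid_log <- function(seed) {
  set.seed(seed)
  n <- sample(3:40, 1)
  inc <- runif(n, 0, 2) * rbinom(n, 1, 0.7)
  delivery_log(
    field_id = sprintf("R%03d", seed),
    gantry_angle = runif(1, 0, 360), couch_angle = runif(1, -90, 90),
    arm = sample(c("CONV", "UHDR"), 1),
    samples = data.frame(
      t_ms = round(seq(0, by = 1, length.out = n) / 0.1) * 0.1,
      mon1 = cumsum(inc), mon2 = cumsum(inc) * (1 + 1e-4),
      hallU = rnorm(n, 0, 0.3), hallT = rnorm(n, 0, 0.3)),
    annotations = if (seed %% 3 == 0) c("note A", "note B") else character()
  )
}

# random rectangular plan with 5-50 spots, centered at the origin,
# integer-ms beam-on duration (10 ms/spot at 100 MU and 1e4 MU/s)
random_plan <- function(seed, arm = "CONV") {
  set.seed(seed)
  repeat {
    nu <- sample(2:8, 1); nt <- sample(2:7, 1)
    if (nu * nt >= 5 && nu * nt <= 50) break
  }
  simple_plan(field_id = sprintf("P%03d", seed), gantry_angle = 90,
              u_start = -(nu - 1) * 2.5 / 2, t_start = -(nt - 1) * 2.5 / 2,
              du = 2.5, dt = 2.5, nu = nu, nt = nt,
              mu_per_spot = 100, mean_sigma = c(3.5, 3.5),
              dose_cal = 0.02, intensity = 1e4, arm = arm)
}

# realistic sensor-noise settings: Hall noise equivalent to `hall_mm` at the
# isocenter plane, monitor noise `monitor_frac` of a spot's MU (spread over
# its beam-on samples)
noise_settings <- function(plan, model, hall_mm = 0.2, monitor_frac = 0.001) {
  slope <- position_to_hall(hall_mm, "U", model) - position_to_hall(0, "U", model)
  n_on <- max(1, round(plan$mu_per_spot / plan$intensity * 1000))
  list(hall_sd = abs(slope),
       monitor_sd = monitor_frac * plan$mu_per_spot / sqrt(n_on))
}

# grid centered on the spots with a 4-sigma margin
grid_for <- function(spots, spacing = 1) {
  m <- 4 * max(spots$sigma_u, spots$sigma_t)
  empty_grid(c(floor(min(spots$u) - m), ceiling(max(spots$u) + m)),
             c(floor(min(spots$t) - m), ceiling(max(spots$t) + m)), spacing)
}

# synthetic image of Gaussian spots with explicit peak amplitudes
gaussian_image <- function(centers, sigmas, amplitudes, grid, background = 0) {
  ax <- flashqa:::grid_axes(grid)
  vals <- matrix(background, length(ax$u), length(ax$t))
  for (i in seq_len(nrow(centers))) {
    vals <- vals + amplitudes[i] *
      outer(exp(-(ax$u - centers$u[i])^2 / (2 * sigmas[i, 1]^2)),
            exp(-(ax$t - centers$t[i])^2 / (2 * sigmas[i, 2]^2)))
  }
  dose_grid(vals, grid$origin, grid$spacing)
}

# ---- independent oracles ---------------------------------------------------

# brute-force gamma: exhaustive search over the fine lattice with its own
# scalar bilinear interpolation; no pruning, no shared code path
oracle_gamma <- function(reference, test, dose_crit = 3, dta = 3,
                         mask_level = 0.9, search_factor = 3, fine_frac = 0.1) {
  ru <- reference$origin[1] + (seq_len(nrow(reference$values)) - 1) * reference$spacing
  rt <- reference$origin[2] + (seq_len(ncol(reference$values)) - 1) * reference$spacing
  d_max <- max(reference$values)
  tol <- dose_crit / 100 * d_max
  mask <- reference$values >= mask_level * d_max
  h <- reference$spacing * fine_frac
  n_off <- floor(search_factor * dta / h)
  offs <- expand.grid(du = (-n_off:n_off) * h, dv = (-n_off:n_off) * h)
  offs <- offs[offs$du^2 + offs$dv^2 <= (search_factor * dta)^2, ]
  # vectorized bilinear interpolation of the test map (own implementation,
  # out-of-grid points read as zero dose)
  bilin <- function(g, u, t) {
    nr <- nrow(g$values); nc <- ncol(g$values)
    fi <- (u - g$origin[1]) / g$spacing + 1
    fj <- (t - g$origin[2]) / g$spacing + 1
    inside <- fi >= 1 & fj >= 1 & fi <= nr + 1e-9 & fj <= nc + 1e-9
    i <- pmin(pmax(floor(fi), 1), nr - 1)
    j <- pmin(pmax(floor(fj), 1), nc - 1)
    a <- pmin(pmax(fi - i, 0), 1); b <- pmin(pmax(fj - j, 0), 1)
    out <- g$values[cbind(i, j)] * (1 - a) * (1 - b) +
      g$values[cbind(i + 1, j)] * a * (1 - b) +
      g$values[cbind(i, j + 1)] * (1 - a) * b +
      g$values[cbind(i + 1, j + 1)] * a * b
    out[!inside] <- 0
    out
  }
  dist_term <- (offs$du^2 + offs$dv^2) / dta^2
  gam <- matrix(NA_real_, nrow(reference$values), ncol(reference$values))
  for (k in which(mask)) {
    ij <- arrayInd(k, dim(mask))
    dv <- bilin(test, ru[ij[1]] + offs$du, rt[ij[2]] + offs$dv)
    gam[k] <- sqrt(min(dist_term + ((dv - reference$values[k]) / tol)^2))
  }
  gam
}

# brute-force per-voxel PBS-average rate: full scan of the cumulative time
# series with local linear interpolation of each crossing
oracle_pbs_rate <- function(times, cum_curve, lower = 0.05, upper = 0.95) {
  D <- cum_curve[length(cum_curve)]
  cross <- function(thr) {
    for (k in seq_along(cum_curve)) {
      if (cum_curve[k] >= thr) {
        if (k == 1) return(times[1])
        return(times[k - 1] + (thr - cum_curve[k - 1]) /
                 (cum_curve[k] - cum_curve[k - 1]) * (times[k] - times[k - 1]))
      }
    }
    times[length(times)]
  }
  t_lo <- cross(lower * D)
  t_hi <- cross(upper * D)
  (upper - lower) * D / ((t_hi - t_lo) / 1000)
}
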