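# Synthetic-data generator: occupancy chains, intensity/length trajectories,
# steady-state curves, QD tracks.

test_that("occupancy chain honours trivial limits", {
  # no ligand, no binding
  p0 <- sim_preset_named("r82a", concentration_nM = 0)
  occ <- simulate_occupancy(p0, duration = 5, seed = 1)
  expect_true(all(occ$values == 0L))

  # absorbing bound state: k_off = 0, c > 0, long run ends all-bound
  pa <- sim_preset_named("r82a", concentration_nM = 500, k_off = 0)
  occ <- simulate_occupancy(pa, duration = 60, seed = 1)
  expect_true(all(occ$values[nrow(occ$values), ] == 1L))

  expect_error(simulate_occupancy(p0, duration = -1), "duration")
})

test_that("occupancy chain reaches the closed-form Langmuir equilibrium", {
  # K_d = k_off / k_on = 76.19 nM; at 100 nM the stationary occupancy is
  # c / (c + K_d) = 0.5676. Long equilibrium-initialized run, tolerance set
  # by the autocorrelation-corrected Monte-Carlo s.e. (tau = 1/k_obs).
  p <- sim_preset_named("r82a", concentration_nM = 100)
  occ <- simulate_occupancy(p, duration = 500, init = "equilibrium", seed = 7)
  p_eq <- 100 / (100 + 0.16 / (2.1e6 * 1e-9))
  n_eff <- length(occ$values) / (2 * (1 / 0.37) / occ$dt)
  se <- sqrt(p_eq * (1 - p_eq) / n_eff)
  expect_lt(abs(mean(occ$values) - p_eq), 3 * se)
})

test_that("occupancy generation is reproducible under a fixed seed", {
  p <- sim_preset_named("r82a")
  a <- simulate_occupancy(p, duration = 5, seed = 99)
  b <- simulate_occupancy(p, duration = 5, seed = 99)
  expect_identical(a$values, b$values)
  c_ <- simulate_occupancy(p, duration = 5, seed = 100)
  expect_false(identical(a$values, c_$values))
})

test_that("intensity trajectory matches exact limits", {
  p <- sim_preset_named("r82a", t_half_bleach = Inf, noise_sd = 0,
                        concentration_nM = 0)
  occ <- simulate_occupancy(p, duration = 2, seed = 1)
  sim <- simulate_intensity_trajectory(occ, p, seed = 1)
  n_dyes <- ncol(occ$values)
  # all-unbound, no bleach, no noise: constant n_dyes * b0
  expect_equal(sim$trajectory$value,
               rep(n_dyes * p$dye_brightness, nrow(occ$values)))

  # all-bound with pife_factor 3: exactly 3x the unbound constant
  p3 <- sim_preset_named("r82a", t_half_bleach = Inf, noise_sd = 0,
                         pife_factor = 3, k_off = 0, k_on = 1e12,
                         concentration_nM = 1e6)
  occ3 <- simulate_occupancy(p3, duration = 2, seed = 1)
  expect_true(all(occ3$values == 1L))
  sim3 <- simulate_intensity_trajectory(occ3, p3, seed = 1)
  expect_equal(sim3$trajectory$value,
               rep(3 * n_dyes * p3$dye_brightness, nrow(occ3$values)))
})

test_that("photobleaching halves the expected intensity per half-life", {
  # per-dye survival expectation is 2^(-t / t_half); with 1000 dyes the
  # realized fraction at t = t_half is 0.5 within 3 binomial s.e.
  p <- sim_preset_named("r82a", concentration_nM = 0, t_half_bleach = 300,
                        noise_sd = 0, dna_length_bp = 1e6)
  occ <- simulate_occupancy(p, duration = 301, seed = 5)
  sim <- simulate_intensity_trajectory(occ, p, seed = 5)
  i300 <- sim$trajectory$value[sim$trajectory$time_s == 300]
  frac <- i300 / sim$trajectory$value[1]
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("compaction trajectory evaluates the piecewise model exactly", {
  p <- sim_preset_named("spo0j_wt", lag_sd = 0, rate_sd = 0,
                        length_noise_sd = 0, l0_um = 6)
  sim <- simulate_compaction_trajectory(p, duration = 12, seed = 1)
  tr <- sim$trajectory
  # L(5.3) = 6 - 0.51 * (5.3 - 3.3) = 4.98 um
  expect_equal(tr$value[which.min(abs(tr$time_s - 5.3))], 6 - 0.51 * 2,
               tolerance = 1e-12)
  expect_equal(sim$truth$t_lag, 3.3)
  expect_equal(sim$truth$rate, 0.51)

  # zero rate: constant at L0
  p0 <- sim_preset_named("spo0j_wt", rate_mean = 0, rate_sd = 0, lag_sd = 0,
                         length_noise_sd = 0)
  s0 <- simulate_compaction_trajectory(p0, duration = 10, seed = 1)
  expect_true(all(s0$trajectory$value == p0$l0_um))

  # long run clamps at the floor
  pl <- sim_preset_named("spo0j_wt", lag_sd = 0, rate_sd = 0,
                         length_noise_sd = 0)
  sl <- simulate_compaction_trajectory(pl, duration = 60, seed = 1)
  expect_equal(min(sl$trajectory$value), pl$l_floor_um)
  expect_equal(sl$trajectory$value[nrow(sl$trajectory)], pl$l_floor_um)

  expect_error(simulate_compaction_trajectory(p, duration = -2), "duration")
})

test_that("steady-state curve generator reduces to the closed form", {
  params <- two_state_params(13, 390, 2, 4, 0.4, 0.95)
  grid <- 10^seq(0, log10(5000), length.out = 12)
  # zero noise: identical to predict_twostate_curves
  noiseless <- simulate_hbsu_steady_state(params, grid, noise_frac = 0,
                                          seed = 1)
  clean <- predict_twostate_curves(grid, params)
  expect_equal(noiseless$fold_intensity, clean$fold_intensity)
  expect_equal(noiseless$fold_length, clean$fold_length)
  # c = 0 is the unbound reference state
  expect_equal(unlist(predict_twostate_curves(0, params)[, 2:3]),
               c(fold_intensity = 1, fold_length = 1))
  # monotone nondecreasing intensity when I2 >= I1 >= 1
  expect_true(all(diff(clean$fold_intensity) >= 0))
  expect_error(simulate_hbsu_steady_state(params, c(-1, 5)), "nonnegative")
})

test_that("QD track generator round-trips tensions through the WLC", {
  geom <- motion_capture_geometry()
  wlc <- wlc_model()
  tens <- c(1.0, 0.6, 0.3, 0.1)
  trk <- simulate_qd_track(geom, tens, wlc, loc_sd = 0, n_frames = 20,
                           seed = 1)
  prof <- tensions_from_extension(differential_extension(trk, geom), wlc)
  expect_equal(prof$F_pN, tens, tolerance = 1e-6)

  # uniform tension: all differential extensions equal
  trk_u <- simulate_qd_track(geom, rep(0.5, 4), wlc, loc_sd = 0,
                             n_frames = 20, seed = 1)
  xi <- differential_extension(trk_u, geom)$xi
  expect_equal(diff(range(xi)), 0, tolerance = 1e-9)

  # extreme force approaches full extension (z -> s)
  trk_f <- simulate_qd_track(geom, rep(1e6, 4), wlc, loc_sd = 0,
                             n_frames = 20, seed = 1)
  expect_equal(colMeans(trk_f$positions), geom$s_um, tolerance = 1e-3,
               ignore_attr = TRUE)

  expect_error(simulate_qd_track(geom, c(1, 0.5, -0.1, 0.2)), "positive")
})
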