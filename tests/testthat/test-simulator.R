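test_that("thermal model reduces to Newton heating without latent heat", {
  cfg <- thermal_config(latent_boost = 1, k_rate = 5e-4)
  traj <- simulate_temperature(cfg, dt = 1, t_stop_C = 4)
  closed <- cfg$t_env - (cfg$t_env - cfg$t_start) *
    exp(-cfg$k_rate * traj$time_s)
  expect_lt(max(abs(traj$temperature_C - closed)), 0.1)
  expect_true(all(diff(traj$temperature_C) > 0))
  expect_gte(traj$temperature_C[nrow(traj)], 4)
})

test_that("latent heat produces the plateau inside the melting band", {
  traj <- simulate_temperature(thermal_config(), dt = 2, t_stop_C = 4)
  rate <- diff(traj$temperature_C) / diff(traj$time_s)
  mid <- (traj$temperature_C[-1L] + traj$temperature_C[-nrow(traj)]) / 2
  in_band <- mid > -12 & mid < -1.5
  pre_band <- mid > -40 & mid < -20
  expect_lt(mean(abs(rate[in_band])), mean(abs(rate[pre_band])) / 3)
})

test_that("faster heat transfer thaws strictly faster", {
  slow <- simulate_temperature(thermal_config(k_rate = 1e-4), dt = 5)
  fast <- simulate_temperature(thermal_config(k_rate = 1e-3), dt = 5)
  expect_lt(max(fast$time_s), max(slow$time_s))
})

test_that("unstable steps are rejected with advice", {
  expect_error(simulate_temperature(thermal_config(k_rate = 0.5), dt = 10),
               "dt")
})

test_that("damage accrues only in the band and with time in it", {
  traj_slow <- simulate_temperature(thermal_config(k_rate = 1e-4), dt = 5)
  traj_fast <- simulate_temperature(thermal_config(k_rate = 1e-3), dt = 5)
  rates <- list(r_transition = 1e-5, r_storage = 1e-6)
  none <- damage_trajectory(traj_fast, list(r_transition = 0, r_storage = 0),
                            d0 = 0.2)
  expect_true(all(none$d == 0.2))
  d_f <- damage_trajectory(traj_fast, rates, storage_s = 16 * 3600)
  d_s <- damage_trajectory(traj_slow, rates, storage_s = 16 * 3600)
  expect_gt(d_s$time_in_band_s, d_f$time_in_band_s)
  expect_gt(d_s$d[length(d_s$d)], d_f$d[length(d_f$d)])
  expect_gt(d_f$d_storage, d_f$d[length(d_f$d)])
  expect_error(damage_trajectory(traj_fast,
                                 list(r_transition = -1, r_storage = 0)),
               "non-negative")
})

test_that("state_to_cole maps physiology onto the dispersion", {
  base <- cole_parameters(60, 45, 5e-6, 0.75)
  ident <- state_to_cole(list(temperature_C = 4, ice_fraction = 0,
                              damage = 0), base)
  expect_equal(ident$R0, base$R0, tolerance = 1e-12)
  expect_equal(ident$Rinf, base$Rinf, tolerance = 1e-12)
  gone <- state_to_cole(list(temperature_C = 4, ice_fraction = 0,
                             damage = 1), base)
  expect_equal(gone$R0, gone$Rinf)   # beta dispersion fully removed
  half <- state_to_cole(list(temperature_C = 4, ice_fraction = 0,
                             damage = 0.5), base)
  expect_equal(half$R0 - half$Rinf, (base$R0 - base$Rinf) / 2,
               tolerance = 1e-12)
  py_half <- py_parameter(list(R0 = half$R0, Rinf = half$Rinf))
  expect_lt(py_half, py_parameter(base))
  frozen <- state_to_cole(list(temperature_C = -30, ice_fraction = 1,
                               damage = 0), base)
  expect_gt(frozen$Rinf, 20 * base$Rinf)
})

test_that("the noise model has the configured relative scale", {
  base <- cole_parameters(60, 45, 5e-6, 0.75)
  grid <- default_frequency_grid()
  z0 <- cole_impedance(base, grid)
  exact <- synthesize_spectrum(base, grid, noise_sd = 0)
  expect_equal(exact$resistance_ohm, Re(z0), tolerance = 1e-12)
  expect_equal(exact$reactance_ohm, Im(z0), tolerance = 1e-12)

  set.seed(12)
  dev2 <- replicate(300, {
    s <- synthesize_spectrum(base, grid, noise_sd = 0.01)
    z <- complex(real = s$resistance_ohm, imaginary = s$reactance_ohm)
    mean((Mod(z - z0) / Mod(z0))^2)
  })
  rel_rms <- sqrt(mean(dev2))
  expect_lt(abs(rel_rms - 0.01 * sqrt(2)), 0.1 * 0.01 * sqrt(2))

  set.seed(99); s1 <- synthesize_spectrum(base, grid, 0.01)
  set.seed(99); s2 <- synthesize_spectrum(base, grid, 0.01)
  expect_identical(s1$resistance_ohm, s2$resistance_ohm)
  expect_identical(s1$reactance_ohm, s2$reactance_ohm)
})

test_that("calibration inverts the damage scaling, edges included", {
  base <- cole_parameters(60, 45, 5e-6, 0.75)
  # degenerate targets
  top <- calibrate_to_py(c(py_parameter(base), 0), base)
  expect_equal(top$mu, 0, tolerance = 1e-9)
  set.seed(4)
  expect_true(all(draw_damage(5, top)$d == 0))
  # near-total destruction: damage pinned at 1
  bottom <- calibrate_to_py(c(1e-9, 0), base)
  expect_equal(bottom$mu, 1, tolerance = 1e-6)
  expect_error(calibrate_to_py(c(40, 1), base), "achievable")

  cal <- calibrate_to_py(c(16.1, 3.90), base)
  set.seed(8)
  d <- draw_damage(2000, cal, stratified = FALSE)$d
  py <- 100 * (base$R0 - base$Rinf) * (1 - d) /
    (base$Rinf + (base$R0 - base$Rinf) * (1 - d))
  expect_lt(abs(mean(py) - 16.1) / 16.1, 0.05)
  expect_lt(abs(stats::sd(py) - 3.90) / 3.90, 0.05)
})

test_that("the default cohort realizes the designed layout", {
  co <- generate_cohort(simulator_config(seed = 3))
  expect_equal(n_trajectories(co), 20L)
  trajs <- cohort_trajectories(co)
  expect_true(all(vapply(trajs, length, integer(1L)) == 10L))
  expect_true(all(vapply(trajs, function(tr) {
    all(vapply(tr, function(s) length(s$frequency_Hz), integer(1L)) == 36L)
  }, logical(1L))))
  gt <- co$metadata$ground_truth
  expect_equal(nrow(gt), 200L)
  expect_true(all(gt$damage >= 0 & gt$damage <= 1))
})

test_that("impedance declines monotonically along thawing, steepest in the band", {
  co <- generate_cohort(simulator_config(seed = 6, n_fast = 2L, n_slow = 2L,
                                         noise_sd = 0,
                                         include_frozen = TRUE))
  for (traj in cohort_trajectories(co)) {
    thaw <- Filter(function(s) !is_next_day(s), traj)
    zmat <- t(vapply(thaw, function(s) {
      sqrt(s$resistance_ohm^2 + s$reactance_ohm^2)
    }, numeric(36L)))
    expect_true(all(diff(zmat) < 1e-9))   # every frequency, every step
    temps <- vapply(thaw, `[[`, numeric(1L), "temperature_C")
    drop_per_C <- -diff(zmat) / diff(temps)
    mid <- (temps[-1L] + temps[-length(temps)]) / 2
    steepest <- mid[apply(drop_per_C, 2L, which.max)]
    expect_true(all(steepest > -12 & steepest < -1.5))
  }
})

test_that("cohort generation is byte-identical under one seed", {
  cfg <- simulator_config(seed = 31, n_fast = 2L, n_slow = 2L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(generate_cohort(cfg), p1)
  write_spectra_csv(generate_cohort(cfg), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("fitting generated spectra recovers ground-truth Py closely", {
  co <- small_cohort(seed = 13)
  fits <- fit_cole_cohort(co)
  gt <- co$metadata$ground_truth
  key <- function(df) paste(df$sample_id, round(df$temperature_C, 3),
                            df$next_day)
  fits$key <- key(fits); gt$key <- key(gt)
  j <- merge(fits[, c("key", "Py")], gt[, c("key", "true_Py")], by = "key")
  expect_equal(nrow(j), nrow(gt))
  expect_lt(stats::median(abs(j$Py - j$true_Py)), 1.0)
})

test_that("drip-loss records respect the weight invariants", {
  set.seed(2)
  drip <- simulate_drip_loss(10, 10)
  expect_equal(nrow(drip), 20L)
  expect_true(all(drip$final_weight_g > 0))
  expect_true(all(drip$final_weight_g <= drip$initial_weight_g))
  expect_true(all(drip$storage_hours >= 16 & drip$storage_hours <= 26))
  loss <- drip_loss_percent(drip$initial_weight_g, drip$final_weight_g)
  expect_true(all(loss > 0 & loss < 15))
})
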