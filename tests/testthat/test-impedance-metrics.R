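test_that("magnitude and phase follow the polar identities", {
  mp <- magnitude_phase(3, 4)
  expect_equal(mp$magnitude_ohm, 5)
  expect_equal(mp$phase_deg, atan2(4, 3) * 180 / pi, tolerance = 1e-12)
  expect_equal(magnitude_phase(1, 0)$phase_deg, 0)
  mp2 <- magnitude_phase(1, -1)
  expect_equal(mp2$magnitude_ohm, sqrt(2))
  expect_equal(mp2$phase_deg, -45)
  expect_error(magnitude_phase(0, 0), "undefined")

  set.seed(11)
  r <- stats::runif(200, 0.1, 1e4)
  x <- stats::rnorm(200, 0, 100)
  mp3 <- magnitude_phase(r, x)
  phi <- mp3$phase_deg * pi / 180
  expect_equal(mp3$magnitude_ohm * cos(phi), r, tolerance = 1e-12)
  expect_equal(mp3$magnitude_ohm * sin(phi), x, tolerance = 1e-12)
})

test_that("relative_change handles both sign conventions", {
  expect_equal(relative_change(100, 0), 100)    # total loss
  expect_equal(relative_change(100, 100), 0)    # no change
  expect_equal(relative_change(100, 10, mode = "as_printed"), 110)
  expect_error(relative_change(0, 10), "positive")
})

test_that("freshness indices are the per-sample damage ratios", {
  idx <- freshness_index(100, -20, 100, -20)
  expect_equal(idx$R_index, 0)
  expect_equal(idx$X_index, 0)
  expect_equal(freshness_index(100, -20, 80, -10)$R_index, 0.2)
  flagged <- freshness_index(100, 0, 80, -10)
  expect_true(is.na(flagged$X_index))
  expect_false(flagged$x_defined)
  expect_equal(flagged$R_index, 0.2)
})

test_that("freshness indices are invariant to electrode-geometry scale", {
  set.seed(3)
  for (i in 1:20) {
    v <- c(stats::runif(2, 10, 200), stats::runif(2, 1, 50))
    a <- freshness_index(v[1L], -v[3L], v[2L], -v[4L])
    cc <- stats::runif(1, 0.1, 10)
    b <- freshness_index(cc * v[1L], -cc * v[3L], cc * v[2L], -cc * v[4L])
    expect_equal(a$R_index, b$R_index, tolerance = 1e-12)
    expect_equal(a$X_index, b$X_index, tolerance = 1e-12)
  }
})

test_that("greater membrane damage raises the low-frequency R index", {
  base <- cole_parameters(60, 45, 5e-6, 0.75)
  fresh <- cole_impedance(base, 10)
  z_of_damage <- function(d) {
    p <- state_to_cole(list(temperature_C = 4, ice_fraction = 0, damage = d),
                       base)
    p$tau <- base$tau; cole_impedance(p, 10)
  }
  z1 <- z_of_damage(0.1); z5 <- z_of_damage(0.5)
  i1 <- freshness_index(Re(fresh), Im(fresh), Re(z1), Im(z1))
  i5 <- freshness_index(Re(fresh), Im(fresh), Re(z5), Im(z5))
  expect_gt(i5$R_index, i1$R_index)
})

mk_traj <- function(zmags, ax, axis = "time") {
  grid <- default_frequency_grid(n = 5L)
  lapply(seq_along(zmags), function(k) {
    impedance_sample("t", "fast_thaw",
                     time_s = if (axis == "time") ax[k] else k * 60,
                     temperature_C = if (axis == "time") -20 else ax[k],
                     grid, rep(zmags[k], 5L), rep(0, 5L))
  })
}

test_that("impedance change rate is the normalized backward difference", {
  traj <- mk_traj(c(100, 100, 100), c(0, 10, 20))
  icr <- impedance_change_rate(traj, default_frequency_grid(n = 5L)[1L],
                               axis = "time")
  expect_equal(icr$icr, c(0, 0))
  traj2 <- mk_traj(c(100, 50), c(0, 10))
  icr2 <- impedance_change_rate(traj2, default_frequency_grid(n = 5L)[1L],
                                axis = "time")
  expect_equal(icr2$icr, 0.05)   # halving over 10 s
  expect_error(
    impedance_change_rate(traj2, 12345, axis = "time"), "not on")
})

test_that("ICR of a monotonically decreasing series is non-negative", {
  set.seed(5)
  zmags <- sort(stats::runif(10, 10, 100), decreasing = TRUE)
  traj <- mk_traj(zmags, seq(0, 90, by = 10))
  icr <- impedance_change_rate(traj, default_frequency_grid(n = 5L)[1L],
                               axis = "time")
  expect_true(all(icr$icr >= 0))
})

test_that("the ICR peak sits inside the phase-transition zone", {
  co <- generate_cohort(simulator_config(
    seed = 2, n_fast = 1L, n_slow = 1L, noise_sd = 0,
    include_frozen = TRUE))
  traj <- cohort_trajectories(co)[["fast_01"]]
  thaw <- Filter(function(s) !is_next_day(s) && !is.na(s$time_s), traj)
  for (f in default_frequency_grid()[c(1L, 18L, 36L)]) {
    icr <- impedance_change_rate(thaw, f, axis = "temperature")
    peak <- icr[which.max(abs(icr$icr)), ]
    expect_gte(peak$axis_to, -12)
    expect_lte(peak$axis_from, -1.5)
  }
})

test_that("cohort_metrics assembles the batch descriptor table", {
  co <- small_cohort(n_fast = 1L, n_slow = 1L)
  m <- cohort_metrics(co)
  expect_true(all(c("magnitude_ohm", "phase_deg", "icr") %in% names(m)))
  expect_equal(nrow(m), nrow(co$data))
  expect_true(any(!is.na(m$icr)))
})
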