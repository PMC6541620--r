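test_that("average speed is the mean step displacement over dt", {
  still <- track("s", c(0, 1, 2) / 6, c(0, 0, 0), c(0, 0, 0))
  expect_equal(average_speed(still), 0)
  steady <- mk_track(cbind(rep(5, 6), rep(0, 6)))  # 5 um per 10-min step
  expect_equal(average_speed(steady), 30)
  mixed <- mk_track(cbind(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(average_speed(mixed), mean(c(1, 2, 3)) / (1 / 6))  # 12 um/h
})

test_that("average speed is invariant under translation and rotation", {
  set.seed(6)
  steps <- matrix(rnorm(40), 20, 2)
  tr <- mk_track(steps)
  v0 <- average_speed(tr)
  shifted <- track("s", tr$times_h, tr$x_um + 100, tr$y_um - 50)
  expect_equal(average_speed(shifted), v0)
  th <- 0.7
  rot <- track("r", tr$times_h,
               cos(th) * tr$x_um - sin(th) * tr$y_um,
               sin(th) * tr$x_um + cos(th) * tr$y_um)
  expect_equal(average_speed(rot), v0)
})

test_that("hourly running average windows the step speeds correctly", {
  steady <- mk_track(cbind(rep(2, 12), rep(0, 12)))  # 2 h at 12 um/h
  rs <- running_average_speed(steady)
  expect_equal(rs$speed_um_h, c(12, 12))
  expect_equal(rs$t_h, c(0.5, 1.5))
  # fast for 1 h (6 steps of 5 um), then frozen for 2 h
  pw <- mk_track(cbind(c(rep(5, 6), rep(0, 12)), rep(0, 18)))
  rs2 <- running_average_speed(pw)
  expect_equal(rs2$speed_um_h, c(30, 0, 0))
  expect_error(running_average_speed(steady, window_h = 0.1),
               "window smaller")
  short <- mk_track(cbind(c(1, 1), c(0, 0)))
  expect_error(running_average_speed(short), "shorter than one window")
})

test_that("MSD matches hand enumeration on the four-point track", {
  tr <- mk_track(cbind(c(1, 0, 1), c(0, 1, 0)))  # (0,0),(1,0),(1,1),(2,1)
  m <- msd(tr, max_lag_fraction = 1)
  expect_equal(m$msd_um2, c(0, 1, 2, 5))
  expect_equal(m$lag_h, c(0, 1, 2, 3) / 6)
  expect_equal(m$n_pairs[-1], c(3, 2, 1))
})

test_that("MSD equals the O(n^2) double-loop oracle exactly", {
  set.seed(7)
  for (n_steps in c(10, 27, 49)) {
    tr <- mk_track(matrix(rnorm(2 * n_steps), n_steps, 2))
    k_max <- n_steps  # all lags
    m <- msd(tr, max_lag_fraction = 1)
    expect_identical(m$msd_um2[-1], msd_oracle(tr, k_max))
  }
})

test_that("ensemble MSD of identical copies equals the single-track MSD", {
  set.seed(8)
  tr <- mk_track(matrix(rnorm(30), 15, 2))
  single <- msd(tr, max_lag_fraction = 0.5)
  copies <- msd(list(tr, tr, tr), max_lag_fraction = 0.5)
  expect_equal(copies$msd_um2, single$msd_um2)
  expect_equal(copies$n_pairs[-1], 3 * single$n_pairs[-1])
})

test_that("stationary tracks give identically zero MSD", {
  still <- track("s", (0:10) / 6, rep(2, 11), rep(-1, 11))
  expect_true(all(msd(still)$msd_um2 == 0))
  expect_error(msd(list()), "empty track list")
})

test_that("ballistic MSD is quadratic and flagged by curvature", {
  st <- simulate_tracks(trajectory_spec("ballistic", n_tracks = 3,
                                        speed_um_h = 24, seed = 3))
  m <- msd(st$tracks, max_lag_fraction = 1)
  pos <- m$lag_h > 0
  expect_equal(m$msd_um2[pos], (24 * m$lag_h[pos])^2)
  fit <- fit_msd_linear(m)
  expect_lt(fit$r_squared, 1)
  res <- residuals(fit$fit)   # convex residual pattern: + at ends, - inside
  expect_gt(res[1], 0)
  expect_gt(res[length(res)], 0)
  expect_lt(min(res), 0)
})

test_that("linear MSD regression recovers exact lines and 4D slopes", {
  lin <- structure(data.frame(lag_h = 0:6 / 6, msd_um2 = 3 + 8 * (0:6 / 6),
                              n_pairs = 7:1),
                   class = c("msd_result", "data.frame"))
  fit <- suppressWarnings(fit_msd_linear(lin))
  expect_equal(fit$slope, 8)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$r_squared, 1)
  D <- 50
  st <- simulate_tracks(trajectory_spec("random_walk", n_tracks = 40,
                                        D_um2_h = D, seed = 12))
  m <- msd(st$tracks)
  f <- fit_msd_linear(m)
  expect_gt(f$r_squared, 0.99)
  se <- sqrt(diag(vcov(f$fit)))[["lag_h"]]
  expect_lt(abs(f$slope - 4 * D), 3 * se + 0.05 * 4 * D)
  expect_error(fit_msd_linear(lin[1:3, ]), "3 non-zero lags")
})

test_that("motion classes follow the log-log MSD exponent", {
  rw <- simulate_tracks(trajectory_spec("random_walk", n_tracks = 40,
                                        D_um2_h = 30, seed = 14))
  expect_equal(classify_motion(msd(rw$tracks))$class, "diffusive")
  bal <- simulate_tracks(trajectory_spec("ballistic", n_tracks = 5,
                                         speed_um_h = 20, seed = 15))
  cls <- suppressWarnings(classify_motion(msd(bal$tracks)))  # exact power law
  expect_equal(cls$class, "superdiffusive")
  expect_equal(cls$alpha, 2, tolerance = 1e-6)
  still <- track("s", (0:12) / 6, rep(0, 13), rep(0, 13))
  st_cls <- classify_motion(msd(still))
  expect_true(st_cls$degenerate)
})

test_that("speed-decay fitting recovers the half-life and flags flat series", {
  t <- seq(0.5, 15.5, by = 1)
  clean <- data.frame(t_h = t, speed_um_h = 5 + 25 * 2^(-t / 1.7))
  fit <- fit_speed_decay(clean, t_drug_h = 0)
  expect_equal(fit$half_life_h, 1.7, tolerance = 1e-6)
  expect_equal(fit$S0_um_h, 30, tolerance = 1e-6)
  expect_equal(fit$S_inf_um_h, 5, tolerance = 1e-6)
  flat <- data.frame(t_h = t, speed_um_h = rep(12, length(t)))
  ff <- fit_speed_decay(flat, 0)
  expect_false(ff$identifiable)
  expect_true(is.na(ff$half_life_h))
  expect_equal(ff$S0_um_h, ff$S_inf_um_h)
  expect_error(fit_speed_decay(clean[1:3, ], 0), "at least 4")
})

test_that("decay fits on simulated washouts stay within 15% at 10% noise", {
  errs <- vapply(1:4, function(seed) {
    st <- simulate_tracks(trajectory_spec(
      "decaying_speed", n_tracks = 40, S0_um_h = 30, S_inf_um_h = 5,
      half_life_h = 1.7, speed_cv = 0.1, seed = seed))
    fit <- fit_speed_decay(mean_running_speed(st$tracks), 0)
    abs(fit$half_life_h / 1.7 - 1)
  }, numeric(1))
  expect_true(all(errs < 0.15))
})
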