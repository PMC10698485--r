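test_that("normalize_hx divides by the horizontal norm without clamping", {
  f <- marion_field()
  expect_equal(normalize_hx(f$horizontal_norm, f), 1)
  expect_equal(normalize_hx(0, f), 0)
  # out-of-range values pass through: they signal noise or N/S headings
  expect_equal(normalize_hx(1.05 * f$horizontal_norm, f), 1.05)
  expect_error(normalize_hx(1, reference_field(0, 0, -30000)),
               "magnetic pole")
})

test_that("yaw_solutions returns both arccos branches or invalid", {
  y <- yaw_solutions(1, 0)
  expect_true(y$valid)
  expect_equal(c(y$yaw_plus, y$yaw_minus), c(0, 0))
  y2 <- yaw_solutions(0, -27)
  expect_equal(c(y2$yaw_plus, y2$yaw_minus), c(63, -117))
  y3 <- yaw_solutions(c(1.01, -1.2, NaN), 10)
  expect_equal(y3$valid, c(FALSE, FALSE, FALSE))
  expect_true(all(is.na(y3$yaw_plus)))
})

test_that("alpha is measured from the down axis, four-quadrant", {
  f_down <- reference_field(1000 * cosd(-20), 1000 * sind(-20), 40000)
  expect_equal(alpha_angle(-20, f_down), 0)
  f_up <- reference_field(1000 * cosd(-20), 1000 * sind(-20), -40000)
  expect_equal(alpha_angle(-20, f_up), 180)
  f_45 <- reference_field(1000, 0, 1000)
  expect_equal(alpha_angle(90, f_45), 45)
  f_eq <- reference_field(1000, 0, 0)   # magnetic equator
  expect_error(alpha_angle(0, f_eq), "degenerate")
})

test_that("roll_angle is a sign-preserving four-quadrant arctangent plus alpha", {
  expect_equal(roll_angle(0, 500, 0), 0)
  expect_equal(roll_angle(300, 300, 10), 55)
  expect_equal(roll_angle(-300, 300, 0), -45)
  expect_error(roll_angle(0, 0, 10), "degenerate")
})

test_that("solve_sample inverts the forward model on one branch", {
  f <- marion_field()
  for (yaw in c(-120, -10, 40, 170)) {
    for (roll in c(-75, 0.5, 60)) {
      hb <- forward_model(f, yaw, 0, roll)
      s <- solve_sample(hb$h_x, hb$h_y, hb$h_z, f)
      expect_true(s$valid)
      err_p <- abs(angle_diff(s$yaw_plus, yaw)) +
        abs(angle_diff(s$roll_plus, roll))
      err_m <- abs(angle_diff(s$yaw_minus, yaw)) +
        abs(angle_diff(s$roll_minus, roll))
      expect_lt(min(err_p, err_m), 1e-9)
    }
  }
})

test_that("solve_sample interpolates from a prior alpha when h_x is out of range", {
  f <- marion_field()
  h_x <- 1.2 * f$horizontal_norm
  s <- solve_sample(h_x, 300, -500, f, prior_alpha = 30)
  expect_false(s$valid)
  expect_true(s$interpolated)
  expect_equal(s$roll, wrap_angle(atan2d(300, -500) + 30))
  expect_true(is.na(s$yaw_plus))
  # nothing to interpolate from on a first sample
  s0 <- solve_sample(h_x, 300, -500, f)
  expect_false(s0$valid)
  expect_false(s0$interpolated)
  expect_true(is.na(s0$roll))
})

test_that("solve_posture recovers a noiseless zero-pitch series exactly", {
  f <- marion_field()
  sim <- simulate_stream(
    soaring_trajectory(duration_s = 60, base_heading = 90),
    sim_config(f))
  sol <- solve_posture(sim, f)
  expect_true(all(sol$valid))
  expect_false(any(sol$interpolated))
  expect_lt(max(abs(angle_diff(sol$roll, sim$roll_true))), 1e-6)
  expect_lt(max(abs(angle_diff(sol$yaw, sim$yaw_true))), 1e-6)
  # recovered branch angles reproduce the measurements through the
  # forward model (residual far below solver tolerance)
  hb <- forward_model(f, sol$yaw, 0, sol$roll)
  expect_lt(max(abs(hb$h_x - sim$h_x)), 1e-6)
  expect_lt(max(abs(hb$h_y - sim$h_y)), 1e-6)
})

test_that("branches coincide exactly where |h_x| = 1", {
  f <- marion_field()
  hb <- forward_model(f, f$declination, 0, 25)   # heading = declination
  s <- solve_sample(hb$h_x, hb$h_y, hb$h_z, f)
  expect_equal(s$hx, 1, tolerance = 1e-12)
  if (s$valid) {
    expect_equal(angle_diff(s$yaw_plus, s$yaw_minus), 0, tolerance = 1e-5)
    expect_equal(angle_diff(s$roll_plus, s$roll_minus), 0, tolerance = 1e-5)
  }
})

test_that("headings at magnetic north give contiguous interpolated runs", {
  f <- marion_field()
  # heading sweeps through magnetic north each cycle; a small constant
  # pitch pushes |h_x| past 1 there, deterministically
  sim <- simulate_stream(
    soaring_trajectory(duration_s = 60, base_heading = 0,
                       heading_swing = 40),
    sim_config(f, pitch_mean = 1))
  sol <- solve_posture(sim, f)
  expect_true(any(!sol$valid))
  expect_true(any(sol$valid))
  # invalid samples only occur near magnetic north headings
  expect_lt(max(abs(angle_diff(sim$heading_mag[!sol$valid], 0))), 30)
  # all invalid samples after the first valid one get interpolated rolls
  first_valid <- which(sol$valid)[1]
  late_invalid <- !sol$valid & seq_len(nrow(sol)) > first_valid
  expect_true(all(sol$interpolated[late_invalid]))
  expect_true(all(is.finite(sol$roll[late_invalid])))
  # and the series resumes valid afterwards: runs alternate
  runs <- rle(sol$valid)
  expect_gt(sum(runs$values), 1)
})

test_that("interpolation preserves roll sign across a gap that does not cross zero", {
  f <- marion_field()
  # roll stays well positive while the heading crosses magnetic north
  t <- seq(0, 20, by = 1 / 40)
  heading <- wrap_angle(40 * sin(2 * pi * t / 10))
  roll <- 40 + 10 * sin(2 * pi * t / 10)
  yaw <- wrap_angle(heading + f$declination)
  hb <- forward_model(f, yaw, 1, roll)   # 1 deg pitch opens the N window
  sol <- solve_posture(
    tibble::tibble(t = t, h_x = hb$h_x, h_y = hb$h_y, h_z = hb$h_z), f)
  expect_true(any(sol$interpolated))
  valid_sign <- sign(sol$roll[sol$valid])
  expect_true(all(sign(sol$roll[sol$interpolated]) ==
                    valid_sign[1]))
})

test_that("nearest-alpha fill uses the closer valid neighbour", {
  f <- marion_field()
  good <- forward_model(f, 90 + f$declination, 0, 10)
  good2 <- forward_model(f, -60 + f$declination, 0, 10)  # distinct alpha
  bad_hx <- 1.5 * f$horizontal_norm
  samples <- tibble::tibble(
    t = 0:3,
    h_x = c(good$h_x, bad_hx, bad_hx, good2$h_x),
    h_y = c(good$h_y, good$h_y, good$h_y, good2$h_y),
    h_z = c(good$h_z, good$h_z, good$h_z, good2$h_z)
  )
  prev <- solve_posture(samples, f, alpha_fill = "previous")
  near <- solve_posture(samples, f, alpha_fill = "nearest")
  expect_equal(prev$alpha[2], prev$alpha[1])
  expect_equal(prev$alpha[3], prev$alpha[1])
  expect_equal(near$alpha[3], near$alpha[4])
  # leading invalid samples: previous-fill cannot, nearest-fill can
  samples2 <- samples[c(2, 1, 3, 4), ]
  samples2$t <- 0:3
  prev2 <- solve_posture(samples2, f, alpha_fill = "previous")
  expect_false(prev2$interpolated[1])
  expect_true(is.na(prev2$roll[1]))
  near2 <- solve_posture(samples2, f, alpha_fill = "nearest")
  expect_true(near2$interpolated[1])
})

test_that("disambiguation picks the branch oscillating about zero", {
  # branch A spans (-40, 45), branch B (10, 95): A must win
  n <- 21
  sols <- tibble::tibble(
    t = seq(0, 5, length.out = n),
    valid = TRUE,
    roll_plus = seq(-40, 45, length.out = n),
    roll_minus = seq(10, 95, length.out = n)
  )
  out <- disambiguate_branches(sols, window_s = 10)
  expect_true(all(out$branch == "plus"))
  swapped <- dplyr::rename(sols, roll_plus = "roll_minus",
                           roll_minus = "roll_plus")
  expect_true(all(disambiguate_branches(swapped)$branch == "minus"))
  # exact tie goes to plus
  tie <- dplyr::mutate(sols, roll_minus = .data$roll_plus)
  expect_true(all(disambiguate_branches(tie)$branch == "plus"))
  # windows with no valid samples inherit the previous window's choice
  sols2 <- tibble::tibble(
    t = c(0, 2, 11, 14, 21, 23),
    valid = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    roll_plus = c(-10, 10, NA, NA, 50, 60),
    roll_minus = c(40, 80, NA, NA, -20, 20)
  )
  out2 <- disambiguate_branches(sols2, window_s = 10)
  expect_equal(out2$branch, c("plus", "plus", "plus", "plus",
                              "minus", "minus"))
  # empty input stays empty
  expect_equal(nrow(disambiguate_branches(sols[0, ])), 0)
})

test_that("the mean rule is available for short windows", {
  n <- 41
  sols <- tibble::tibble(
    t = seq(0, 4, length.out = n),
    valid = TRUE,
    roll_plus = 30 * sin(seq(0, 2 * pi, length.out = n)),
    roll_minus = 55 + 30 * sin(seq(0, 2 * pi, length.out = n))
  )
  out <- disambiguate_branches(sols, window_s = 4, rule = "mean")
  expect_true(all(out$branch == "plus"))
})

test_that("solve_posture is deterministic and handles empty input", {
  f <- marion_field()
  sim <- simulate_stream(soaring_trajectory(duration_s = 30),
                         sim_config(f, noise_sd = 200, seed = 11))
  a <- solve_posture(sim, f)
  b <- solve_posture(sim, f)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  empty <- solve_posture(sim[0, ], f)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("roll", "valid", "branch") %in% names(empty)))
  expect_error(solve_posture(sim[, c("t", "h_x")], f), "missing column")
  shuffled <- sim[c(2, 1, 3:nrow(sim)), ]
  expect_error(solve_posture(shuffled, f), "ordered in time")
})

test_that("per-sample field tables are accepted and checked", {
  f <- marion_field()
  sim <- simulate_stream(soaring_trajectory(duration_s = 10), sim_config(f))
  ft <- tibble::tibble(h_n = rep(f$h_n, nrow(sim)),
                       h_e = f$h_e, h_d = f$h_d)
  sol_tbl <- solve_posture(sim, ft)
  sol_ref <- solve_posture(sim, f)
  expect_equal(sol_tbl$roll, sol_ref$roll)
  expect_error(solve_posture(sim, ft[1:5, ]), "one row per sample")
})
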