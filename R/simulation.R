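#' Simulation configuration
#'
#' Collects the sensor/environment parameters shared by the synthetic-data
#' generators: the reference field, sampling rate (40 Hz, the logger's native
#' rate), additive per-axis Gaussian sensor noise, a pitch profile (the
#' solver assumes zero pitch; the generators need not), an optional hard-/
#' soft-iron distortion to inject, and a seed for bit-reproducible output.
#'
#' @param field A [reference_field()]; defaults to the bundled geomagnetic
#'   model evaluated at the Marion Island study site (46 S, 37 E, 2019.95).
#' @param sample_rate Samples per second.
#' @param noise_sd Per-axis Gaussian noise standard deviation, nT.
#' @param pitch_mean,pitch_sd Pitch profile in degrees: `(0, 0)` is the
#'   zero-pitch case, `(x, 0)` a constant pitch, `(0, s)` stochastic pitch.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param distortion Optional `mag_calibration` whose inverse is applied to
#'   emulate an uncalibrated sensor (see [fit_calibration()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(field = NULL, sample_rate = 40, noise_sd = 0,
                       pitch_mean = 0, pitch_sd = 0, seed = NULL,
                       distortion = NULL) {
  if (is.null(field)) field <- wmm_field(-46, 37, 2019.95)
  stopifnot(is_reference_field(field), sample_rate > 0, noise_sd >= 0,
            pitch_sd >= 0)
  if (!is.null(distortion)) stopifnot(inherits(distortion, "mag_calibration"))
  structure(list(field = field, sample_rate = sample_rate,
                 noise_sd = noise_sd, pitch_mean = pitch_mean,
                 pitch_sd = pitch_sd, seed = seed, distortion = distortion),
            class = "sim_config")
}

with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parameterized dynamic-soaring trajectory
#'
#' An idealized dynamic-soaring flight: roll oscillates sinusoidally with the
#' cycle period (crossing zero twice per cycle, as the bird banks windward
#' then leeward), while the magnetic heading sweeps about a base heading with
#' a per-cycle swing, a quarter-cycle out of phase with roll so the heading
#' extremes fall at the roll zero-crossings (the turns of the cycle).
#'
#' @param duration_s Flight duration, seconds.
#' @param cycle_period Dynamic-soaring cycle period, seconds (~10 s for
#'   albatrosses).
#' @param roll_amplitude Peak roll, degrees.
#' @param base_heading Mean magnetic heading, degrees from magnetic north.
#' @param heading_swing Heading half-range per cycle, degrees.
#' @return A `soaring_trajectory` object with an `angles_at(t)` closure.
#' @export
soaring_trajectory <- function(duration_s = 1800, cycle_period = 10,
                               roll_amplitude = 60, base_heading = 90,
                               heading_swing = 40) {
  stopifnot(duration_s > 0, cycle_period > 0, roll_amplitude > 0)
  angles_at <- function(t) {
    ph <- 2 * pi * t / cycle_period
    tibble::tibble(
      t = t,
      roll_true = roll_amplitude * sin(ph),
      heading_mag = wrap_angle(base_heading + heading_swing * cos(ph))
    )
  }
  structure(list(duration_s = duration_s, cycle_period = cycle_period,
                 roll_amplitude = roll_amplitude,
                 base_heading = base_heading,
                 heading_swing = heading_swing, angles_at = angles_at),
            class = "soaring_trajectory")
}

sim_pitch <- function(cfg, n) {
  if (cfg$pitch_sd > 0) rnorm(n, cfg$pitch_mean, cfg$pitch_sd)
  else rep(cfg$pitch_mean, n)
}

sim_measure <- function(cfg, yaw, pitch, roll) {
  hb <- forward_model(cfg$field, yaw, pitch, roll)
  n <- nrow(hb)
  if (cfg$noise_sd > 0) {
    hb$h_x <- hb$h_x + rnorm(n, 0, cfg$noise_sd)
    hb$h_y <- hb$h_y + rnorm(n, 0, cfg$noise_sd)
    hb$h_z <- hb$h_z + rnorm(n, 0, cfg$noise_sd)
  }
  if (!is.null(cfg$distortion)) {
    d <- cfg$distortion
    raw <- (as.matrix(hb) / d$intensity_scale) %*% t(solve(d$soft_iron))
    raw <- sweep(raw, 2, d$offset, "+")
    hb$h_x <- raw[, 1]; hb$h_y <- raw[, 2]; hb$h_z <- raw[, 3]
  }
  hb
}

#' Simulate a magnetometer stream along a soaring trajectory
#'
#' Samples the trajectory at the configured rate, applies the pitch profile,
#' pushes the true angles through the forward rotation model, and adds sensor
#' noise (and, optionally, an injected iron distortion). Ground truth is
#' returned alongside the measurements so recovery can be scored exactly.
#'
#' @param traj A [soaring_trajectory()].
#' @param cfg A [sim_config()].
#' @return A tibble with columns `t`, measured `h_x`, `h_y`, `h_z` (nT), and
#'   ground truth `yaw_true`, `pitch_true`, `roll_true`, `heading_mag`
#'   (degrees; `yaw_true` is geographic, `heading_mag` magnetic).
#' @export
simulate_stream <- function(traj, cfg = sim_config()) {
  stopifnot(inherits(traj, "soaring_trajectory"), inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    t <- seq(0, traj$duration_s, by = 1 / cfg$sample_rate)
    ang <- traj$angles_at(t)
    ang$yaw_true <- wrap_angle(ang$heading_mag + cfg$field$declination)
    ang$pitch_true <- sim_pitch(cfg, nrow(ang))
    hb <- sim_measure(cfg, ang$yaw_true, ang$pitch_true, ang$roll_true)
    dplyr::bind_cols(ang[, "t"], hb,
                     ang[, c("yaw_true", "pitch_true", "roll_true",
                             "heading_mag")])
  })
}

#' Simulate a compass swing
#'
#' Emulates the control experiment used to validate the method: the logger is
#' held at each magnetic heading in 10 degree increments starting at magnetic
#' north, and at each heading rotated through a full 360 degrees of roll.
#' Measurements use the configured noise and pitch profile (the physical
#' swing is hand-held, so zero pitch and a small sensor noise are the
#' realistic defaults).
#'
#' @param cfg A [sim_config()].
#' @param yaw_step Heading increment, degrees.
#' @param roll_step Roll increment within each sweep, degrees.
#' @return A tibble like [simulate_stream()]'s, with `heading_mag` labelling
#'   the nominal magnetic heading of each sweep.
#' @export
compass_swing <- function(cfg = sim_config(), yaw_step = 10, roll_step = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    headings <- seq(0, 360 - yaw_step, by = yaw_step)
    rolls <- wrap_angle(seq(-180 + roll_step, 180, by = roll_step))
    g <- tidyr::expand_grid(heading_mag = headings, roll_true = rolls)
    g$t <- (seq_len(nrow(g)) - 1) / cfg$sample_rate
    g$yaw_true <- wrap_angle(g$heading_mag + cfg$field$declination)
    g$pitch_true <- sim_pitch(cfg, nrow(g))
    hb <- sim_measure(cfg, g$yaw_true, g$pitch_true, g$roll_true)
    dplyr::bind_cols(g[, "t"], hb,
                     g[, c("yaw_true", "pitch_true", "roll_true",
                           "heading_mag")])
  })
}

#' Pitch-sensitivity error grid
#'
#' Quantifies the cost of the zero-pitch assumption: for every magnetic
#' heading and roll on a 1 degree grid (one hemisphere, heading 0-180; the
#' other mirrors about the magnetic meridian) and each true pitch value,
#' exact magnetometer readings are generated with the full forward model,
#' inverted with the zero-pitch solver, and the wrapped absolute roll error
#' scored on the yaw branch nearer the true yaw (the grid has no temporal
#' structure, so the windowed disambiguator does not apply). Cells where
#' \eqn{|h_x| > 1} (no yaw solution) are marked invalid.
#'
#' @param field A [reference_field()].
#' @param pitch_values True pitch angles to evaluate, degrees.
#' @param yaw_step,roll_step Grid increments, degrees.
#' @param headings Magnetic headings to evaluate (default one hemisphere,
#'   `seq(0, 180, yaw_step)`).
#' @return A `pitch_error_grid` tibble: `heading_mag`, `pitch`, `roll`,
#'   `hx`, `valid`, `error` (degrees in \[0, 180\], `NA` where invalid).
#' @examples
#' f <- reference_field(11355, -10954, -27690)
#' g <- pitch_error_grid(f, pitch_values = 0, yaw_step = 30, roll_step = 60)
#' max(g$error, na.rm = TRUE) < 1e-6  # exact inversion at zero pitch
#' @export
pitch_error_grid <- function(field, pitch_values = c(0.25, 0.5, 0.75, 1, 10),
                             yaw_step = 1, roll_step = 1, headings = NULL) {
  stopifnot(is_reference_field(field), field$horizontal_norm > 0)
  if (is.null(headings)) headings <- seq(0, 180, by = yaw_step)
  rolls <- seq(-180, 180, by = roll_step)
  beta <- field$declination
  hnorm <- field$horizontal_norm
  grids <- purrr::map(pitch_values, function(p) {
    g <- tidyr::expand_grid(heading_mag = headings, roll = rolls)
    yaw_true <- wrap_angle(g$heading_mag + beta)
    hb <- forward_model(field, yaw_true, p, g$roll)
    hx <- hb$h_x / hnorm
    ys <- yaw_solutions(hx, beta)
    use_plus <- abs(angle_diff(ys$yaw_plus, yaw_true)) <=
      abs(angle_diff(ys$yaw_minus, yaw_true))
    yaw_hat <- ifelse(use_plus, ys$yaw_plus, ys$yaw_minus)
    alpha_hat <- wrap_angle(atan2d(hnorm * sind(yaw_hat - beta), field$h_d))
    roll_hat <- wrap_angle(atan2d(hb$h_y, hb$h_z) + alpha_hat)
    tibble::tibble(
      heading_mag = g$heading_mag, pitch = p, roll = g$roll, hx = hx,
      valid = ys$valid,
      error = ifelse(ys$valid, abs(angle_diff(g$roll, roll_hat)), NA_real_)
    )
  })
  structure(dplyr::bind_rows(grids),
            class = c("pitch_error_grid", class(tibble::tibble())))
}

#' Width of the invalid-yaw heading window
#'
#' Helper summarizing a [pitch_error_grid()]: per pitch value, the number of
#' heading columns containing any invalid cell. Non-decreasing in |pitch|.
#'
#' @param grid A `pitch_error_grid`.
#' @return A tibble with `pitch` and `invalid_headings` columns.
#' @export
invalid_window_width <- function(grid) {
  grid |>
    dplyr::group_by(.data$pitch, .data$heading_mag) |>
    dplyr::summarise(any_invalid = any(!.data$valid), .groups = "drop_last") |>
    dplyr::summarise(invalid_headings = sum(.data$any_invalid),
                     .groups = "drop")
}
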