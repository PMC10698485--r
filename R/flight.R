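#' Control roll angle from accelerometer sway/heave channels
#'
#' For a slowly rotated (negligible centripetal acceleration) logger, gravity
#' distributes over the sway and heave axes and roll is the four-quadrant
#' arctangent \eqn{\phi = \mathrm{atan2}(A_y, A_z)}. Used as the control
#' against magnetometer-derived roll; not valid in dynamic-soaring flight,
#' where centripetal acceleration contaminates the heave axis.
#'
#' @param a_y,a_z Sway and heave accelerations (g), vectors.
#' @return Roll in degrees, (-180, 180].
#' @examples
#' accel_roll(0, 1)        # 0: level, 1 g on heave
#' accel_roll(0.5, 0.866)  # 30
#' @export
accel_roll <- function(a_y, a_z) {
  if (any(a_y == 0 & a_z == 0, na.rm = TRUE)) {
    stop("degenerate accelerometer sample: A_y = A_z = 0", call. = FALSE)
  }
  wrap_angle(atan2d(a_y, a_z))
}

series_rate <- function(series) {
  if (nrow(series) < 2) return(NA_real_)
  1 / stats::median(diff(series$t))
}

#' Resample a roll series to a lower rate by nearest-sample selection
#'
#' Angles are not value-interpolated (interpolating across a wrap fabricates
#' values); instead the time-nearest sample is selected on the target grid,
#' matching how a 40 Hz magnetometer series is down-scaled to 24 Hz video.
#'
#' @param series A data frame with columns `t` (seconds) and `roll`
#'   (degrees).
#' @param target_rate Target rate, Hz (must not exceed the source rate).
#' @param offset_s Shift of the target grid, seconds (for aligning to a
#'   reference series; see [align_series()]).
#' @return A tibble with `t` (target grid) and `roll`.
#' @export
resample_roll <- function(series, target_rate = 24, offset_s = 0) {
  stopifnot(all(c("t", "roll") %in% names(series)))
  if (nrow(series) == 0) return(tibble::as_tibble(series))
  src_rate <- series_rate(series)
  if (!is.na(src_rate) && target_rate > src_rate * (1 + 1e-6)) {
    stop(sprintf("target rate %.3g Hz exceeds source rate %.3g Hz",
                 target_rate, src_rate), call. = FALSE)
  }
  t0 <- series$t[1] + offset_s
  grid <- seq(t0, max(series$t), by = 1 / target_rate)
  idx <- nearest_index(series$t, grid)
  tibble::tibble(t = grid, roll = series$roll[idx])
}

nearest_index <- function(t_src, t_query) {
  i <- findInterval(t_query, t_src)
  i[i < 1] <- 1L
  ip1 <- pmin(i + 1L, length(t_src))
  closer_next <- abs(t_src[ip1] - t_query) < abs(t_query - t_src[i])
  ifelse(closer_next, ip1, i)
}

#' Binned wrap-safe roll error between two series
#'
#' Subtracts the estimate from the reference with angular wrapping (the error
#' between 179 and -179 degrees is 2, never 358) and summarizes the absolute
#' error per time bin, mirroring per-video-file validation bins. Symmetric
#' under swapping the two series.
#'
#' @param estimate,reference Data frames with columns `t` and `roll` on a
#'   common time grid (same timestamps within `tol_s`).
#' @param bin_s Bin duration, seconds (300 = one 5-min video file).
#' @param tol_s Grid-match tolerance, seconds.
#' @return A tibble with one row per bin: `bin_start`, `bin_duration`,
#'   `mean_abs_error`, `sd`, `n_samples`, and per-source roll ranges
#'   (`est_min`, `est_max`, `ref_min`, `ref_max`), all in degrees.
#' @export
binned_roll_error <- function(estimate, reference, bin_s = 300,
                              tol_s = 1e-6) {
  stopifnot(all(c("t", "roll") %in% names(estimate)),
            all(c("t", "roll") %in% names(reference)))
  if (nrow(estimate) != nrow(reference) ||
      any(abs(estimate$t - reference$t) > tol_s)) {
    stop("series are not on a common time grid; resample/align them first ",
         "(see resample_roll(), align_series())", call. = FALSE)
  }
  err <- abs(angle_diff(reference$roll, estimate$roll))
  keep <- !is.na(err)
  tibble::tibble(
    t = estimate$t[keep], err = err[keep],
    est = estimate$roll[keep], ref = reference$roll[keep]
  ) |>
    dplyr::mutate(bin_start = min(.data$t) +
                    bin_s * floor((.data$t - min(.data$t)) / bin_s)) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(
      bin_duration = bin_s,
      mean_abs_error = mean(.data$err),
      sd = stats::sd(.data$err),
      n_samples = dplyr::n(),
      est_min = min(.data$est), est_max = max(.data$est),
      ref_min = min(.data$ref), ref_max = max(.data$ref),
      .groups = "drop"
    )
}

#' Count dynamic-soaring cycles from roll-angle peaks
#'
#' After optional moving-average smoothing, zero crossings of the roll series
#' are located; within each inter-crossing segment the sample of largest
#' |roll| is a candidate peak, and candidates below the noise floor
#' `min_peak_deg` are discarded. By default each retained peak counts as one
#' cycle (half-cycle banking events, matching per-flight counts of hundreds
#' over 1-2 h); `per = "pair"` counts a positive+negative peak pair as one.
#'
#' @param series Data frame with columns `t`, `roll`.
#' @param min_peak_deg Minimum |roll| for a peak to count, degrees.
#' @param smooth_window_s Moving-average window, seconds (0 disables).
#' @param per `"peak"` or `"pair"`.
#' @return A `cycle_set` tibble of peaks (`t`, `roll`) with attributes
#'   `count` and `per`; `glance()` summarizes it.
#' @export
count_cycles <- function(series, min_peak_deg = 5, smooth_window_s = 0.5,
                         per = c("peak", "pair")) {
  per <- match.arg(per)
  stopifnot(all(c("t", "roll") %in% names(series)))
  x <- series$roll
  if (nrow(series) >= 3 && smooth_window_s > 0) {
    rate <- series_rate(series)
    k <- max(1L, round(smooth_window_s * rate))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && k <= nrow(series)) x <- moving_average(x, k)
  }
  s <- sign(x)
  seg <- cumsum(c(1, abs(diff(s)) > 0))
  peaks <- tibble::tibble(t = series$t, roll = series$roll,
                          smoothed = x, seg = seg) |>
    dplyr::filter(.data$smoothed != 0) |>
    dplyr::group_by(.data$seg) |>
    dplyr::slice_max(abs(.data$smoothed), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(abs(.data$smoothed) >= min_peak_deg) |>
    dplyr::select("t", "roll")
  count <- if (per == "pair") {
    min(sum(peaks$roll > 0), sum(peaks$roll < 0))
  } else {
    nrow(peaks)
  }
  structure(peaks, count = count, per = per,
            class = c("cycle_set", class(tibble::tibble())))
}

# centred moving average; the window shrinks symmetrically at the edges
moving_average <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
glance.cycle_set <- function(x, ...) {
  tibble::tibble(
    count = attr(x, "count"),
    per = attr(x, "per"),
    n_peaks = nrow(x),
    mean_abs_peak = if (nrow(x)) mean(abs(x$roll)) else NA_real_
  )
}

#' Estimate the time offset between two roll series
#'
#' Replaces manual visual synchronization with a reproducible grid search:
#' the offset within `max_offset_s` minimizing the mean absolute wrapped
#' difference between the shifted estimate and the reference. A 100 ms
#' mismatch can cost up to ~10 degrees of apparent error at dynamic-soaring
#' roll rates, so sub-sample alignment matters.
#'
#' @param estimate,reference Data frames with columns `t`, `roll`, on
#'   (near-)uniform grids.
#' @param max_offset_s Search half-range, seconds.
#' @param step_s Search step; defaults to the reference sample interval.
#' @return A one-row tibble: `offset_s` (add to the estimate's clock) and
#'   `mae` at the optimum.
#' @export
align_series <- function(estimate, reference, max_offset_s = 2,
                         step_s = NULL) {
  stopifnot(all(c("t", "roll") %in% names(estimate)),
            all(c("t", "roll") %in% names(reference)))
  if (is.null(step_s)) step_s <- 1 / series_rate(reference)
  offsets <- seq(-max_offset_s, max_offset_s, by = step_s)
  mae <- vapply(offsets, function(off) {
    idx <- nearest_index(estimate$t + off, reference$t)
    mean(abs(angle_diff(reference$roll, estimate$roll[idx])), na.rm = TRUE)
  }, numeric(1))
  best <- which.min(mae)
  tibble::tibble(offset_s = offsets[best], mae = mae[best])
}
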