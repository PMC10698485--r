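#' Normalize the surge-axis magnetometer reading
#'
#' Divides the body-frame surge (x) component by the horizontal norm of the
#' reference field, giving the dimensionless \eqn{h_x = H_x / \|H_{NE}\|_2}
#' whose arccosine yields the yaw solutions. Values outside \[-1, 1\] are
#' returned unchanged: they are meaningful, signalling noise or
#' miscalibration (or a heading at magnetic north/south), and are flagged
#' invalid downstream rather than clamped.
#'
#' @param h_x Surge-axis field measurements (nT), any length.
#' @param field A [reference_field()].
#' @return Dimensionless numeric vector.
#' @export
normalize_hx <- function(h_x, field) {
  stopifnot(is_reference_field(field))
  if (field$horizontal_norm == 0) {
    stop("degenerate reference field: zero horizontal component ",
         "(magnetic pole)", call. = FALSE)
  }
  h_x / field$horizontal_norm
}

#' Two-branch yaw solution
#'
#' Inverts \eqn{h_x = \cos(\varphi - \beta)}: \eqn{\varphi = \pm\cos^{-1}(h_x)
#' + \beta}. The sign lost in the arccosine is unavoidable, so both branches
#' are returned; [disambiguate_branches()] chooses between them over
#' dynamic-soaring windows. When \eqn{|h_x| > 1} no yaw exists and the sample
#' is flagged invalid (a value, not an error, so series processing can
#' interpolate across such runs).
#'
#' @param h_x Dimensionless normalized surge readings (see [normalize_hx()]).
#' @param beta Magnetic declination in degrees.
#' @return A tibble with columns `valid`, `yaw_plus`, `yaw_minus`
#'   (degrees in (-180, 180], `NA` where invalid).
#' @examples
#' yaw_solutions(0, -27)  # (63, -117)
#' yaw_solutions(1.01, 0) # invalid
#' @export
yaw_solutions <- function(h_x, beta) {
  valid <- is.finite(h_x) & abs(h_x) <= 1
  acv <- rep(NA_real_, length(h_x))
  acv[valid] <- acosd(pmin(pmax(h_x[valid], -1), 1))
  tibble::tibble(
    valid = valid,
    yaw_plus = wrap_angle(acv + beta),
    yaw_minus = wrap_angle(-acv + beta)
  )
}

#' Auxiliary angle from the down axis
#'
#' \eqn{\alpha = \mathrm{atan2}(\|H_{NE}\|_2 \sin(\varphi - \beta),\ H_D)},
#' the angle, measured from the positive down axis, of the reference field
#' projected into the plane orthogonal to the surge axis. With the NED
#' convention the bottom hemisphere is positive; in the Southern Hemisphere
#' (upward field, \eqn{H_D < 0}) flight along the declination gives
#' \eqn{\alpha = 180}.
#'
#' @param yaw Yaw angle(s) in degrees.
#' @param field A [reference_field()].
#' @return \eqn{\alpha} in degrees, in (-180, 180].
#' @export
alpha_angle <- function(yaw, field) {
  stopifnot(is_reference_field(field))
  num <- field$horizontal_norm * sind(yaw - field$declination)
  if (field$h_d == 0 && any(abs(num) < 1e-12, na.rm = TRUE)) {
    stop("degenerate geometry: flight along the field line on the magnetic ",
         "equator (H_D = 0 and yaw = declination); alpha is undefined",
         call. = FALSE)
  }
  wrap_angle(atan2d(num, field$h_d))
}

#' Roll angle from the sway/heave readings and alpha
#'
#' \eqn{\phi = \mathrm{atan2}(H_y, H_z) + \alpha}, a four-quadrant arctangent
#' preserving the sign, wrapped to (-180, 180].
#'
#' @param h_y,h_z Sway- and heave-axis field measurements (nT).
#' @param alpha Auxiliary angle(s) in degrees (see [alpha_angle()]).
#' @return Roll in degrees, in (-180, 180].
#' @export
roll_angle <- function(h_y, h_z, alpha) {
  if (any(h_y == 0 & h_z == 0, na.rm = TRUE)) {
    stop("degenerate sample: H_y = H_z = 0 (yaw coincides with the field ",
         "direction); roll is undefined", call. = FALSE)
  }
  wrap_angle(atan2d(h_y, h_z) + alpha)
}

# field argument -> per-sample vectors (list of hn, he, hd, hnorm, beta)
field_vectors <- function(field, samples) {
  if (is_reference_field(field)) {
    if (field$horizontal_norm == 0) {
      stop("degenerate reference field: zero horizontal component ",
           "(magnetic pole)", call. = FALSE)
    }
    list(hd = field$h_d, hnorm = field$horizontal_norm,
         beta = field$declination)
  } else if (is.data.frame(field)) {
    need <- c("h_n", "h_e", "h_d")
    if (!all(need %in% names(field))) {
      stop("per-sample `field` must have columns h_n, h_e, h_d ",
           "(see field_along_track())", call. = FALSE)
    }
    if (nrow(field) != nrow(samples)) {
      stop("per-sample `field` must have one row per sample", call. = FALSE)
    }
    hnorm <- sqrt(field$h_n^2 + field$h_e^2)
    if (any(hnorm == 0)) {
      stop("degenerate reference field at sample ", which(hnorm == 0)[1],
           ": zero horizontal component (magnetic pole)", call. = FALSE)
    }
    list(hd = field$h_d, hnorm = hnorm,
         beta = atan2d(field$h_e, field$h_n))
  } else {
    stop("`field` must be a reference_field or a per-sample field data frame",
         call. = FALSE)
  }
}

#' Choose between the two yaw/roll branches over soaring windows
#'
#' Dynamic-soaring roll must cross zero within each ~10 s cycle, so over a
#' window the correct branch oscillates about zero. The default rule picks,
#' per non-overlapping window, the branch with the smaller
#' \eqn{|\min(\phi) + \max(\phi)|} over the window's valid samples
#' (`rule = "minmax"`); `rule = "mean"` picks the branch with the smaller
#' \eqn{|\mathrm{mean}(\phi)|}, suited to shorter (2-5 s) windows. Ties go to
#' the plus branch (the branches coincide exactly when \eqn{|h_x| = 1}).
#' Windows with no valid samples inherit the previous window's choice
#' (leading ones take the first decided choice).
#'
#' @param solutions A tibble with columns `t`, `valid`, `roll_plus`,
#'   `roll_minus` (as produced inside [solve_posture()]).
#' @param window_s Window length in seconds, anchored at the series start.
#' @param rule `"minmax"` or `"mean"`.
#' @return `solutions` with a `branch` column (`"plus"`, `"minus"`, or
#'   `"undecided"` when no window could be decided).
#' @export
disambiguate_branches <- function(solutions, window_s = 10,
                                  rule = c("minmax", "mean")) {
  rule <- match.arg(rule)
  if (nrow(solutions) == 0) {
    return(dplyr::mutate(solutions, branch = character(0)))
  }
  w <- floor((solutions$t - solutions$t[1]) / window_s)
  score <- function(x) {
    if (rule == "minmax") abs(min(x) + max(x)) else abs(mean(x))
  }
  per_w <- solutions |>
    dplyr::mutate(.w = w) |>
    dplyr::group_by(.data$.w) |>
    dplyr::summarise(
      choice = if (!any(.data$valid)) NA_character_
      else if (score(.data$roll_plus[.data$valid]) <=
               score(.data$roll_minus[.data$valid])) "plus" else "minus",
      .groups = "drop"
    )
  ch <- per_w$choice
  ch <- fill_forward_chr(ch)
  ch <- rev(fill_forward_chr(rev(ch)))       # leading undecided windows
  ch[is.na(ch)] <- "undecided"
  per_w$choice <- ch
  solutions$branch <- per_w$choice[match(w, per_w$.w)]
  solutions
}

fill_forward_chr <- function(x) {
  for (i in seq_along(x)) {
    if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  }
  x
}

# previous / nearest valid index for each row; 0 where none
fill_index <- function(valid, t, method) {
  idx <- which(valid)
  n <- length(valid)
  if (length(idx) == 0) return(integer(n))
  prev <- idx[pmax(findInterval(seq_len(n), idx), 1)]
  prev[findInterval(seq_len(n), idx) == 0] <- 0L
  if (method == "previous") return(prev)
  pos <- findInterval(seq_len(n), idx)
  nxt <- ifelse(pos < length(idx), idx[pos + 1], 0L)
  out <- prev
  for (i in seq_len(n)) {
    if (prev[i] == 0L) out[i] <- nxt[i]
    else if (nxt[i] != 0L &&
             abs(t[nxt[i]] - t[i]) < abs(t[i] - t[prev[i]])) out[i] <- nxt[i]
  }
  out
}

#' Solve a magnetometer series for yaw and roll under the zero-pitch model
#'
#' The full estimation pipeline: per sample, normalize the surge reading
#' ([normalize_hx()]), invert for the two yaw branches ([yaw_solutions()]),
#' compute \eqn{\alpha} ([alpha_angle()]) and roll ([roll_angle()]) on each
#' branch; then choose a branch per soaring window
#' ([disambiguate_branches()]); finally, samples with \eqn{|h_x| > 1}
#' (headings at magnetic north/south, or noise) get their roll interpolated
#' by substituting the previous (or nearest) valid \eqn{\alpha} into the
#' roll equation, on the assumption that \eqn{\alpha} changes slowly.
#' The result is a pure, deterministic function of its inputs.
#'
#' @param samples A data frame with columns `t` (seconds, non-decreasing),
#'   `h_x`, `h_y`, `h_z` (calibrated body-frame field, nT). Extra columns are
#'   preserved.
#' @param field A [reference_field()], or a per-sample field data frame from
#'   [field_along_track()] (columns `h_n`, `h_e`, `h_d`, one row per sample).
#' @param window_s Branch-disambiguation window in seconds (~ one
#'   dynamic-soaring cycle).
#' @param alpha_fill `"previous"` (causal, the default) or `"nearest"`:
#'   which valid \eqn{\alpha} to substitute across invalid runs.
#' @param rule Branch-scoring rule, see [disambiguate_branches()].
#' @return A `posture_solution` tibble: the input columns plus `hx`
#'   (dimensionless), `valid`, `interpolated`, both branches (`yaw_plus`,
#'   `yaw_minus`, `alpha_plus`, `alpha_minus`, `roll_plus`, `roll_minus`),
#'   `branch`, and the chosen `yaw`, `alpha`, `roll` (degrees; `yaw` is `NA`
#'   for interpolated samples).
#' @examples
#' f <- reference_field(11355, -10954, -27690)
#' tr <- soaring_trajectory(duration_s = 30)
#' sim <- simulate_stream(tr, sim_config(f))
#' sol <- solve_posture(sim, f)
#' summary(abs(angle_diff(sol$roll, sim$roll_true)))
#' @export
solve_posture <- function(samples, field, window_s = 10,
                          alpha_fill = c("previous", "nearest"),
                          rule = c("minmax", "mean")) {
  alpha_fill <- match.arg(alpha_fill)
  rule <- match.arg(rule)
  need <- c("t", "h_x", "h_y", "h_z")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("`samples` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) {
    out <- dplyr::mutate(samples, hx = numeric(0), valid = logical(0),
                         interpolated = logical(0), yaw_plus = numeric(0),
                         yaw_minus = numeric(0), alpha_plus = numeric(0),
                         alpha_minus = numeric(0), roll_plus = numeric(0),
                         roll_minus = numeric(0), branch = character(0),
                         yaw = numeric(0), alpha = numeric(0),
                         roll = numeric(0))
    return(new_posture_solution(out, window_s, rule))
  }
  if (is.unsorted(samples$t)) {
    stop("`samples` must be ordered in time", call. = FALSE)
  }
  fv <- field_vectors(field, samples)
  hx <- samples$h_x / fv$hnorm
  ys <- yaw_solutions(hx, fv$beta)
  valid <- ys$valid
  sin_d <- rep(NA_real_, length(hx))
  sin_d[valid] <- sqrt(pmax(0, 1 - hx[valid]^2))
  deg_alpha <- valid & fv$hnorm * sin_d < 1e-9 & fv$hd == 0
  if (any(deg_alpha, na.rm = TRUE)) {
    stop("degenerate geometry at sample ", which(deg_alpha)[1],
         ": flight along the field line on the magnetic equator",
         call. = FALSE)
  }
  alpha_plus <- wrap_angle(atan2d(fv$hnorm * sin_d, fv$hd))
  alpha_minus <- wrap_angle(atan2d(-fv$hnorm * sin_d, fv$hd))
  deg_roll <- samples$h_y == 0 & samples$h_z == 0
  if (any(deg_roll & valid)) {
    stop("degenerate sample ", which(deg_roll & valid)[1],
         ": H_y = H_z = 0 (yaw coincides with the field direction)",
         call. = FALSE)
  }
  base <- atan2d(samples$h_y, samples$h_z)
  sol <- dplyr::mutate(
    samples,
    hx = hx, valid = valid,
    yaw_plus = ys$yaw_plus, yaw_minus = ys$yaw_minus,
    alpha_plus = alpha_plus, alpha_minus = alpha_minus,
    roll_plus = wrap_angle(base + alpha_plus),
    roll_minus = wrap_angle(base + alpha_minus)
  )
  sol <- disambiguate_branches(sol, window_s = window_s, rule = rule)
  plus <- sol$branch != "minus"          # undecided ties resolve to plus
  alpha_chosen <- ifelse(plus, sol$alpha_plus, sol$alpha_minus)
  fi <- fill_index(valid, sol$t, alpha_fill)
  can_fill <- !valid & fi > 0
  can_fill[deg_roll] <- FALSE          # H_y = H_z = 0: roll undefined
  alpha_fill_v <- rep(NA_real_, nrow(sol))
  alpha_fill_v[can_fill] <- alpha_chosen[fi[can_fill]]
  sol$interpolated <- can_fill
  sol$alpha <- ifelse(valid, alpha_chosen, alpha_fill_v)
  sol$yaw <- ifelse(valid, ifelse(plus, sol$yaw_plus, sol$yaw_minus),
                    NA_real_)
  sol$roll <- wrap_angle(ifelse(
    valid, ifelse(plus, sol$roll_plus, sol$roll_minus),
    base + alpha_fill_v))
  sol$branch[!valid] <- "undecided"
  new_posture_solution(sol, window_s, rule)
}

new_posture_solution <- function(x, window_s, rule) {
  structure(x, window_s = window_s, rule = rule,
            class = c("posture_solution", class(tibble::tibble())))
}

#' Solve a single magnetometer sample
#'
#' One-sample convenience wrapper around the per-sample operations, with an
#' optional externally supplied prior \eqn{\alpha} for the interpolation path
#' (used when \eqn{|h_x| > 1}).
#'
#' @param h_x,h_y,h_z Body-frame field components (nT).
#' @param field A [reference_field()].
#' @param prior_alpha Previous valid \eqn{\alpha} in degrees, or `NULL`.
#' @return A one-row tibble with `hx`, `valid`, `interpolated`, the branch
#'   pair, and `roll` (interpolated when invalid and `prior_alpha` given;
#'   `NA` when invalid with nothing to interpolate from).
#' @export
solve_sample <- function(h_x, h_y, h_z, field, prior_alpha = NULL) {
  stopifnot(is_reference_field(field))
  hx <- normalize_hx(h_x, field)
  ys <- yaw_solutions(hx, field$declination)
  base <- atan2d(h_y, h_z)
  if (ys$valid) {
    ap <- alpha_angle(ys$yaw_plus, field)
    am <- alpha_angle(ys$yaw_minus, field)
    tibble::tibble(
      hx = hx, valid = TRUE, interpolated = FALSE,
      yaw_plus = ys$yaw_plus, yaw_minus = ys$yaw_minus,
      alpha_plus = ap, alpha_minus = am,
      roll_plus = roll_angle(h_y, h_z, ap),
      roll_minus = roll_angle(h_y, h_z, am),
      roll = NA_real_
    )
  } else {
    roll <- if (is.null(prior_alpha)) NA_real_
    else roll_angle(h_y, h_z, prior_alpha)
    tibble::tibble(
      hx = hx, valid = FALSE, interpolated = !is.null(prior_alpha),
      yaw_plus = NA_real_, yaw_minus = NA_real_,
      alpha_plus = NA_real_, alpha_minus = NA_real_,
      roll_plus = NA_real_, roll_minus = NA_real_,
      roll = roll
    )
  }
}

#' @export
glance.posture_solution <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_valid = sum(x$valid),
    pct_valid = if (nrow(x)) 100 * mean(x$valid) else NA_real_,
    pct_interpolated = if (nrow(x)) 100 * mean(x$interpolated) else NA_real_,
    window_s = attr(x, "window_s"),
    rule = attr(x, "rule")
  )
}
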