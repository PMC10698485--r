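#' Fit a hard-/soft-iron magnetometer calibration
#'
#' Raw magnetometer readings from a sensor rotated through diverse
#' orientations lie on an ellipsoid: hard-iron effects translate its centre,
#' soft-iron effects stretch and shear it. The fit is a linear least-squares
#' solution of the general quadric
#' \eqn{x^\top A x + 2 b^\top x = 1}, from which the offset is the ellipsoid
#' centre \eqn{-A^{-1} b} and the soft-iron correction the symmetric square
#' root of the centred quadratic form, normalized to unit determinant so it
#' captures shape only. The intensity scale maps corrected units to nT by
#' making the median corrected norm equal `reference_intensity` — required
#' because the yaw inversion divides body-frame readings by reference-frame
#' norms, so the two must be commensurate.
#'
#' @param raw A data frame or matrix of raw triples (columns `h_x`, `h_y`,
#'   `h_z`, or any three numeric columns in sensor units).
#' @param reference_intensity Total field intensity at the calibration site,
#'   nT (e.g. `wmm_field(...)$total_intensity`).
#' @param min_sv_ratio Conditioning floor: smallest/largest singular value of
#'   the centred cloud must exceed this (coplanar rotation sets cannot
#'   constrain the ellipsoid).
#' @return A `mag_calibration` object: `offset` (length-3, sensor units),
#'   `soft_iron` (3x3 symmetric positive-definite, unit determinant),
#'   `intensity_scale` (sensor units to nT), and fit diagnostics.
#' @seealso [apply_calibration()], [write_calibration()], [tidy.mag_calibration()]
#' @export
fit_calibration <- function(raw, reference_intensity,
                            min_sv_ratio = 0.05) {
  x <- as.matrix(raw_triples(raw))
  if (nrow(x) < 9) {
    stop("calibration needs at least 9 samples spanning diverse orientations",
         call. = FALSE)
  }
  if (!is.numeric(reference_intensity) || reference_intensity <= 0) {
    stop("`reference_intensity` must be a positive field intensity in nT",
         call. = FALSE)
  }
  ctr <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] / sv[1] < min_sv_ratio) {
    stop(sprintf(
      paste0("calibration cloud is ill-conditioned (singular-value ratio ",
             "%.3g < %.3g): rotations are near-coplanar; rotate the sensor ",
             "about all three axes"), sv[3] / sv[1], min_sv_ratio),
      call. = FALSE)
  }
  d <- cbind(x[, 1]^2, x[, 2]^2, x[, 3]^2,
             2 * x[, 1] * x[, 2], 2 * x[, 1] * x[, 3], 2 * x[, 2] * x[, 3],
             2 * x)
  p <- stats::lsfit(d, rep(1, nrow(x)), intercept = FALSE)$coefficients
  a <- matrix(c(p[1], p[4], p[5],
                p[4], p[2], p[6],
                p[5], p[6], p[3]), 3, 3)
  b <- p[7:9]
  offset <- drop(-solve(a, b))
  # (x-c)' A (x-c) = 1 + c'Ac  (since x'Ax + 2b'x = 1 and b = -Ac)
  k <- 1 + drop(crossprod(offset, a %*% offset))
  w <- a / k
  eg <- eigen(w, symmetric = TRUE)
  if (any(eg$values <= 0)) {
    stop("calibration fit did not produce a positive-definite ellipsoid; ",
         "check the input for outliers or insufficient rotation coverage",
         call. = FALSE)
  }
  s0 <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  soft <- s0 / det(s0)^(1 / 3)
  corr_norm <- sqrt(rowSums((sweep(x, 2, offset) %*% soft)^2))
  scale_nt <- reference_intensity / stats::median(corr_norm)
  resid <- scale_nt * corr_norm / reference_intensity - 1
  structure(
    list(offset = offset, soft_iron = soft, intensity_scale = scale_nt,
         n = nrow(x), rms_residual = sqrt(mean(resid^2)),
         sv_ratio = sv[3] / sv[1],
         reference_intensity = reference_intensity),
    class = "mag_calibration"
  )
}

raw_triples <- function(raw) {
  if (is.matrix(raw)) {
    stopifnot(ncol(raw) == 3)
    return(raw)
  }
  nm <- intersect(c("h_x", "h_y", "h_z"), names(raw))
  if (length(nm) == 3) return(as.matrix(raw[, nm]))
  num <- vapply(raw, is.numeric, logical(1))
  if (sum(num) < 3) stop("need three numeric columns of raw readings",
                         call. = FALSE)
  as.matrix(raw[, which(num)[1:3]])
}

#' Apply a fitted calibration to raw readings
#'
#' `corrected = intensity_scale * soft_iron %*% (raw - offset)`, returning
#' body-frame field components in nT.
#'
#' @param model A `mag_calibration` from [fit_calibration()] or
#'   [read_calibration()].
#' @param raw Raw triples (data frame or matrix); data-frame inputs keep
#'   their other columns.
#' @return A tibble with calibrated `h_x`, `h_y`, `h_z` columns (nT).
#' @export
apply_calibration <- function(model, raw) {
  stopifnot(inherits(model, "mag_calibration"))
  x <- raw_triples(raw)
  corr <- model$intensity_scale * sweep(x, 2, model$offset) %*%
    t(model$soft_iron)
  out <- if (is.data.frame(raw)) tibble::as_tibble(raw) else tibble::tibble(
    .rows = nrow(corr))
  out$h_x <- corr[, 1]
  out$h_y <- corr[, 2]
  out$h_z <- corr[, 3]
  out
}

#' Serialize a calibration model to / from JSON
#'
#' @param model A `mag_calibration`.
#' @param path File path for the JSON document.
#' @return `read_calibration()` returns the `mag_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "mag_calibration"))
  jsonlite::write_json(
    list(offset = model$offset,
         soft_iron = model$soft_iron,
         intensity_scale = model$intensity_scale,
         reference_intensity = model$reference_intensity,
         n = model$n, rms_residual = model$rms_residual),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(offset = as.numeric(j$offset),
         soft_iron = matrix(as.numeric(j$soft_iron), 3, 3, byrow = TRUE),
         intensity_scale = as.numeric(j$intensity_scale),
         n = j$n, rms_residual = j$rms_residual, sv_ratio = NA_real_,
         reference_intensity = as.numeric(j$reference_intensity)),
    class = "mag_calibration"
  )
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration>\n")
  cat(sprintf("  offset: (%.2f, %.2f, %.2f) sensor units\n",
              x$offset[1], x$offset[2], x$offset[3]))
  cat(sprintf("  intensity scale: %.4g nT per unit; rms sphere residual %.2f%%\n",
              x$intensity_scale, 100 * x$rms_residual))
  invisible(x)
}

#' Tidy a magnetometer calibration fit
#'
#' @param x A `mag_calibration`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (offsets, soft-iron entries,
#'   scale); `glance()`: one-row fit summary.
#' @export
tidy.mag_calibration <- function(x, ...) {
  si <- x$soft_iron
  tibble::tibble(
    term = c("offset_x", "offset_y", "offset_z",
             paste0("soft_iron_", c("xx", "xy", "xz", "yy", "yz", "zz")),
             "intensity_scale"),
    estimate = c(x$offset, si[1, 1], si[1, 2], si[1, 3],
                 si[2, 2], si[2, 3], si[3, 3], x$intensity_scale)
  )
}

#' @rdname tidy.mag_calibration
#' @export
glance.mag_calibration <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rms_residual = x$rms_residual,
    sv_ratio = x$sv_ratio,
    reference_intensity = x$reference_intensity
  )
}

#' Segment-wise recalibration over long deployments
#'
#' Field intensity and residual iron effects can drift over multi-day
#' deployments; this splits the series into contiguous segments and fits one
#' calibration per segment. Off by default in the solve pipeline.
#'
#' @param raw Data frame with a `t` column plus raw triples.
#' @param reference_intensity nT, as in [fit_calibration()].
#' @param segment_s Segment length in seconds.
#' @return A tibble with one row per segment: `segment`, `t_start`, `t_end`
#'   and a `model` list-column of `mag_calibration` objects.
#' @export
fit_calibration_segments <- function(raw, reference_intensity,
                                     segment_s = 86400) {
  stopifnot("t" %in% names(raw))
  seg <- floor((raw$t - raw$t[1]) / segment_s)
  raw |>
    dplyr::mutate(.seg = seg) |>
    dplyr::group_by(.data$.seg) |>
    dplyr::group_map(~ tibble::tibble(
      segment = .y$.seg, t_start = min(.x$t), t_end = max(.x$t),
      model = list(fit_calibration(.x, reference_intensity))
    )) |>
    dplyr::bind_rows()
}
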