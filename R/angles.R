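#' Angle utilities
#'
#' All public interfaces in this package work in degrees; these helpers keep
#' angles on the principal branch and compute wrap-safe differences.
#'
#' @param x Numeric vector of angles in degrees.
#' @return `wrap_angle()` returns angles normalized to (-180, 180];
#'   `angle_diff()` the wrap-safe signed difference `a - b` in (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 360))
#' angle_diff(179, -179) # 2, never 358
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

#' @rdname wrap_angle
#' @param a,b Numeric vectors of angles in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# degree-argument trig, used throughout so the rotation model reads like the
# equations it implements (internal computation in radians)
deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)
sind <- function(x) sin(deg2rad(x))
cosd <- function(x) cos(deg2rad(x))
atan2d <- function(y, x) rad2deg(atan2(y, x))
acosd <- function(x) rad2deg(acos(x))
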