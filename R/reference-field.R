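#' Construct a geomagnetic reference field from its north-east-down components
#'
#' The reference field \eqn{H_i = (H_N, H_E, H_D)} is the local geomagnetic
#' vector in the north-east-down (NED) inertial frame: north along the local
#' meridian, east along the parallel, down positive toward the Earth's centre
#' (so the Southern-Hemisphere field has a negative down component). The
#' derived quantities are the horizontal norm
#' \eqn{\|H_{NE}\|_2 = \sqrt{H_N^2 + H_E^2}}, the magnetic declination
#' \eqn{\beta = \mathrm{atan2}(H_E, H_N)} (degrees east of true north) and the
#' total intensity \eqn{\|H_i\|_2}.
#'
#' @param h_n,h_e,h_d Field components in nT (north, east, down).
#' @return An object of class `reference_field`: a list with elements `h_n`,
#'   `h_e`, `h_d`, `horizontal_norm`, `declination`, `total_intensity`.
#' @examples
#' reference_field(1, 0, 0)  # north-aligned: declination 0
#' reference_field(0, 1, 0)  # east-aligned: declination 90
#' @seealso [wmm_field()] for a model lookup, [field_along_track()] for
#'   GPS-supplemented fields.
#' @export
reference_field <- function(h_n, h_e, h_d) {
  comps <- c(h_n, h_e, h_d)
  if (length(comps) != 3 || !all(is.finite(comps))) {
    stop("`h_n`, `h_e`, `h_d` must be three finite numbers", call. = FALSE)
  }
  if (all(comps == 0)) {
    stop("degenerate reference field: all three components are zero",
         call. = FALSE)
  }
  structure(
    list(
      h_n = h_n, h_e = h_e, h_d = h_d,
      horizontal_norm = sqrt(h_n^2 + h_e^2),
      declination = atan2d(h_e, h_n),
      total_intensity = sqrt(h_n^2 + h_e^2 + h_d^2)
    ),
    class = "reference_field"
  )
}

#' @export
print.reference_field <- function(x, ...) {
  cat("<reference_field>\n")
  cat(sprintf("  H_N %.1f  H_E %.1f  H_D %.1f nT\n", x$h_n, x$h_e, x$h_d))
  cat(sprintf("  declination %.2f deg, horizontal %.1f nT, total %.1f nT\n",
              x$declination, x$horizontal_norm, x$total_intensity))
  invisible(x)
}

#' @export
as.data.frame.reference_field <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

is_reference_field <- function(x) inherits(x, "reference_field")

field_as_tibble <- function(x) tibble::as_tibble(unclass(x))

# ---- geomagnetic model (degree-12 spherical-harmonic synthesis) -------------

#' Read a Gauss-coefficient file in the standard .COF text format
#'
#' The file format is the plain-text layout used to distribute World Magnetic
#' Model coefficients: a header line with the epoch, then one line per
#' spherical-harmonic term `n m g h gdot hdot` (main-field coefficients in nT,
#' secular variation in nT/yr), terminated by lines of 9s.
#'
#' @param path Path to the coefficient file. Defaults to the coefficient set
#'   bundled with the package (epoch 2020.0).
#' @return A list with `epoch` (decimal year), `model` (name from the header)
#'   and `coef` (a tibble with columns `n`, `m`, `g`, `h`, `gdot`, `hdot`).
#' @export
read_wmm_cof <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "WMM2020.COF", package = "magposture")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("geomagnetic model configuration error: coefficient file not found: ",
         path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  epoch <- suppressWarnings(as.numeric(hdr[1]))
  if (!is.finite(epoch)) {
    stop("geomagnetic model configuration error: cannot parse epoch from ",
         "header of ", path, call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^9+$", trimws(body))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (is.null(mat) || ncol(mat) != 6 || anyNA(mat)) {
    stop("geomagnetic model configuration error: malformed coefficient rows",
         call. = FALSE)
  }
  coef <- tibble::as_tibble(as.data.frame(mat))
  names(coef) <- c("n", "m", "g", "h", "gdot", "hdot")
  list(epoch = epoch, model = if (length(hdr) >= 2) hdr[2] else "unknown",
       coef = coef)
}

# Schmidt semi-normalized associated Legendre functions and their colatitude
# derivatives at cos(theta) = ct, up to degree nmax. Standard stable
# recursions; n, m <= 12 so double precision is ample.
schmidt_legendre <- function(ct, st, nmax) {
  P <- matrix(0, nmax + 1L, nmax + 1L)
  dP <- matrix(0, nmax + 1L, nmax + 1L)
  P[1, 1] <- 1
  for (n in 1:nmax) {
    for (m in 0:n) {
      if (n == m) {
        if (n == 1) {
          P[2, 2] <- st
          dP[2, 2] <- ct
        } else {
          k <- sqrt((2 * n - 1) / (2 * n))
          P[n + 1, n + 1] <- k * st * P[n, n]
          dP[n + 1, n + 1] <- k * (st * dP[n, n] + ct * P[n, n])
        }
      } else {
        c1 <- (2 * n - 1) / sqrt(n^2 - m^2)
        c2 <- sqrt(((n - 1)^2 - m^2) / (n^2 - m^2))
        Pm2 <- if (n >= 2) P[n - 1, m + 1] else 0
        dPm2 <- if (n >= 2) dP[n - 1, m + 1] else 0
        P[n + 1, m + 1] <- c1 * ct * P[n, m + 1] - c2 * Pm2
        dP[n + 1, m + 1] <- c1 * (ct * dP[n, m + 1] - st * P[n, m + 1]) -
          c2 * dPm2
      }
    }
  }
  list(P = P, dP = dP)
}

#' Evaluate the geomagnetic reference field from the World Magnetic Model
#'
#' Synthesises the NED field vector from degree-12 Gauss coefficients: the
#' geodetic (WGS84) coordinate is converted to spherical geocentric
#' coordinates, the potential gradient is evaluated through Schmidt
#' semi-normalized associated Legendre recursions with linear secular
#' variation about the model epoch, and the vector is rotated back to the
#' geodetic frame. Altitude is fixed at sea level, appropriate for birds
#' flying within metres of the sea surface.
#'
#' Dates are accepted within `epoch - 0.5` to `epoch + 5.5` years: the model
#' is defined for five years from its epoch and a brief extrapolation through
#' the linear secular-variation terms changes the field by only a few nT.
#'
#' @param lat,lon Geodetic latitude and longitude, WGS84 decimal degrees.
#' @param date Decimal year (e.g. `2019.95`).
#' @param cof A parsed coefficient set from [read_wmm_cof()], or a path to a
#'   .COF file, or `NULL` for the bundled epoch-2020.0 coefficients.
#' @return A [reference_field()] object.
#' @examples
#' marion <- wmm_field(-46, 37, 2019.95)
#' marion$h_d < 0  # Southern-Hemisphere field points upward
#' @export
wmm_field <- function(lat, lon, date, cof = NULL) {
  if (!is.numeric(lat) || !is.numeric(lon) || abs(lat) > 90 || abs(lon) > 360) {
    stop("`lat` must be in [-90, 90] and `lon` in [-180, 360]", call. = FALSE)
  }
  if (is.character(cof) || is.null(cof)) cof <- read_wmm_cof(cof)
  if (date < cof$epoch - 0.5 || date > cof$epoch + 5.5) {
    stop(sprintf(
      "date %.2f outside the validity window of the %.1f coefficient epoch",
      date, cof$epoch), call. = FALSE)
  }
  a_wgs <- 6378.137
  f_wgs <- 1 / 298.257223563
  e2 <- f_wgs * (2 - f_wgs)
  r_ref <- 6371.2
  phi <- deg2rad(lat)
  lam <- deg2rad(lon)
  rc <- a_wgs / sqrt(1 - e2 * sin(phi)^2)
  p <- rc * cos(phi)
  z <- rc * (1 - e2) * sin(phi)
  r <- sqrt(p^2 + z^2)
  phip <- asin(z / r)                 # geocentric latitude
  ct <- sin(phip)                     # cos(colatitude)
  st <- cos(phip)
  nmax <- max(cof$coef$n)
  leg <- schmidt_legendre(ct, st, nmax)
  dt <- date - cof$epoch
  xp <- 0; yp <- 0; zp <- 0
  cf <- cof$coef
  cm <- cos(cf$m * lam)
  sm <- sin(cf$m * lam)
  g <- cf$g + dt * cf$gdot
  h <- cf$h + dt * cf$hdot
  ar <- (r_ref / r)^(cf$n + 2)
  for (i in seq_len(nrow(cf))) {
    n <- cf$n[i]; m <- cf$m[i]
    gc_hs <- g[i] * cm[i] + h[i] * sm[i]
    # X' = -sum ar * (g cos + h sin) dP/dphi'; dP/dphi' = -dP/dtheta
    xp <- xp + ar[i] * gc_hs * leg$dP[n + 1, m + 1]
    if (st > 1e-12) {
      yp <- yp + ar[i] * m * (g[i] * sm[i] - h[i] * cm[i]) *
        leg$P[n + 1, m + 1] / st
    }
    zp <- zp - (n + 1) * ar[i] * gc_hs * leg$P[n + 1, m + 1]
  }
  psi <- phip - phi                   # rotate geocentric -> geodetic
  reference_field(
    h_n = xp * cos(psi) - zp * sin(psi),
    h_e = yp,
    h_d = xp * sin(psi) + zp * cos(psi)
  )
}

# ---- GPS-track fields -------------------------------------------------------

validate_fixes <- function(fixes) {
  need <- c("t", "lat", "lon")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) {
    stop("GPS fixes are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fixes) == 0) stop("empty GPS fix list", call. = FALSE)
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180)) {
    stop("GPS fixes out of range: lat in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  if (is.unsorted(fixes$t, strictly = TRUE)) {
    stop("GPS fixes must be strictly increasing in time", call. = FALSE)
  }
  fixes
}

#' Reference field along a GPS track
#'
#' Associates each query time with a reference field, either from the most
#' recent GPS fix at or before that time (`mode = "per_fix"`, step lookup;
#' times before the first fix use the first fix) or from one anchor
#' coordinate for the whole series (`mode = "single_coordinate"`). Step
#' lookup rather than positional interpolation is used because the field
#' varies negligibly over the few hundred kilometres between typical
#' foraging-trip fixes.
#'
#' @param fixes A data frame of GPS fixes with columns `t` (UTC seconds,
#'   strictly increasing), `lat`, `lon` (WGS84 degrees).
#' @param t Numeric vector of query times (UTC seconds).
#' @param date Decimal year passed to [wmm_field()].
#' @param mode `"per_fix"` or `"single_coordinate"`.
#' @param anchor Optional `c(lat, lon)` anchor overriding the first fix in
#'   `single_coordinate` mode.
#' @param cof Coefficient set or path, as in [wmm_field()].
#' @return A tibble with one row per element of `t`: columns `t`, `h_n`,
#'   `h_e`, `h_d`, `horizontal_norm`, `declination`, `total_intensity`.
#' @export
field_along_track <- function(fixes, t, date,
                              mode = c("per_fix", "single_coordinate"),
                              anchor = NULL, cof = NULL) {
  mode <- match.arg(mode)
  if (is.character(cof) || is.null(cof)) cof <- read_wmm_cof(cof)
  if (mode == "single_coordinate") {
    if (is.null(anchor)) {
      fixes <- validate_fixes(fixes)
      anchor <- c(fixes$lat[1], fixes$lon[1])
    }
    f <- wmm_field(anchor[1], anchor[2], date, cof)
    return(dplyr::bind_cols(tibble::tibble(t = t),
                            field_as_tibble(f)[rep(1, length(t)), ]))
  }
  fixes <- validate_fixes(fixes)
  per_fix <- purrr::map(seq_len(nrow(fixes)), function(i) {
    field_as_tibble(wmm_field(fixes$lat[i], fixes$lon[i], date, cof))
  })
  idx <- findInterval(t, fixes$t)     # 0 before first fix -> clamp to 1
  idx[idx < 1] <- 1L
  dplyr::bind_cols(tibble::tibble(t = t),
                   dplyr::bind_rows(per_fix)[idx, ])
}
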