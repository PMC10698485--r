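parse_timestamps <- function(x, what = "timestamp") {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  parsed <- rep(NA_real_, length(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    need <- is.na(parsed)
    if (!any(need)) break
    parsed[need] <- as.numeric(strptime(x[need], fmt, tz = "UTC"))
  }
  bad <- which(is.na(parsed) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row %d: '%s'", what, bad[1], x[bad[1]]),
         call. = FALSE)
  }
  parsed
}

require_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a magnetometer CSV export
#'
#' Expects columns `timestamp` (ISO-8601 or epoch seconds), `h_x`, `h_y`,
#' `h_z` (calibrated nT, or raw sensor units if a calibration is applied
#' afterwards), and optionally `a_x`, `a_y`, `a_z` accelerometer channels
#' (g). Rows are sorted by time (with a warning if they arrive shuffled);
#' duplicated timestamps are an error naming the row; gaps longer than twice
#' the nominal interval are reported as a warning.
#'
#' @param path CSV file path.
#' @param nominal_rate Expected sampling rate in Hz, for gap detection.
#' @return A tibble with `t` (UTC seconds) plus the data columns.
#' @export
read_mag_csv <- function(path, nominal_rate = 40) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("timestamp", "h_x", "h_y", "h_z"), path)
  df$t <- parse_timestamps(df$timestamp, "timestamp")
  dup <- which(duplicated(df$t))
  if (length(dup)) {
    stop(sprintf("%s: duplicated timestamp at row %d", path, dup[1]),
         call. = FALSE)
  }
  if (is.unsorted(df$t)) {
    warning(path, ": rows were not in time order; sorted", call. = FALSE)
    df <- df[order(df$t), ]
  }
  gaps <- which(diff(df$t) > 2 / nominal_rate)
  if (length(gaps)) {
    warning(sprintf("%s: %d gap(s) longer than %.3g s (first after t = %.3f)",
                    path, length(gaps), 2 / nominal_rate, df$t[gaps[1]]),
            call. = FALSE)
  }
  keep <- intersect(c("t", "h_x", "h_y", "h_z", "a_x", "a_y", "a_z"),
                    names(df))
  tibble::as_tibble(df[, keep])
}

#' Read a GPS track CSV
#'
#' Columns `timestamp` (ISO-8601 or epoch seconds), `lat`, `lon` (WGS84
#' decimal degrees). Fixes must be strictly increasing in time.
#'
#' @param path CSV file path.
#' @return A tibble with columns `t`, `lat`, `lon`.
#' @export
read_gps_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("timestamp", "lat", "lon"), path)
  out <- tibble::tibble(t = parse_timestamps(df$timestamp),
                        lat = df$lat, lon = df$lon)
  validate_fixes(out)
}

#' Read a reference roll-series CSV
#'
#' Columns `timestamp`, `roll_deg` and optionally `source` (e.g. `video`),
#' as produced by horizon-angle extraction from bird-borne video.
#'
#' @param path CSV file path.
#' @return A tibble with columns `t`, `roll`, `source`.
#' @export
read_roll_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("timestamp", "roll_deg"), path)
  tibble::tibble(
    t = parse_timestamps(df$timestamp),
    roll = wrap_angle(df$roll_deg),
    source = if ("source" %in% names(df)) df$source else "reference"
  )
}

#' Write / read a posture solution CSV
#'
#' Fixed column layout: `timestamp, yaw_plus, yaw_minus, roll_plus,
#' roll_minus, roll_chosen, alpha, valid, interpolated, branch`; angles in
#' degrees, flags 0/1, empty cells for absent values. The round trip is
#' lossless to full double precision.
#'
#' @param solution A `posture_solution` from [solve_posture()].
#' @param path Output CSV path.
#' @return `write_posture_csv()` returns `path` invisibly;
#'   `read_posture_csv()` the tibble.
#' @export
write_posture_csv <- function(solution, path) {
  out <- tibble::tibble(
    timestamp = solution$t,
    yaw_plus = ifelse(solution$valid, solution$yaw_plus, NA_real_),
    yaw_minus = ifelse(solution$valid, solution$yaw_minus, NA_real_),
    roll_plus = ifelse(solution$valid, solution$roll_plus, NA_real_),
    roll_minus = ifelse(solution$valid, solution$roll_minus, NA_real_),
    roll_chosen = solution$roll,
    alpha = solution$alpha,
    valid = as.integer(solution$valid),
    interpolated = as.integer(solution$interpolated),
    branch = solution$branch
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_posture_csv
#' @export
read_posture_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("timestamp", "roll_chosen", "valid"), path)
  dplyr::mutate(df, valid = as.logical(.data$valid),
                interpolated = as.logical(.data$interpolated))
}

# ---- run configuration and orchestration ------------------------------------

#' Read a solve-run configuration
#'
#' YAML keys: `input` (magnetometer CSV, required); exactly one reference-
#' field source among `field_vector` (list `h_n`, `h_e`, `h_d` in nT),
#' `field_anchor` (list `lat`, `lon`) or `track` (GPS CSV path); `date`
#' (decimal year, required with `field_anchor`/`track`); optional
#' `calibration` (JSON model path), `window_s` (default 10), `alpha_fill`,
#' `rule`, `reference_roll` (CSV for validation), `resample_rate` (default
#' 24), `bin_s` (default 300), `compare_single_coordinate` (with `track`),
#' `seed`, `out_dir` (required).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$input)) stop("config: `input` is required", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config: `out_dir` is required",
                                 call. = FALSE)
  sources <- c(!is.null(cfg$field_vector), !is.null(cfg$field_anchor),
               !is.null(cfg$track))
  if (sum(sources) != 1) {
    stop("config: exactly one of `field_vector`, `field_anchor`, `track` ",
         "must be given", call. = FALSE)
  }
  if (is.null(cfg$field_vector) && is.null(cfg$date)) {
    stop("config: `date` (decimal year) is required with a model-based field",
         call. = FALSE)
  }
  defaults <- list(window_s = 10, alpha_fill = "previous", rule = "minmax",
                   resample_rate = 24, bin_s = 300,
                   compare_single_coordinate = FALSE, seed = NULL,
                   calibration = NULL, reference_roll = NULL, cof = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[nm] <- defaults[nm]
  }
  structure(cfg, class = "run_config")
}

run_config_field <- function(cfg, samples) {
  if (!is.null(cfg$field_vector)) {
    fv <- cfg$field_vector
    list(field = reference_field(fv$h_n, fv$h_e, fv$h_d), single = NULL)
  } else if (!is.null(cfg$field_anchor)) {
    fa <- cfg$field_anchor
    list(field = wmm_field(fa$lat, fa$lon, cfg$date, cfg$cof), single = NULL)
  } else {
    fixes <- read_gps_csv(cfg$track)
    list(
      field = field_along_track(fixes, samples$t, cfg$date, "per_fix",
                                cof = cfg$cof),
      single = field_along_track(fixes, samples$t, cfg$date,
                                 "single_coordinate", cof = cfg$cof)
    )
  }
}

#' Run the full solve workflow from a configuration
#'
#' Reads the magnetometer CSV, applies an optional calibration model, builds
#' the reference field (static vector, model lookup at an anchor, or along a
#' GPS track), solves for posture, and writes the outputs plus a JSON run
#' manifest (configuration echo, package version, seed) so a run can be
#' reproduced bit-for-bit. With a `track` source and
#' `compare_single_coordinate: true` it additionally solves with the
#' deployment-site field alone and reports the wrap-safe roll/yaw differences
#' between the two solutions. With `reference_roll` it resamples the
#' solution to the reference rate and writes binned validation errors.
#'
#' @param cfg A `run_config` (see [read_run_config()]) or path to one.
#' @return Invisibly, a list of the written file paths.
#' @export
run_solve <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- read_mag_csv(cfg$input)
  if (!is.null(cfg$calibration)) {
    model <- read_calibration(cfg$calibration)
    samples <- apply_calibration(model, samples)
  }
  fld <- run_config_field(cfg, samples)
  sol <- solve_posture(samples, fld$field, window_s = cfg$window_s,
                       alpha_fill = cfg$alpha_fill, rule = cfg$rule)
  paths <- list(posture = file.path(cfg$out_dir, "posture.csv"))
  write_posture_csv(sol, paths$posture)
  if (!is.null(fld$single) && isTRUE(cfg$compare_single_coordinate)) {
    sol1 <- solve_posture(samples, fld$single, window_s = cfg$window_s,
                          alpha_fill = cfg$alpha_fill, rule = cfg$rule)
    paths$posture_single <- file.path(cfg$out_dir, "posture_single.csv")
    write_posture_csv(sol1, paths$posture_single)
    diff <- tibble::tibble(
      quantity = c("roll", "yaw"),
      mean_abs_diff = c(
        mean(abs(angle_diff(sol$roll, sol1$roll)), na.rm = TRUE),
        mean(abs(angle_diff(sol$yaw, sol1$yaw)), na.rm = TRUE)),
      sd_abs_diff = c(
        stats::sd(abs(angle_diff(sol$roll, sol1$roll)), na.rm = TRUE),
        stats::sd(abs(angle_diff(sol$yaw, sol1$yaw)), na.rm = TRUE))
    )
    paths$field_comparison <- file.path(cfg$out_dir, "field_comparison.csv")
    readr::write_csv(diff, paths$field_comparison)
  }
  if (!is.null(cfg$reference_roll)) {
    ref <- read_roll_csv(cfg$reference_roll)
    est <- resample_roll(tibble::tibble(t = sol$t, roll = sol$roll),
                         cfg$resample_rate)
    refr <- resample_roll(ref, cfg$resample_rate)
    n <- min(nrow(est), nrow(refr))
    errs <- binned_roll_error(est[seq_len(n), ], refr[seq_len(n), ],
                              bin_s = cfg$bin_s)
    paths$validation <- file.path(cfg$out_dir, "validation.csv")
    readr::write_csv(errs, paths$validation)
  }
  manifest <- list(
    package = "magposture",
    version = as.character(utils::packageVersion("magposture")),
    config = unclass(cfg),
    n_samples = nrow(samples),
    pct_valid = 100 * mean(sol$valid)
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
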