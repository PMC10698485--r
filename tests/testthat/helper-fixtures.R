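# Shared fixtures, all generated in code.

# Geomagnetic field at the Marion Island study site (46 S, 37 E, 2019.95),
# frozen from the package's validated model evaluation so solver tests do
# not depend on the geomag module. D = -43.97 deg, I = -60.33 deg.
marion_field <- function() {
  reference_field(11354.591105, -10954.196441, -27689.451457)
}

# Quasi-uniform orientations on the sphere (Fibonacci lattice), for
# calibration clouds.
sphere_points <- function(n, radius = 1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    center[1] + radius * sin(phi) * cos(theta),
    center[2] + radius * sin(phi) * sin(theta),
    center[3] + radius * cos(phi)
  )
}

# A synthetic distortion model: hard-iron offset plus a 2:1 axis-scaled
# soft-iron matrix, as a mag_calibration whose *inverse* the simulator
# injects.
synthetic_distortion <- function(reference_intensity) {
  soft <- diag(c(0.5, 1, 1))
  soft <- soft / det(soft)^(1 / 3)
  structure(
    list(offset = c(100, -50, 20), soft_iron = soft, intensity_scale = 1,
         n = NA_integer_, rms_residual = NA_real_, sv_ratio = NA_real_,
         reference_intensity = reference_intensity),
    class = "mag_calibration"
  )
}

write_temp_csv <- function(df, dir = tempdir()) {
  path <- tempfile(fileext = ".csv", tmpdir = dir)
  readr::write_csv(df, path)
  path
}
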