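# magposture

Yaw and roll estimation for dynamic-soaring seabirds from tri-axial
magnetometer data.

Albatrosses and other procellariiform seabirds travel by dynamic soaring:
~10 s cycles of windward climbs and leeward descents with sustained, large
banking. The centripetal acceleration of this flight mode contaminates the
heave axis of tri-axial accelerometers, so the usual accelerometer-based
posture estimates break down exactly when the flight is most interesting.
Magnetometers are immune to acceleration. `magposture` implements a
magnetometer-only posture estimator for this regime, aimed at movement
ecologists working with Daily-Diary-style bio-loggers (40 Hz tri-axial
magnetometer, optional accelerometer and GPS).

## The model

The body-frame field is the rotated reference field,
`H_b = R_x(phi) R_y(theta) R_z(phi_yaw) H_i`, a passive intrinsic
yaw-pitch-roll rotation of the local geomagnetic NED vector
`H_i = (H_N, H_E, H_D)`. One equation cannot determine three angles, but
dynamic-soaring birds hold pitch near zero, and with `theta = 0` the system
inverts in closed form:

- normalize the surge reading: `h_x = H_x / ||H_NE||_2`;
- yaw: `phi_yaw = +/- acos(h_x) + beta`, where `beta` is the magnetic
  declination — the arccosine leaves a two-branch ambiguity;
- auxiliary angle from the down axis:
  `alpha = atan2(||H_NE||_2 sin(phi_yaw - beta), H_D)`;
- roll: `phi = atan2(H_y, H_z) + alpha`.

The branch is chosen per ~10 s window: soaring roll must cross zero within
a cycle, so the branch whose windowed `|min(roll) + max(roll)|` is smaller
is the physical one. Headings at magnetic north/south (or noisy samples)
give `|h_x| > 1` and no yaw solution; roll is then interpolated by
substituting the previous valid `alpha`, which varies slowly.

Around this core the package provides: a bundled degree-12 geomagnetic
reference model (plus static-vector and GPS-track field sources),
hard-/soft-iron ellipsoid calibration anchored to the reference intensity,
a synthetic-data simulator (soaring trajectories, compass swings,
pitch-sensitivity error grids), and validation tools (accelerometer control
roll, wrap-safe binned errors, soaring-cycle counting). Everything is
tibble-in/tibble-out and pipe-friendly, with `autoplot()`, `tidy()` and
`glance()` methods.

## Worked example

Simulate a 10-minute soaring flight over Marion Island (1% field-intensity
sensor noise, stochastic pitch of SD 0.5 deg violating the zero-pitch
assumption slightly), then recover posture:

```r
library(magposture)

field <- wmm_field(-46, 37, 2019.95)
field
#> <reference_field>
#>   H_N 11354.6  H_E -10954.2  H_D -27689.5 nT
#>   declination -43.97 deg, horizontal 15777.2 nT, total 31868.9 nT

traj <- soaring_trajectory(duration_s = 600, cycle_period = 10,
                           roll_amplitude = 60, base_heading = 90,
                           heading_swing = 40)
sim <- simulate_stream(traj, sim_config(field,
                                        noise_sd = 0.01 * field$total_intensity,
                                        pitch_sd = 0.5, seed = 1))
sol <- solve_posture(sim, field, window_s = 10)
glance(sol)
#> # A tibble: 1 × 6
#>       n n_valid pct_valid pct_interpolated window_s rule
#>   <int>   <int>     <dbl>            <dbl>    <dbl> <chr>
#> 1 24001   24001       100                0       10 minmax

median(abs(angle_diff(sol$roll, sim$roll_true)))
#> [1] 0.4810248   # degrees

glance(count_cycles(tibble::tibble(t = sol$t, roll = sol$roll)))
#> # A tibble: 1 × 4
#>   count per   n_peaks mean_abs_peak
#>   <int> <chr>   <int>         <dbl>
#> 1   120 peak      120          60.0
```

All 24,001 samples yield valid yaw branches (the heading sweep stays away
from magnetic north/south), recovered roll is within half a degree of truth
at the median despite the noise and pitch jitter, and cycle counting finds
the constructed 120 banking peaks (60 cycles, one positive and one negative
peak each). `autoplot(sol)` shows both roll branches, the chosen branch and
any interpolated stretches.

A shell workflow with the same functionality (calibrate / simulate / solve /
validate subcommands, YAML config, JSON calibration models, CSV data) is in
`inst/cli/magposture.R`.

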