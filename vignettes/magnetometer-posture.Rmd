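---
title: "Magnetometer-only posture estimation for dynamic-soaring birds: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-only posture estimation for dynamic-soaring birds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magposture)
```

## The estimation problem

Large soaring seabirds bank hard and continuously. The centripetal
acceleration of dynamic soaring adds to gravity on the heave axis of a
tri-axial accelerometer, so the standard accelerometer decomposition of
static acceleration into pitch and roll fails in exactly the flight mode of
interest. A tri-axial magnetometer measures a field that is indifferent to
acceleration, and comparing the measured body-frame field with the known
local geomagnetic field constrains the bird's rotation.

The model is `H_b = D_ib H_i`, where `H_i = (H_N, H_E, H_D)` is the local
field in north-east-down coordinates and `D_ib = R_x(roll) R_y(pitch)
R_z(yaw)` is the direction cosine matrix of a passive intrinsic
yaw-pitch-roll rotation (`rot_x()`, `rot_y()`, `rot_z()`, `dcm_ib()`,
`forward_model()`). Two assumptions make the frames usable: the tag's axes
coincide with the bird's body axes (tags are taped in line on the back),
and NED is treated as inertial, which is adequate metres above the sea
surface.

A single vector equation cannot determine three angles. The package's
working assumption — reasonable for albatross cruising flight, and tested
quantitatively below — is that pitch is zero. Setting `pitch = 0` gives a
closed-form inversion chain (`normalize_hx()`, `yaw_solutions()`,
`alpha_angle()`, `roll_angle()`, orchestrated by `solve_posture()`):

1. `h_x = H_x / ||H_NE||` depends on yaw alone; `yaw = ±acos(h_x) + beta`
   with `beta` the declination. The arccosine loses a sign, leaving two
   branches.
2. With yaw fixed, the field component in the sway-heave plane makes an
   angle `alpha = atan2(||H_NE|| sin(yaw - beta), H_D)` with the down axis
   (positive toward the lower hemisphere, per the NED convention).
3. `roll = atan2(H_y, H_z) + alpha`, a four-quadrant, sign-preserving
   arctangent.

## Branch disambiguation

Each valid sample carries two (yaw, roll) candidates. Dynamic-soaring roll
must cross zero within each cycle as the bird reverses its bank, so over a
window of roughly one cycle the physical branch oscillates about zero while
the spurious one is displaced. Per non-overlapping window (default
`window_s = 10` s, about one cycle), `disambiguate_branches()` picks the
branch with the smaller `|min(roll) + max(roll)|` over the window's valid
samples. A raw signed minimum would systematically favour large negative
rolls; the absolute value of the min+max sum is the quantity that is small
exactly when the oscillation straddles zero. Exact ties — the branches
coincide when `|h_x| = 1` — resolve to the plus branch. An alternative
`rule = "mean"` (smallest `|mean(roll)|`) suits shorter 2–5 s windows
(half a cycle); both are exposed, min+max over 10 s is the default.
Windows with no valid samples inherit the previous window's choice, and
leading undecided windows take the first decided one.

This rule presumes soaring-like roll dynamics. For fixtures without them —
a compass swing sweeps roll through a full circle at constant heading — the
branch must come from the heading label instead, which is how the package's
own swing and error-grid evaluations select it.

## Invalid headings and interpolation

When the heading approaches magnetic north or south, most of the field
projects onto the surge axis, and noise or slight pitch pushes `|h_x|`
past 1: the arccosine has no solution. Out-of-range `h_x` is deliberately
*never* clamped into [−1, 1]: clamping would silently fabricate headings
equal to the declination. Invalid samples are flagged, and their roll is
recovered by substituting a recent valid `alpha` into the roll equation,
on the observation that `alpha` varies slowly in time. The default fill is
the previous valid `alpha` (causal, streaming-friendly); `alpha_fill =
"nearest"` takes the closer valid neighbour in time. Branch bookkeeping
during an invalid run is not self-evident; the package runs disambiguation
first over the valid samples and then draws the fill `alpha` from the
chosen branch, a deterministic two-pass rule that also behaves sensibly
when an invalid run spans a window boundary.

Genuinely degenerate geometry raises errors rather than numbers: a zero
horizontal field (magnetic pole), flight along the field line on the
magnetic equator (`H_D = 0` with `yaw = beta`), and `H_y = H_z = 0` (the
yaw coincides with the field direction, roll undefined).

## The reference field

`reference_field()` wraps a user-supplied NED vector, which always
bypasses any model. `wmm_field()` evaluates a bundled degree-12
spherical-harmonic geomagnetic model (Gauss coefficients in the standard
.COF text format, epoch 2020.0; any other coefficient file can be supplied
by path). The evaluator converts WGS84 geodetic coordinates to spherical
geocentric, runs Schmidt semi-normalized Legendre recursions with linear
secular variation, and rotates the vector back to the geodetic frame; it
reproduces the model's published test vectors to under half a nanotesla.
Altitude is fixed at sea level — albatross flight is within metres of it.
Dates are accepted in `[epoch − 0.5, epoch + 5.5]`: the 2019/20 field
season (decimal year 2019.95) sits at the boundary between model epochs,
and back-extrapolating 0.05 yr through the secular-variation terms moves
the field by only a couple of nT, orders of magnitude below the sensor
noise this method tolerates.

For birds that range far from the colony, `field_along_track()` associates
each sample with the field at the most recent GPS fix (a right-continuous
step lookup), or with a single anchor coordinate. Step lookup rather than
positional interpolation is a deliberate simplification: over the few
hundred kilometres of a foraging trip the field changes declination by a
degree or two, which the solve-and-compare workflow in `run_solve()`
(`compare_single_coordinate: true`) quantifies per run.

## Calibration

The yaw inversion divides body-frame measurements by reference-frame
norms, so raw sensor units must be mapped to commensurate nT.
`fit_calibration()` fits the general quadric `x'Ax + 2b'x = 1` to a cloud of
raw triples by linear least squares: the ellipsoid centre is the hard-iron
offset; the symmetric square root of the centred form, normalized to unit
determinant, is the shape-only soft-iron correction; and the intensity
scale makes the median corrected norm equal the reference intensity at the
calibration site. The fit is deterministic — no iterative optimizer — and
refuses near-coplanar clouds (singular-value ratio floor), which cannot
constrain an ellipsoid. Calibration quality gates everything downstream:
with a synthetic 2:1 soft-iron distortion and a 100-count offset, fitting
on a simulated calibration swing recovers the injected parameters to
better than 1% and keeps the downstream median roll error under a degree.
`fit_calibration_segments()` exposes segment-wise refitting for multi-day
deployments where the ambient intensity drifts; it is off by default.

## What the simulator emulates, and what it does not

`simulate_stream()` generates exact forward-model readings for a
parameterized trajectory and corrupts them with isotropic per-axis
Gaussian noise (the simplest defensible sensor model; magnitude
configurable, with ~30 nT typical of this logger class and 1% of intensity
a conservative stress level), an optional pitch profile (constant or
Gaussian), and an optional injected iron distortion. The built-in
`soaring_trajectory()` is an idealized cycle: sinusoidal roll (guaranteed
to cross zero twice per cycle) with the heading swinging about a base
heading a quarter-cycle out of phase. `compass_swing()` reproduces the
validation fixture: 36 magnetic headings in 10° steps from magnetic north,
each with a full 360° roll sweep. One honest subtlety: with strictly
noiseless zero-pitch data `|h_x|` never exceeds 1, so the invalid windows
that a physical swing shows at north/south only arise once sensor noise is
included; the package's swing checks therefore use a small (30 nT) noise
for the validity pattern and the noiseless sweep for exactness.

None of this is flight dynamics: there is no aerodynamic or wind model, no
coupling of roll amplitude to wind speed, no tag-to-body misalignment, no
temperature drift, and no non-Gaussian sensor artifacts. Passing the
synthetic suite demonstrates that the inversion, branch logic,
interpolation, calibration and cycle counting are correct under the stated
noise model — not that field data from a particular logger will achieve
the same errors, which also absorb video-reference error, clock mismatch
and attachment geometry.

## The cost of the zero-pitch assumption

`pitch_error_grid()` quantifies the assumption directly: generate exact
readings with the *full* forward model at a true pitch, invert with the
zero-pitch solver, and score the wrapped absolute roll error on the branch
nearer the true yaw, per cell of a 1° magnetic-heading × roll grid (one
hemisphere; the surface mirrors across the magnetic meridian, which the
test suite verifies). Invalid cells are skipped and the invalid heading
window widens monotonically with |pitch|.

Under the Marion Island field (inclination about −60°), the worst valid
cell reaches about 22.7° of roll error at 10° true pitch and about 8.0° at
pitches up to 1° — `scripts/acceptance.R` recomputes both numbers from
scratch. The maxima sit at magnetic-*south* headings: there `h_x = −cos(
pitch) + sin(pitch)·|H_D|/||H_NE||` stays inside [−1, 1], so the solver
returns a formally valid but strongly biased yaw, and the error is a
smooth function of the field inclination rather than a fragile boundary
artifact. Figure-style summaries of the same surface (its colour scale
dominated by the bulk of cells) read lower — roughly "up to 20" and
"below 5" — but the strict grid maximum is the honest number and is what
the package reports. Near east/west headings the error is smallest at any
pitch, which is why dynamic soaring, whose heading sweeps through east or
west at least once per cycle, is a favourable regime: the per-cycle valid
samples anchor both the branch choice and the interpolation `alpha`.

## Validation utilities

`accel_roll()` computes the control roll `atan2(A_y, A_z)` for slowly
rotated loggers (it is *not* valid in soaring flight — that is the point
of the package). `resample_roll()` down-samples by nearest-sample
selection, never interpolating angle values across the wrap;
`binned_roll_error()` reports the mean and SD of the wrap-safe absolute
difference per time bin (default 300 s, one video file), symmetric in its
arguments; `align_series()` replaces visual clock synchronization with a
±2 s grid search minimizing the mean absolute wrapped difference (a 100 ms
clock error can masquerade as ~10° of roll error at soaring roll rates).
`count_cycles()` smooths with a centred moving average (default 0.5 s,
window shrinking at the edges), locates zero crossings, takes the extreme
sample of each inter-crossing segment, and discards peaks below a 5° noise
floor — below typical video-reference error, and small enough to keep
genuine shallow banking. A "cycle" is counted per peak by default (per-
flight counts of hundreds over 1–2 h, one peak per ~5 s half-cycle);
`per = "pair"` counts positive/negative pairs instead.

## Numerical conventions and problem sizes

All public interfaces use degrees, with angles normalized to (−180°, 180°];
internal computation is in radians. Validity is `|h_x| ≤ 1` inclusive —
the boundary value is an exact, legitimate solution. Determinism is
treated as part of the contract: `solve_posture()` is a pure function of
its inputs, simulators are bit-reproducible under a fixed seed without
consuming the global RNG stream, and `run_solve()` writes a manifest from
which a run reproduces bit-for-bit. The shipped test suite exercises the
solver on 5° inversion grids, the full 1° pitch-error grids, a 30-minute
simulated flight at 40 Hz (72,001 samples), and 360-sample-per-heading
compass swings; these sizes make the whole suite run in seconds while
leaving no grid coarser than the analyses they mirror.

## Known limitations

Pitch is assumed zero, not estimated; species or flight phases with
sustained pitch need a different sensor fusion (gyroscopes). Yaw accuracy
is unvalidated by an independent heading reference here, as in the field
generally. The branch rule presumes zero-crossing roll dynamics and can
stay undecided (or choose arbitrarily) when a bird holds a steady bank for
many windows near magnetic north/south. The geomagnetic model is a main-
field model: magnetic storms and crustal anomalies are outside it. And the
calibration model is linear — temperature effects and per-axis
nonlinearity are not corrected.
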