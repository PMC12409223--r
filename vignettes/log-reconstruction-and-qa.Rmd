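---
title: "Log-file dose reconstruction and QA for UHDR proton PBS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-file dose reconstruction and QA for UHDR proton PBS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashqa)
```

## Scope and problem

In ultra-high dose rate (FLASH) proton therapy the dose rate delivered to
each point of the field is a quantity of clinical interest, but pencil-beam
scanning (PBS) delivers dose as a sequence of Gaussian spots with dead
times in between, so "the" dose rate of a voxel is a derived, time-resolved
quantity. `flashqa` reconstructs delivered 2D dose and dose-rate maps from
time-resolved machine delivery logs, mirrors the simplified calculation a
treatment planning system (TPS) performs, and implements the
patient-specific (PSQA) and daily (DQA) quality-assurance decision chain
that compares the two. Everything runs on synthetic deliveries from the
built-in simulator, so the full pipeline is testable without machine
access.

## The delivery log and its invariants

A log is a 1 kHz record starting at field load: two *cumulative*
dose-monitor channels (MU), two raw Hall-sensor channels (one per scanning
magnet), and time stamps quantized to 0.1 ms. Cumulative (rather than
incremental) monitor storage is this package's convention: monotone
channels make validation, MU attribution and pause detection robust, and
increments are recovered exactly by differencing. Validation enforces:
non-negative 0.1 ms-quantized times; strictly increasing sample times with
spacing equal to the nominal period within 0.05 ms; and non-decreasing,
non-negative monitor channels. The two monitors are independent; the
package analyses `mon1` and warns when the final channels disagree by more
than 1% relative (an invented but conservative consistency bound).

## Spot segmentation

Beam-on samples are those whose monitor increment exceeds a threshold,
which defaults to half the median positive increment — this separates
quantization/noise-level increments from beam-on without configuration,
because during beam-on the increment is near `intensity × sample period`
while during dead times it is near zero. Maximal runs of beam-on samples
become spots, with three refinements:

* **MU attribution.** A spot's MU is the difference of the cumulative
  channel between the quiet plateaus surrounding its run, with each run
  extended over adjacent contiguous positive (sub-threshold) increments.
  Partial increments arise when a spot starts or ends between sample
  ticks; attributing them by contiguity makes noise-free MU recovery exact
  (the parameter-recovery suite checks 1e-6 relative over 100 random
  plans).
* **Position estimation.** The mean position is the increment-weighted
  mean of the Hall-derived positions over the run's interior samples. The
  first and last sample of a run are excluded (when the run has more than
  two samples) because they can straddle the magnets' ramping interval;
  weighting by increments keeps intensity ramps at spot edges from biasing
  the estimate.
* **Interruption merging.** A beam-off gap longer than the maximum
  expected dead time (11 ms row change + 2 samples margin) between runs
  whose positions agree within 1 mm is an interruption inside one spot:
  the runs merge into a single record flagged `contains_pause`. If the
  position moved, the gap was a pause at a spot boundary and the runs stay
  separate spots.

Beam widths are not observable in the log; they come from the
commissioning table at the log's gantry angle (nearest entry within 5°),
optionally modulated by a per-position variation field clamped to ±10%,
matching the observed spread of real beam sizes across a spot map.

## Dose and dose-rate reconstruction

The dose map is the sum of unit-integral bivariate Gaussian densities
weighted by each spot's dose-area `MU × dose_cal` (times the recombination
factor for UHDR), evaluated at voxel centers with **no tail cutoff**. The
grid is voxel-centered, U horizontal / T vertical, origin at isocenter. A
warning fires when the spacing exceeds half the smallest beam width.

Cumulative dose per voxel supports two accrual modes:

* `spot-termination` (default): each spot's dose lands as one step at its
  termination time — the natural reading of a reconstruction built on spot
  end-time stamps;
* `sample-resolved`: dose accrues in proportion to the spot's per-sample
  monitor increments, giving a piecewise-linear curve. Both modes end at
  exactly the static dose map (checked to 1e-12).

The PBS-average (Folkerts) dose rate of a voxel is
`0.9 · D_v / (t95 − t05)` with the crossing times of the 5% and 95% levels
*of that voxel's own total dose* (the metric is per-voxel, not relative to
the map maximum). Two threshold modes are provided:

* `sample-crossing` (default): the crossing time is the first stored
  sample/event time at which the cumulative dose reaches the level. When
  a level falls just before or after a beam-off plateau, neighbouring
  voxels can disagree sharply — this reproduces the characteristic
  edge-voxel artifact of log-derived dose-rate maps, and is deliberately
  the default so reconstructed maps look like what the log data actually
  support.
* `interpolated`: crossings located by linear interpolation on the
  cumulative curve. For constant-rate delivery this yields exactly
  `D_v / T` (closed form, tested); it is the mode used for quantitative
  cross-model comparisons.

Degenerate voxels (a zero-length 5–95% window, e.g. a single-step voxel in
spot-termination mode) are flagged invalid with a reason rather than given
an infinite rate, and voxels below a dose floor (default 1% of the map
maximum) are excluded: rates in far Gaussian tails are numerically defined
but physically meaningless.

The same machinery converts a 1 kHz point-detector current trace: charge
by the rectangle rule, dose via the Gy/C calibration, and the 5–95%
interpolated rate. A cross-module test checks that a trace equal to a
voxel's per-sample dose reproduces that voxel's map rate to 1e-9.

## The simplified TPS model

The TPS-side calculation deliberately simplifies: spots on a rectangular
grid with a single MU weight; one angle-averaged beam width; constant beam
intensity; constant spot-changing dead times of 4 ms within a row (U step)
and 11 ms between rows (T step); and Gaussian tails truncated at a
beam-spread cutoff (default 4σ, losing `exp(−8)` ≈ 0.03% of a spot's
dose-area). Scan order is a raster with U as the fast axis and
boustrophedon row traversal — the real scan order is machine configuration;
boustrophedon minimizes magnet ramp distance and is stated as this
package's convention. "Dose per spot is constant while the beam is on" is
read as uniform accrual during beam-on, i.e. a piecewise-linear cumulative
curve whose 5%/95% crossings are found by exact interpolation; that is what
makes TPS dose-rate maps smooth across neighbouring voxels, in contrast to
the sample-crossing log maps. The dose-averaged rate is implemented as
`DADR_v = Σ d_iv r_i / Σ d_iv` with `r_i = d_iv /` (spot *i*'s beam-on
duration): it depends only on beam-on durations, so pauses and dead times
leave it unchanged while the PBS-average rate drops — a definitional
contrast the tests exercise.

## QA decision chain

PSQA compares a measured (here: log-reconstructed) field against the TPS
reference; DQA runs the identical pipeline against the PSQA-day
measurement, additionally applying the daily UHDR recombination factor and
propagating an exclusion recommendation when the daily log contains an
interruption (an interlock during a UHDR delivery excludes the patient
from that arm).

1. *Laser/isocenter alignment* is a physical measurement; the pipeline
   records a supplied pass/fail.
2. *Five-spot check*: each spot of a center + (±40, 0), (0, ±40) mm
   pattern (the pattern is configurable; the geometry is this package's
   default) is fit with an axis-aligned 2D Gaussian plus constant
   background by Levenberg–Marquardt with the analytic Jacobian —
   finite-difference Jacobians fail when the moment-based start is already
   near-exact. Tolerances: 2 mm position, ±10% size. The suggested global
   correction is the translation that undoes the mean offset.
3. *Central dose*: measured/planned ratio at the field center; outside 5%
   the map is rescaled by `1/ratio` (after which a re-check passes
   exactly).
4. *Mean deviation and boosting*: the signed mean relative deviation over
   the 90% isodose; beyond 3% in magnitude a boosting factor
   `1/(1 + dev/100)` is applied to model the repeated delivery *before*
   the gamma comparison (the repeat-then-evaluate order is what makes an
   in-tolerance global output error recoverable).
5. *Gamma 3%/3 mm*: global normalization to the reference maximum, mask
   and statistics restricted to the 90% isodose, search radius 3×DTA, test
   map bilinearly interpolated at 1/10 voxel. Pass requires > 90% of
   masked voxels at γ ≤ 1. The implementation prunes voxels whose current
   γ beats the pure-distance term; the test suite checks it against an
   unpruned brute-force oracle to 0.02.
6. *UHDR dose-rate floor*: every sampled local rate must be strictly above
   40 Gy/s ("above" is read as strict).

Statuses: `pass`; `pass-with-correction` when any offset, scaling or
boosting was applied and the corrected field passes; `clinical-review`
whenever the gamma pass fraction is at or below 90% after corrections;
`fail` for hard tolerance violations (five-spot, dose-rate floor,
alignment).

Two open readings are resolved as follows and exposed as configuration:
the mean deviation is computed signed and compared in magnitude; gamma
normalization is to the reference maximum rather than the prescription.

## The delivery simulator

`simulate_delivery()` realizes exactly the simplified timing model:
constant intensity during beam-on, 4/11 ms dead times, boustrophedon
raster, plus a linear Hall ramp across each dead time (the real ramp shape
is unspecified machine behaviour; linear is the simplest testable
contract). The cumulative monitor channel is evaluated analytically at
sample times, so total MU is conserved to machine precision. Noise is
independent Gaussian per sample: on the Hall channels in sensor units, and
on *beam-on* monitor increments (clamped non-negative). Noise is not
applied to beam-off samples: the recording contract defines beam-off as
zero increment, and pause detection relies on it; a real acquisition
system's quantization noise on an idle channel is below one count.

Default study conditions used throughout validation: random rectangular
plans of 5–50 spots at 2.5 mm spacing, 100 MU per spot at 10⁴ MU/s (10 ms
beam-on per spot), beam width 3.5 mm, dose-area calibration
0.02 Gy·mm²/MU, Hall noise equivalent to 0.2 mm at isocenter, monitor
noise 0.1% of a spot's MU. Grids use 1 mm spacing with 4σ margins — sizes
chosen so the whole validation study (20 deliveries reconstructed twice,
plus a 400-spot gamma case on a 77×77 mm grid) completes in seconds.

What the simulator does *not* emulate: beam transport or Monte-Carlo
physics, depth dose (a 250 MeV transmission beam is depth-flat over the
measurement region), intensity fluctuations within a spot, magnet
hysteresis, current-dependent recombination, or detector response
(measured maps are assumed calibrated dose grids). Passing tests therefore
demonstrate the correctness of the reconstruction and QA *computations*
under the stated delivery model, not the fidelity of that model to any
particular machine.

## Numerical choices and degenerate inputs

* Times are 0.1 ms-quantized; crossing-time differences are measured
  between quantized times in sample-crossing mode.
* Position estimates exclude run-edge samples (ramp contamination); MU
  attribution extends runs over contiguous positive increments (exact
  partial-sample accounting).
* Calibration curves never extrapolate: out-of-domain sensor readings are
  data errors.
* A flat image, a peak on the crop border, or a non-converged fit are
  errors in the five-spot analysis; an empty log segments to zero spots
  without error; a zero trace yields dose 0 with an invalid rate.
* Pause-monotonicity of the PBS-average rate (a pause can only lengthen a
  voxel's 5–95% window) is exact for noise-free logs; with sensor noise
  the paused and unpaused analyses see slightly different position
  estimates, so the property is validated noise-free.
* The 2×2-spot timing identity (spot end times 10, 24, 45, 59 ms at
  1 MU/spot and 100 MU/s) anchors the timeline arithmetic in the tests.

## Known limitations

* 2D only: no CT-based recalculation, no DVH/V95/D98 metrics (reports
  state "not computed"), no 3D gamma.
* The delivery report's layout is this package's own; blinding is enforced
  structurally (restricted parts are never serialized) rather than by
  redaction.
* The recombination correction is a single daily scalar, not
  current-dependent.
* Vendor log formats are out of scope; only the package's own text dialect
  is read.
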