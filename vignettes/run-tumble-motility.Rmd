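---
title: "Run-and-tumble motility analysis on prolate-spheroid physics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-and-tumble motility analysis on prolate-spheroid physics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runtumble)
```

## The problem

Swimming bacteria alternate near-straight runs with reorientation events.
Classifying track portions into these phases usually relies on fixed speed
or turn-angle cutoffs, which cannot work across a population whose cell
lengths span more than an order of magnitude: a displacement that is
clearly active swimming for a long filamentous cell is indistinguishable
from Brownian jitter for a coccoid one. This package instead derives, for
every cell, the expectations of Brownian motion from the cell's own
geometry, and labels as active anything that Brownian motion is unlikely to
produce. The same physics powers forward models for how speed and tumble
angle must change as cells elongate, which is the scientific question the
pipeline is built to address.

## Cell-body hydrodynamics

Cells are rigid prolate ellipsoids of revolution: length $l$ = full major
axis, width $w$ = full minor axis, aspect ratio $l/w$. At low Reynolds
number the drag of such a body is known exactly (Perrin's friction
factors). With semi-axes $a = l/2$, $b = w/2$ and eccentricity
$u = \sqrt{1-(b/a)^2}$, writing $A(u) = \operatorname{atanh}(u)/u$:

$$f_{t,\parallel} = \frac{16\pi\eta a\,u^2}{2\,[(1+u^2)A - 1]},\qquad
  f_{t,\perp} = \frac{32\pi\eta a\,u^2}{2\,[(3u^2-1)A + 1]},\qquad
  f_r = \frac{32\pi\eta a^3 u^2 (2-u^2)}{6\,[(1+u^2)A - 1]}.$$

For $u \to 0$ these collapse to the Stokes sphere ($6\pi\eta a$,
$8\pi\eta a^3$); the implementation switches to series expansions of the
bracketed terms below $u = 10^{-3}$ so the sphere limit is reached with full
floating-point precision rather than catastrophic cancellation. The
implementation is validated in the test suite against an independent
numerical quadrature of the general ellipsoid integrals to $10^{-4}$
relative error for aspect ratios 1–40.

Einstein relations give the diffusivities $D = kT/f$; rotation about a
minor axis, the mode that degrades the swimming direction, has
$D_r = kT/f_r$ and the passive orientation-loss time constant

$$\tau = \frac{1}{2 D_r} = \frac{f_r}{2kT}.$$

For a normal-size cell (1.7 × 0.7 µm at 33 °C) $\tau \approx 0.43$ s; for a
10 µm cell it is 33 s — elongation buys straight runs.

**Viscosity.** `water_viscosity()` is a Kestin-type pure-water correlation
anchored at 20 °C (1.002 mPa s); at 33 °C it yields 0.749 mPa s, within a
fraction of a percent of standard property tables over 0–40 °C. The
correlation is smooth and is extrapolated outside that range (hot-water
accuracy is not needed for culture work).

## Brownian probability thresholds

Over a window $t$ the axial displacement of a passive spheroid is
$N(0, 2D_t t)$ and its orientation change $N(0, 2D_r t)$. The speed and
angular-velocity thresholds are the values whose probability of arising
from Brownian motion is below $p = 0.01$. Because the criteria are applied
to magnitudes, the quantile is the half-normal one, $z_{1-p/2}$: this is
the convention under which exactly 1% of Brownian windows exceed each
criterion, which the acceptance suite verifies on $10^5$ simulated windows.
The signed variant $z_{1-p}$ (about 10% lower thresholds) is available as
`tail = "signed"`.

The evaluation window defaults to 0.17 s (five frames at 30 fps), matching
the position-smoothing window; it is long enough to average out body
wobble, and the thresholds scale as $1/\sqrt{t}$ so the analysis is not
sensitive to the exact choice. Within `segment_track()` the criteria are
re-evaluated at the realized whole-frame window so calibration is exact at
any frame rate.

Per-frame speed is computed as the magnitude of the summed frame-wise
displacement projections on the body axis over the window. Projecting frame
by frame (rather than projecting the net displacement on one axis) keeps
the statistic exactly $N(0, 2D_{t,\parallel}t)$ under the simulated
dynamics even though the axis itself rotates.

**Motile/non-motile discrimination.** A track is non-motile if its axial
frame displacements are compatible with mean 0 (two-sided t-test) *and*
variance at most $2D_t\,\Delta t$ (one-sided chi-square), both at
$\alpha = 0.001$; rejection of either declares the cell motile. The union
of two level-0.001 tests gives a theoretical false-positive rate of about
0.2%, and the acceptance suite measures ≤ 0.5% on $10^4$ simulated Brownian
cells.

## Segmentation details

Labels come from sliding windows assigned to their centre frame. Three
robustness rules, each with a resolution argument, are applied:

* label flickers shorter than half the window are merged into their
  surroundings — a windowed criterion cannot resolve events below its own
  support, and such flickers are almost always noise crossings;
* a run's speed is the median of the windows fully interior to it, so
  boundary windows straddling the adjacent tumble (and sub-resolution
  pauses absorbed into the run) do not dilute it;
* tumble angles — the signed angle between the mean directions of the
  flanking runs — are only reported when both flanking runs are complete
  and at least one window long, and the half-window of run frames adjacent
  to the tumble is excluded from the direction average, because those
  frames already contain the tumble's rotation.

The first and last segments of a track are flagged incomplete and excluded
from summaries, as are tumbles without complete flanking runs.

On simulated normal-size populations these rules give ≥ 85% frame-label
agreement with ground truth. Run times recover with a modest negative bias
(threshold crossings clip run boundaries; the tolerance used in the tests
is 25%) and run speeds within 15%, with the residual deficit traceable to
sub-resolution tumbles merged into runs.

## Forward models of elongation

* **Resistive force theory.** The flagellar bundle is one rigid helix
  (axial length 6.0 µm, pitch 2.34 µm, radius 0.25 µm, thickness 0.1 µm,
  rotation 2π×131 rad/s — the observed population averages). With pitch
  angle $\psi$ and drag coefficients $c_t, c_n$ per unit length,
  $A = \ell(c_t\cos^2\psi + c_n\sin^2\psi)$,
  $B = \ell R \sin\psi\cos\psi\,(c_n-c_t)$, and
  $v = B\omega_f/(f_t + A)$. Lighthill's slender-body coefficients (with
  the pitch as reference wavelength) are the default; Gray–Hancock is a
  config option. Both predict the observed *decrease* of speed with length,
  lying above the measured speeds as expected for a single-bundle
  idealization.
* **Power scaling.** Between the extremes of constant power density
  ($P \propto V$: $v = \sqrt{(f_{t,n}/f_t)(V/V_n)\,v_n^2}$, speed grows
  with length) and constant power
  ($v = \sqrt{(f_{t,n}/f_t)\,v_n^2}$, speed falls), any intermediate power
  law is bracketed. The same construction with $f_r$ gives the tumble
  angular velocity, whence maximum tumble angles (angular velocity × the
  tumble-time regression $t = t_n + b\log_{10}(l/l_n)$, $b = 0.37$) and,
  through the uniform-up-to-maximum model, the mean $|\cos|$ statistic
  $\frac{1}{\alpha_m}\int_0^{\alpha_m}\lvert\cos\alpha\rvert\,d\alpha$.
  The absolute value is used because reversals (>90° turns) would otherwise
  pull the average toward 90° and hide the geometric restriction; at
  $\alpha_m = \pi$ the statistic equals $2/\pi \approx 0.64$, the uniform
  reference line.
* The reference tumble angular velocity is mean tumble angle over mean
  tumble time (90° / 0.4 s ≈ 3.93 rad/s), a deliberately conservative
  estimate exposed as a constructor default rather than hard-coded.

## Dispersal statistics

The MSAD of runs, $\langle\Phi^2\rangle = 2 D_r t$, is fitted by least
squares over lags 0.03–0.33 s (the linear regime); $\tau = 1/(2D_r)$ with
confidence bounds from the regression slope. A non-positive slope is
reported as unbounded ($\tau = \infty$) rather than a negative diffusivity.

Bacterial diffusivity is estimated two independent ways:
$D_b = v^2\tau_{\text{run}}/(n(1-\alpha))$ from run/tumble statistics
($n = 2$ dimensions, $\alpha$ = mean cosine of angles between successive
runs), and by fitting Taylor's dispersion equation
$\mathrm{RMSD}(t) = [2v^2\rho\,(t - \rho(1-e^{-t/\rho}))]^{1/2}$ to pooled
root-mean-square net displacements, with $D_b = v^2\rho/n$. Tracks are
truncated to a common 2 s horizon for the RMSD (the estimator needs
equal-length segments; 2 s is the track-length cutoff of the pipeline) and
the fit is evaluated on a log-spaced lag grid to balance the ballistic and
diffusive regimes. Standard errors for the Taylor route come from the fit
covariance by the delta method; a bootstrap over tracks is the recommended
route for the run/tumble estimator.

On an idealized ensemble — brief tumbles, no Brownian noise — the two
estimators agree within a few percent (the acceptance suite allows 30%).
Under realistic conditions they genuinely diverge: zero-speed tumbles of
0.4 s suppress the Taylor RMSD relative to run statistics, and rotational
diffusion shortens the effective correlation time. A sizeable disagreement
between the two routes on real data is therefore informative, not a bug.

Size classes are base-2 logarithmic bins (2 per octave by default): cell
lengths in an elongation series are roughly exponentially distributed, so
logarithmic bins avoid over-representing short cells and refine the range
where the parameters change fastest. Bins with fewer than 100 observations
are flagged excluded.

## The synthetic-data generator

`simulate_trajectory()` is an Euler–Maruyama integrator at
$\Delta t = 1/(\text{frame rate} \times \text{oversampling})$ (default
1/300 s), downsampled to the 30 fps output grid:

* run/tumble durations exponential (defaults 0.6 s and 0.4 s);
* per-run speeds lognormal with median 15.1 µm/s and shape 0.366 — the
  parameters whose arithmetic mean and sd are 16.1 and 6.1 µm/s, the
  normal-size population values;
* tumble angles uniform on $(-\pi,\pi]$ by default, with truncated-uniform
  and forward-biased (wrapped-normal) alternatives, plus an optional
  probability of a π reversal at run start;
* translational noise applied in the body frame with the two distinct
  translational diffusivities and rotated to the lab frame; orientation
  noise with $D_r$; all three from the Perrin factors for the cell's
  geometry. An internal step whose rotational noise exceeds 0.5 rad is
  refused as unstable.

**Tumble micro-dynamics.** Each tumble turns at the constant rate that
completes its drawn target angle exactly within its drawn exponential
duration. This keeps three properties simultaneously true — durations
exponential, realized angles equal to the drawn ones, and a mean rotation
rate equal to the conservative angle/time estimate — which a fixed-rate
rotation capped by the duration cannot (it leaves large angles
unrealized). A fixed-rate variant remains available via
`active_tumble_rate`.

`simulate_brownian_population()` (the killed-cell control) integrates
directly at the output frame rate: pure Brownian increments are exactly
Gaussian at any step size, so oversampling would add cost without accuracy.

What the generator does *not* emulate: cell–cell and cell–wall
hydrodynamics, out-of-plane excursions (the analysis plane is 2-D
throughout, as in a single focal plane), body wobble from imperfect
bundling (smoothing removes it in real data; no wobble term is simulated),
flagellar dynamics, and chemotactic modulation. Passing tests therefore
demonstrate correctness of the analysis chain under the stated stochastic
model, not robustness to every optical artefact of real video.

## Rendering, detection, tracking

The renderer draws each cell as an anti-aliased filled ellipse at
2.75 px/µm on 8-bit frames, with 2 pixels of apparent broadening on each
full axis emulating the constant phase-contrast overestimate; detection
subtracts the same 2-pixel correction (0.73 µm) from measured lengths, the
way a bead calibration would.

Detection: per-pixel temporal-median background subtraction; a spatial
median over a plus-shaped 5-pixel window (area ≈ a 1 µm particle at
2.75 px/µm; a 3×3 square erodes the tips of cells only 4 px wide);
Otsu threshold by default; particles below the area of a 1 µm disc
discarded. Cell length is the arc length of the Zhang–Suen skeleton of the
mask, ordered along its principal axis, smoothed (the raw 8-connected
staircase overestimates oblique lengths by up to 8%), and extended from its
projected endpoints along the principal axis to the region boundary. Widths
near one pixel are unreliable at this magnification, so a fixed 0.7 µm
width is the default (config-overridable to the measured minor axis).
Single-frame lengths carry ±0.2 µm of digitization error; the pipeline uses
per-track medians, which are accurate to well under a pixel for cells
≥ 3 µm.

Tracking links particles whose pixel masks overlap in consecutive frames
(no gap closing); a nearest-centroid gate is the fallback for maskless
tables. Any merge or branch splits all involved tracks at that frame, and
tracks shorter than 2 s are dropped. Orientations from image moments are
axial (mod π); `resolve_orientation()` disambiguates the head by the motion
direction with hysteresis for elongated cells (aspect ratio ≥ 3, the
threshold at which moment orientations become reliable) and uses
centroid-triplet directions below it.

## Numerical choices and limitations

* Seeds: all stochastic stages consume R's RNG; identical seed and
  configuration give bit-identical trajectories.
* The Taylor fit uses Levenberg–Marquardt with ballistic-limit starting
  values and positivity bounds; non-convergence is an error, not a silent
  NA.
* Degenerate inputs are first-class: zero MSAD slope → unbounded τ;
  mean cos = 1 → undefined diffusivity (error); blank frames → empty
  detections; a constant stack → zero background residual.
* Touching cells merge into one detection (split downstream by the
  tracking rule) — a documented limitation of connected-component
  detection.
* The simulator and analysis share the Perrin physics; the independent
  quadrature oracle in the tests guards that shared core against
  transcription errors.
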