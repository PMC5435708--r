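# runtumble

Physics-grounded analysis of bacterial run-and-tumble motility in video
microscopy data.

Peritrichous bacteria such as *Escherichia coli* explore their surroundings
through sequences of near-straight **runs** and reorienting **tumbles**.
Both phases are shaped by the cell's geometry: drag and rotational Brownian
motion are set by the friction coefficients of the cell body, so a short
cell and a filamentous one have completely different expectations for what
"moving" and "turning" look like. This package implements a segmentation
method built on that observation, together with the forward models that
predict how swimming speed and tumble angle change with cell aspect ratio,
and a ground-truth simulator that makes every stage testable without real
videos. It is written for microbiologists and biophysicists quantifying
swimming behaviour from phase-contrast microscopy tracks.

## The model at the core

Cells are treated as rigid prolate ellipsoids of revolution with full axes
*(l, w)*. Perrin's rigorous friction factors give the translational drag
along the major and minor axes and the rotational drag *f_r* about a minor
axis; the Einstein relations convert them into diffusivities
*D_t = kT / f_t* and *D_r = kT / f_r*.

Over a window *t*, a passive spheroid's displacement along its major axis is
N(0, 2 *D_t* *t*) and its orientation change is N(0, 2 *D_r* *t*). The
segmentation thresholds are the values exceeded by Brownian motion with
probability below 0.01 — no subjective cutoff, and automatically adapted to
each cell's own size:

* **run**: windowed speed above the speed threshold *and* angular velocity
  below the angular threshold;
* **tumble**: everything else.

Around this core the package provides:

* motile/non-motile discrimination (t-test on the mean axial displacement
  plus a one-sided chi-square variance test against 2 *D_t* *t*);
* the orientation-loss time constant tau = 1/(2 *D_r*), and its empirical
  estimate from mean-square angular deviations (MSAD) of runs;
* population diffusivity by two independent estimators:
  *D_b = v² tau_run / (n (1 − alpha))* from run/tumble statistics, and a
  nonlinear fit of Taylor's dispersion equation to RMSD(t);
* forward models for speed and tumble angle versus cell length: resistive
  force theory (*v = B omega_f / (f_t + A)*), constant-power-density and
  constant-power scaling, and the tumble-angle restriction model
  (mean |cos| of angles uniform up to a maximum angle);
* a run-and-tumble simulator with anisotropic Brownian noise, an ellipse
  renderer producing 8-bit TIFF stacks, a particle detector
  (background-median subtraction, Otsu threshold, skeleton-based lengths)
  and an overlap-based tracker.

## A worked example

Segment simulated normal-size cells (length 1.7 um, width 0.7 um) at 33 °C
and recover their motility statistics:

```r
library(runtumble)

med  <- medium(306.15)                 # 33 C, pure-water viscosity
cell <- ellipsoid_geometry(1.7, 0.7)
diffusivities(cell, med)
#> Brownian diffusivities: D_t major 0.6629, minor 0.5587 um^2/s; D_r 1.177 rad^2/s

thr <- brownian_thresholds(cell, med)
thr
#> Brownian thresholds (t = 0.17 s, p = 0.01, magnitude tail):
#>   speed 7.19 um/s, angular velocity 9.58 rad/s

set.seed(42)
cfg  <- sim_config(duration = 20, arena = 1e4)
segs <- lapply(1:20, function(i) {
  sim <- simulate_trajectory(cell, motility_parameters(), cfg, med)
  segment_track(sim$trajectory, thr)
})
(sm <- summarize_motility(segs))
#> motility summary: 343 runs, 352 tumbles (244 tumble angles)
#>   run time 0.56 +/- 0.48 s, run speed 15.5 +/- 5.9 um/s
#>   tumble time 0.51 +/- 0.44 s, mean cos -0.01, mean |cos| 0.64

diffusivity_run_tumble(sm)
#> bacterial diffusivity (run-and-tumble statistics): D_b = 67.1 um^2/s
```

Reading the numbers: the generator was configured with mean run time 0.6 s
and mean run speed 16.1 um/s; the recovered 0.56 s and 15.5 um/s show the
small threshold-crossing bias discussed in the methods vignette. The mean
cosine of the tumble angle near 0 and mean |cos| near 2/pi (0.64) are the
signatures of uniformly distributed tumble angles — the run-and-tumble
regime of short cells. For elongated cells the same pipeline yields
restricted angles and much longer orientation time constants
(`theoretical_time_constant(ellipsoid_geometry(10, 0.7), med)` gives 33 s
versus 0.43 s for the normal size).

The forward-model overlays of speed and tumble restriction versus length
come from `model_grid(lengths)`; image stacks are rendered with
`render_frames()` and analysed with `subtract_background()`,
`detect_stack()` and `link_tracks()`.

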