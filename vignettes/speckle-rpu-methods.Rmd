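---
title: "Methods: speckle simulation and Relative Perfusion Unit quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle simulation and Relative Perfusion Unit quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleRPU)
```

# Scope and model

This package implements relative perfusion quantification for laser
speckle contrast imaging (LSCI) together with a synthetic scene generator
that emulates three porcine bowel experiments: a partially devascularized
bowel loop with a continuous ischemic gradient, the same loop under
progressive arterial/venous occlusion coupled to mean arterial pressure
(MAP), and a pair of side-to-side anastomoses. Raw intraoperative videos
for such experiments are not publicly available, and commercial LSCI
devices do not publish their internal processing; the package therefore
adopts a standard published physical model end to end and treats the
reported perfusion levels as *calibration targets that the full imaging
pipeline must recover through the physics*, not as numbers to pass
through.

## Speckle physics

Fully developed speckle has negative-exponential intensity statistics, so
a static speckle field has spatial contrast $K = \sigma/\mu = 1$. Moving
scatterers decorrelate the field with correlation time $\tau_c$
(inversely related to flow speed); integrating over an exposure $T$
blurs the pattern and lowers the contrast. For a Lorentzian velocity
spectrum (exponential field correlation $g_1(\tau) = e^{-\tau/\tau_c}$),
the single-exposure closed form is

$$K^2(T, \tau_c) = \frac{x}{2}\left[2 - x\,(1 - e^{-2/x})\right],
  \qquad x = \tau_c / T .$$

This Fercher–Briers-type model is a substitution for whatever a given
commercial device computes internally, which is unpublished. The
substitution is safe for every readout in this package because the RPU
normalization (below) is invariant to affine transformations of the raw
flow quantity.

## From perfusion to rendered video

The generator owns a ground-truth perfusion field $p$ (percent, 0–100).
`perfusion_to_correlation_time()` maps $p$ to $\tau_c$ by numerically
inverting $K^2$ so that the flow index $F = 1/K^2$ is *affine* in $p$:
$p = 0$ maps to a capped quasi-static correlation time (`tau_cap`, 1 s)
and $p = 100$ to the correlation time whose contrast is `k_full_flow`
(0.1). With the default 5 ms exposure this spans flow indices from about
1 to 100. The inversion uses a 4000-point log-log interpolation grid of
the monotone $K^2(x)$ curve; the exported scalar path agrees with direct
root-finding to well under 0.1 %.

`render_video()` has two modes:

* **analytic** (default): each pixel's exposure-integrated intensity is
  drawn from a gamma distribution with mean `mean_intensity` and shape
  $1/K^2$ — the standard "effective degrees of freedom"
  parameterization. Pixels are independent, matching the ~1:1
  pixel-to-speckle ratio of the emulated optics. This runs in seconds
  and is what tests and default experiments use.
* **dynamic**: the physics reference. A complex field evolves per
  substep as a first-order autoregressive process with correlation
  $e^{-\Delta t/\tau_c}$; substep intensities (negative-exponential) are
  averaged over the exposure window, and the field decorrelates through
  the dead time between frames. The discrete integral converges to the
  closed form only when $\tau_c$ spans several substeps: with the
  default 40 substeps per 5 ms exposure, correlation times below
  ~0.25 ms are underresolved and the renderer warns. Property tests
  compare the two modes in the resolved regime (ground truth up to
  ~45 %, 128 substeps), where they agree within a few percent.

Detector counts are quantized to the configured bit depth (16-bit
default, mean 3000 counts — far enough below the ceiling that the
exponential tail is not clipped). Optional Gaussian read noise is off by
default; nothing is known about the emulated sensor's noise. Mean frame
intensity is independent of perfusion: flow changes contrast, not
brightness.

## Contrast estimation and the flow index

`spatial_contrast()` computes $K$ per pixel over a 7×7 window — common
LSCI practice, statistically adequate at a 1:1 speckle:pixel ratio —
using the *population* standard deviation (fixed so brute-force oracles
match exactly) and reflect padding (so border regions are not silently
shifted). `temporal_contrast()` is provided as the along-time
alternative; whether the emulated device computes spatial, temporal or
spatiotemporal contrast is not public, and the default pipeline's choice
(spatial per frame, then temporal smoothing) is an assumption, stated as
such.

The raw flow value is $F = 1/\max(K, k_{floor})^2$ with
$k_{floor} = 0.05$, which keeps $F$ finite on pathological windows.
`smooth_temporal()` then applies a 5-frame sliding average (full windows
only), mirroring a device-style temporal smoothing window without
claiming its exact scheme.

## RPU quantification

All sampled regions — ROIs and the Hot/Cold references — are discrete
disks of exactly 317 pixels (radius ≈ 10 px), the nearest-to-center
pixels with ties broken by angle then row-major order. The protocol
fixes the area, not the shape; a disk is the natural choice because it
is rotation-fair along curved arcs. A 21-pixel alternate area, also in
circulation for this style of quantification, remains available through
the `area_px` argument; 317 is the operative default for all regions.

$$\mathrm{ROI_{RPU}} = 100 \cdot
  \frac{\mathrm{ROI_{raw}} - \mathrm{Cold_{raw}}}
       {\mathrm{Hot_{raw}} - \mathrm{Cold_{raw}}}$$

References are user-supplied coordinates (manual selection is the
protocol; `validate_references()` is advisory only). The implemented
contract is *fixed coordinates, values re-sampled on each representative
frame*; for cross-time-point series (occlusion) the reference raw values
are measured once at baseline and held fixed, so the series tracks
global perfusion loss. RPU is never clipped anywhere in computation;
display clamping happens only in `render_heatmap()`.

"Averaging 5 representative frames while taking the cardiac cycle into
account" is operationalized as spreading the 5 frames uniformly over a
configurable cardiac-period window (default 60 frames = 0.5 s at
120 fps) so that systolic and diastolic phases average out; no concrete
algorithm is public, and the selector is pluggable.

# The synthetic scenes

## Ischemic gradient

A rectangular bowel band (10 cm × 4 cm at 20 px/cm) with three parallel
arcs (mesenteric, centerline, antimesenteric). The axial profile is
piecewise linear — the minimal model consistent with a "steady" decline
followed by a "sharp" one: constant at the ischemic level (1.9 %) within
2 cm of the stapled edge, a steep rise to the slope break at 5 cm, a
gentle rise reaching the plateau (98.8 %) at 8 cm. The gentle slope is
*solved* so that the watershed-segment mean sampled at the analysis
default (0.5 cm ROI spacing over 4–6 cm) equals 78.3 % exactly in ground
truth; the resulting slopes (≈ 5 %/cm distal, ≈ 27 %/cm proximal) give
the two-piece structure the breakpoint detector is asked to find, and
incidentally reproduce a watershed within-segment SD (~12–13) close to
the reported one.

Across the bowel, the mesenteric arc is offset upward and the
antimesenteric downward. The offset split is asymmetric
(`arc_offset_split` = 1.2/16.6) so that the centerline sits at the
plateau level while the arcs sit at 100 and 83.4 — the only assignment
consistent with all three reported perfused-segment values. The offset
is constant in a band around each arc (a 317-px disk centred on an arc
sees a uniform level), ramps between them, tapers to zero between the
decline onset and the ischemic zone, and vanishes near the staple line.
The band extends 0.75 cm beyond the 10 cm span (the bowel continues
distally) so that regions sampled at 10 cm stay on tissue. Landmarks
place the Hot reference on the mesenteric arc at 9 cm (ground truth
exactly 100) and the Cold reference on avascular background beyond the
stapled edge (zero flow, quasi-static speckle).

## Occlusion schedules

No MAP values are published for the emulated experiments, so the MAP
scale is an explicit simulation convention: baseline 65 mmHg, floors of
20 mmHg (arterial) and 45 mmHg (venous), all configurable. MAP falls
linearly with occlusion fraction; the global perfusion scale factor is
linear in MAP plus Gaussian noise at interior steps, clamped, pinned at
the endpoints (1 at baseline, ≤ 0.05 at complete occlusion — complete
arterial and venous occlusion produce the same low-perfusion state), and
made non-increasing, since progressive clamping never restores flow.
Venous occlusion reaches complete perfusion loss over a smaller MAP drop,
encoding the observed higher pressure-sensitivity of venous outflow
obstruction; the venous scale-per-mmHg slope is therefore steeper by
construction. The noise default (0.10 in scale units) was calibrated by
simulation — endpoint pinning and the monotonicity constraint damp the
effective noise, so the naive variance-ratio formula misleads — such that
the default 10-step schedule's MAP regression has a median R² of ~0.96
across seeds (`scripts/calibrate_occlusion_noise.R`).

## Anastomoses

Two parallel bands (antimesenteric anastomosis above, mesenteric below)
whose perfusion interpolates 10 matched point values spanning 0–4.5 cm.
The default profiles are linear declines chosen so the antimesenteric
profile has mean 54 / SD 18 and the mesenteric mean 38 / SD 15, with the
antimesenteric value strictly higher at every matched index. A 100 %
reference patch (surface-capillary analogue) sits in the margin between
the bands; the Cold reference sits on background. Bands overhang the
measured span on both sides for the same endpoint-region reason as
above.

# Statistics

Segment summaries use one-way ANOVA over the labelled ranges (ischemic
0–2, watershed 4–6, perfused 8–10 cm); the 2–4 and 6–8 cm transition
zones are excluded from summaries but still sampled for onset detection.
Arc and anastomosis comparisons are two-sided *paired* t-tests —
matched-point designs imply pairing, and sidedness is otherwise
unstated. Profile spacing defaults to 0.5 cm: fine enough to localize
the onset to half a centimetre. The onset detector fits every continuous
two-piece linear model with the breakpoint at a sample position (no
continuous optimization — reproducible and oracle-checkable), picks the
SSE minimizer, and demands the proximal slope exceed the distal by 2×,
returning "no onset" otherwise; for the bowel gradient the search is
restricted to the declining span (2–8 cm), because a single-breakpoint
model is only meaningful between the two plateaus. The MAP regression is
ordinary least squares with $R^2 = 1 - SSE/SST$. α = 0.05 is the
reporting threshold throughout; no multiple-testing correction is
applied (none is reported for the emulated analyses), and no
animal-level hierarchical structure is modelled.

# What passing tests do and do not show

The generator emulates the *geometry and calibration levels* of the
experiments: distance-resolved perfusion, arc offsets, pressure-coupled
global scaling, paired anastomosis profiles. It deliberately does not
model vessel trees or mesentery anatomy, 3-D tissue or scope-angle
effects (the emulated scope is fixed, perpendicular, 20 cm), motion
artifacts, respiratory/cardiac tissue motion, detector noise beyond
optional Gaussian read noise, or any real device's raw value scale.
End-to-end recovery therefore demonstrates that the quantification chain
is unbiased and correctly normalized under the stated physics — not that
it would survive motion artifact or anatomical heterogeneity in vivo.

Recovered values carry two small, understood systematic effects: the
windowed $1/\hat K^2$ estimator is slightly biased at finite window
size (sub-point at the defaults, cancelling to first order in the RPU
ratio), and regions centred on profile kinks average across the kink
(e.g. the ischemic mean reads ~2.3 rather than 1.9 because the 2 cm
sample's disk straddles the steep rise). Seed-to-seed spread of segment
means is dominated by sampling noise of the Hot reference (a 317-px
region at low contrast); validation therefore pools segment means over
five seeds, as the emulated study pools animals and frames.

# Problem sizes and runtime choices

Default experiment sizes — chosen as the package's desk-scale working
point — are: gradient scene 141×261 px rendered for 60 frames
(one cardiac window), occlusion 10 steps × 15 frames, anastomosis
162×151 px × 60 frames. A full gradient experiment runs in about a
second in analytic mode; the dynamic mode is reserved for physics
verification on small scenes. All randomness flows through explicit
integer seeds; identical seeds give byte-identical videos, identical
summaries, and identical written stacks.

# Known limitations

* The dynamic renderer underresolves correlation times shorter than a
  couple of substeps (it warns); quantitative dynamic-mode work at high
  perfusion needs more `substeps_per_frame`.
* Flow-map TIFFs store float32 normalized by the stack maximum;
  precision is relative to that maximum, not per element.
* Both a 317-pixel (default) and a 21-pixel region area are supported;
  results are reported for the default unless stated otherwise.
* MAP values are conventions; only the *relative* pressure-perfusion
  structure (linearity, venous steepness) is meaningful.
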