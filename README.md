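# speckleRPU

Quantification of tissue perfusion from laser speckle contrast imaging
(LSCI) as **Relative Perfusion Units (RPU)**, with a synthetic
dynamic-speckle scene generator that emulates three intraoperative porcine
bowel experiments at desk scale. The package is aimed at researchers
developing or validating relative perfusion quantification for
intraoperative imaging: it provides the full measurement chain — speckle
rendering, contrast estimation, flow-index maps, reference-normalized ROI
statistics — plus the statistical readouts used to characterize bowel
perfusion gradients, occlusion responses and anastomotic perfusion.

## The quantity at the core

LSCI images blood flow through the blurring of coherent-light speckle.
Over a spatial window the speckle contrast is `K = sigma / mu`; for an
exposure `T` and a speckle correlation time `tau_c` (inversely related to
flow speed) the single-exposure model with a Lorentzian velocity spectrum
gives

    K^2(T, tau_c) = (x / 2) * (2 - x * (1 - exp(-2 / x))),   x = tau_c / T

The raw flow index used here is `1 / K^2`. Because absolute raw values
depend on device and tissue factors, perfusion is reported on a
scene-relative scale anchored by manually selected references — a
maximally perfused region ("Hot") and a minimally perfused region
("Cold"):

    ROI_RPU = 100 * (ROI_raw - Cold_raw) / (Hot_raw - Cold_raw)

RPU is 0 at the Cold reference, 100 at the Hot reference, and is never
clipped (ROIs brighter than Hot legitimately exceed 100). All regions —
ROIs and both references — are 317-pixel disks; each ROI value averages 5
representative frames spread over a cardiac-cycle-length window. RPU is
invariant to affine rescaling of the raw flow quantity, which is what
makes the substitution of a standard published speckle model for any
particular device's proprietary raw scale safe.

## Worked example

The gradient scenario builds a 10 cm partially devascularized bowel loop
(perfused plateau distally, watershed zone, ischemic zone at the stapled
edge), renders speckle video at 120 fps optics, recovers RPU profiles
along the mesenteric, centerline and antimesenteric arcs, and runs the
standard readouts:

```r
library(speckleRPU)
res <- run_gradient_experiment(seed = 1)
res$segments
#> <comparison_result> anova: statistic = 202.3, p = 5.72e-10
#>    segment      mean        sd n
#>   ischemic  2.321417  1.422458 5
#>  watershed 78.614064 13.819080 5
#>   perfused 99.426734  0.931036 5
res$arc_comparison
#> <comparison_result> t (paired): statistic = 24.08, p = 1.76e-09
#>             arc     mean       sd  n
#>      mesenteric 90.82137 14.58744 10
#>  antimesenteric 75.08517 13.16219 10
as.numeric(res$onset)
#> [1] 5
```

The three segments separate cleanly (ANOVA p ~ 6e-10) with means near the
calibrated ground truth (98.8 / 78.3 / 1.9); the mesenteric border reads
higher than the antimesenteric border at every matched distance (paired
p ~ 2e-9); and the two-piece breakpoint detector localizes the sharp
perfusion decline at 5 cm from the stapled edge — 1 cm proximal to the
4 cm devascularization margin. The segment means are *recovered through
the imaging physics* (speckle rendering, contrast estimation, reference
normalization), not read off the ground truth.

Other entry points: `run_occlusion_experiment()` (progressive
arterial/venous occlusion with MAP-coupled perfusion and per-segment
RPU-on-MAP regression), `run_anastomosis_experiment()` (10 matched points
along paired side-to-side anastomoses), and `run_pipeline()` which chains
scene → render → contrast → RPU → analysis for a named scenario and
writes stacks (multi-frame TIFF + JSON sidecars), profile CSVs, heatmap
PNGs and a provenance-stamped `summary.json`.

## Further reading

The methods vignette (`vignettes/speckle-rpu-methods.Rmd`) describes the
speckle model and its inversion, every tunable parameter with its default
and rationale, what the synthetic scenes do and do not emulate, and the
package's numerical choices and limitations.
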