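# OCTbiometry

Full-eye optical coherence tomography (OCT) biometry under osmotic stress,
as a tested, fully synthetic-data-driven R pipeline.

Topical saline drops of varying tonicity shift the hydration state of the
eye: hypertonic challenges thin the cornea, shallow the anterior chamber,
opacify the lens and bow the iris outward; hypotonic challenges do the
opposite. OCT can watch all of this at once — but it images depth in
*optical-path length* (geometric distance × refractive index), so every
structure behind a refracting surface appears displaced. `OCTbiometry` is
for researchers quantifying such dynamics on full-eye OCT cross-sections:
it provides

* a **ground-truthed phantom**: a schematic eye (mouse baseline or a
  physical calibration model eye) rendered into OCT B-scans by per-A-scan
  Snell's-law ray tracing, with seeded speckle and osmotic-challenge time
  series driven by piecewise exponential relaxations;
* **segmentation** of the six ocular boundaries (cornea ×2, lens ×2,
  retinal inner limiting membrane, iris pigment epithelium) with sub-pixel
  gradient refinement and optional seed points;
* **optical distortion correction** by layer-wise ray tracing with the
  standard index stack *n* = 1.40 (cornea), 1.33 (aqueous), 1.57 (lens),
  1.33 (vitreous): each point moves along the refracted probing ray by
  (optical-path increment)/*n*;
* the six **biometric parameters** — CCT, ACD, LT, CRD (axial distances on
  the anteroposterior axis), LSI (mean lens backscatter from the anterior
  capsule toward the nucleus) and IC (signed iris curvature: the maximum
  perpendicular distance of the iris pigment epithelium from the
  root–contact chord, + = anterior bowing);
* **dynamics**: baseline normalization `100·(p−p₀)/p₀` over 5 repeat
  acquisitions, per-phase peak changes, exponential fits
  `y = y₀ + A(1−e^{−(t−t₀)/τ})`, and steady-state detection (rate < 1 % of
  the initial rate; `t₀ + τ·ln 100` for an exact exponential).

## Worked example

```r
library(OCTbiometry)

b <- renderBScan(mouseEye(), tissueOptics())   # noiseless baseline B-scan
b
#> BScanImage 1687 x 241 (axial x lateral), pitch 3.0/10.0 um, t = 0.0 min [baseline]

measureBiometry(b)[, c("cct", "acd", "lt", "crd", "lsi", "ic")]
#>   cct acd   lt    crd lsi   ic
#> 1 119 404 1860 3079.9  25 26.6
```

The phantom's ground truth is CCT 119, ACD 404, LT 1860, CRD 3080 µm with a
uniform lens backscatter of 25 and an isotonic iris sag of +28.6 µm: the
full segment → dewarp → measure chain recovers the axial parameters to well
under one pixel (peripheral refraction compresses the imaged iris root
inward, which biases |IC| low by a few micrometres — see the vignette).

A full challenge experiment is three calls:

```r
sc <- readScenario("group1")       # 250-1000-250 mOsmol/kg hypertonic study
sc
#> OsmoticScenario 'group1' (mouse eye): 3 phase(s), 5 baseline repeats
#>   1. isotonic    250 mOsmol/kg,   10 min, 0.20 frames/min, tau 2.0 min
#>   2. hypertonic 1000 mOsmol/kg,   13 min, 1.00 frames/min, tau 2.5 min
#>   3. reversal    250 mOsmol/kg,   40 min, 0.20 frames/min, tau 6.0 min

ts  <- renderTimeSeries(sc, seed = 1, noise = FALSE)  # 28 frames + truth
bio <- measureStack(ts$frames)
dyn <- summarizeDynamics(buildResponseSeries(bio, k = 5), sc)
subset(dyn, phase == "hypertonic" & parameter %in% c("cct", "acd", "lsi"))
#>   parameter      phase    peak peakTime amplitude  tau
#>         cct hypertonic -20.557       23   -20.687 2.50
#>         acd hypertonic -11.444       23   -11.496 2.50
#>         lsi hypertonic  28.641       23    28.800 2.50
```

The hypertonic phase drives the calibrated peak responses (corneal thinning
−20.7 %, chamber shallowing −11.5 %, lens scattering +28.8 % as the
asymptotes of 2.5-min exponentials); the measured peaks land within 0.2
percentage points of the encoded dynamics, and the fitted amplitudes and
time constants recover the calibration itself.

Disk-based runs (`runSimulate()`, `runMeasure()`, `runDynamics()`,
`runReplicate()`) write TIFF stacks with CSV sidecars, biometry and summary
CSVs, and JSON logs; `inst/scripts/oct-pipeline.R` wraps them for the shell.

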