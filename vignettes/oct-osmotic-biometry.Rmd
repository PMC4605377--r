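---
title: "Full-eye OCT biometry under osmotic stress: models and methods"
author: "OCTbiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-eye OCT biometry under osmotic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Optical coherence tomography images the whole rodent eye in cross-section,
but it measures depth in *optical-path length*: every structure behind a
refracting interface appears both deeper (by the refractive index of the
medium) and laterally displaced (by refraction of the probing ray). Any
quantitative biometry therefore needs three stages: segmentation of the
tissue interfaces in image coordinates, correction of the optical distortion,
and measurement of the biometric parameters in geometric coordinates. When
the ocular hydration state is perturbed with topical saline of varying
tonicity, the eye responds dynamically — the cornea thins or swells, the
anterior chamber shallows, the lens scatters more light, the iris bows — and
a fourth stage quantifies those response curves.

`OCTbiometry` implements this pipeline end to end, together with a
ground-truthed synthetic phantom so that every stage is testable without any
instrument or animal. The six parameters follow the standard definitions:

* **CCT** — central corneal thickness, anterior corneal surface to
  endothelium;
* **ACD** — anterior chamber depth, endothelium to anterior lens surface;
* **LT** — crystalline lens thickness;
* **CRD** — cornea–retina distance, endothelium to the retinal inner
  limiting membrane (ILM);
* **LSI** — lens scattering intensity, the mean linear backscatter from the
  anterior capsule toward the anterior nucleus along the A-scan;
* **IC** — iris curvature, the signed maximum perpendicular distance of the
  iris pigment epithelium from the chord joining the iris root and the most
  peripheral iris–lens contact point (+ = anterior/convex bowing).

## The phantom

The schematic eye (`EyeGeometry`) models the five axial interfaces as
circular arcs (apex position + signed radius of curvature) and each iris
wing as a quadratic arc between the iris–lens contact point at the pupil
margin and the iris root, displaced perpendicular to the chord so that the
maximum perpendicular distance equals a signed sag amplitude. Two baseline
geometries are packaged:

* the **mouse eye**: CCT 119, ACD 404, LT 1860, CRD 3080 µm, isotonic iris
  sag +28.6 µm. Curvature radii are *not* measured quantities; they are
  plausible documented defaults for the adult mouse (cornea 1450/1400 µm,
  lens 1000/−1050 µm, ILM −1600 µm) and are free configuration.
* the **model eye**: a physical calibration eye with manufacturer dimensions
  CCT 0.55, ACD 3.03, LT 3.9 mm; the 6 mm vitreous depth is a package
  default (the manufacturer specifies only the anterior segment) so that the
  retinal surface exists for the full chain, and the radii are human-scale
  defaults.

`renderBScan()` is the forward model. Each image column is an A-scan: a
vertical ray traced anterior→posterior, refracted at every fitted arc by
Snell's law (indices air 1, cornea 1.40, aqueous 1.33, lens 1.57, vitreous
1.33), while the optical path `sum(n_i * geometric segment)` accumulates.
Layer backscatter is deposited in the launch column between the optical-path
depths of the interface crossings with exact partial-volume weighting at the
boundaries, which makes sub-pixel boundary localization meaningful. This
reproduces exactly the distortion a spectral-domain instrument exhibits; on
the AP axis the interface depths equal the cumulative `n·t` sums to within
quantization. The iris band (40 µm thick, high backscatter) is drawn where
the refracted ray meets it, and everything below it is shadowed. Rays that
would land peripheral to the iris root image the limbus (cornea + shadow)
instead.

Two modelling consequences are worth knowing. First, the mouse lens focuses
the parallel probing beam close to the retina, so the *corrected* retinal
points from many A-scans converge laterally toward the axis; the package
therefore measures the ILM position from the robust centre of that cluster
rather than an extrapolated arc. Second, refraction compresses the imaged
periphery: rays never quite reach the geometric iris root, which biases the
measured |IC| low by roughly 5 %. Both effects are physical, not artefacts
of the implementation.

The noise model is multiplicative gamma speckle of unit mean with shape
`speckleLooks` (default 4, i.e. a four-look average with contrast 0.5 —
typical of lightly compounded OCT frames) plus an additive Gaussian floor
(SD 1 intensity unit). Noise is seeded and strictly separable: a fixed seed
reproduces the stack bitwise, and the noiseless image is independent of the
seed. Sensitivity roll-off with depth is not modelled (it is a property of
the spectrometer, not of the tissue).

## Osmotic scenarios

An `OsmoticScenario` holds the phase schedule (agent osmolality, duration,
imaging frequency) and, per phase, the asymptotic fractional change and
relaxation time constant of each parameter. Within a phase every parameter
relaxes exponentially toward its asymptote,
`p(t) = p∞ + (p(t0) − p∞)·exp(−(t−t0)/τ)`, continuous across phase
boundaries; isotonic reversal phases have zero asymptotic change and so
relax back toward baseline. Osmolality above 250 mOsmol/kg is hypertonic
(dehydration: negative geometric amplitudes, positive lens-scattering and
iris-sag responses), below 250 hypotonic (opposite signs), 250 isotonic.

The packaged schedules mirror the study design: a 60-min isotonic control
imaged every 5 min, and four challenge groups with 5 baseline repeats each.
The strong hypertonic challenge (Group I, 250–1000–250 mOsmol/kg, 10 + 13 +
40 min, imaged at 1/min during the challenge) carries the calibrated peak
amplitudes CCT −20.7 %, ACD −11.5 %, CRD −2.3 %, LT 0, LSI +28.8 %, and an
iris-sag asymptote of +48.2 µm. Group II (Drop-500) is described only as
having "decreased rate and magnitude", so its amplitudes default to half of
Group I with a slower τ. Group III (hypotonic Drop-100) has no printed
magnitudes either; the defaults are opposite-sign (CCT +15 %, ACD +8 %,
CRD +2 %, LSI 0) with a slower τ and an iris-sag asymptote of −24.6 µm.
Group IV chains a hypertonic and a hypotonic phase (single acquisition per
phase) and drives the iris through +48.2 then −24.6 µm. Time constants
(2.5, 2.8, 4.5, 3 min for the challenge phases) were chosen once so that
each phase reaches the steady state — change rate below 1 % of the initial
rate, i.e. after `τ·ln(100) ≈ 4.6 τ` — within its scheduled duration.
These amplitudes are the *study conditions*: the phantom encodes them, and
the analysis chain must re-measure them through the images.

`eyeAtTime()` maps the responses onto the geometry: the CCT change moves the
corneal endothelium (the anterior cornea is the fixed depth reference), the
ACD change translates the lens, the CRD change translates the retina, the
iris sag follows its own response with the root riding on the lens, and the
LSI change scales the opacified-lens intensity multiplier. The opacification
front sits at 0.3 of the optical lens thickness, anterior to which the lens
backscatter is multiplied — deep enough to cover the LSI sampling window, so
the measured LSI ratio equals the multiplier. Radii are held fixed over
time; a response that would violate the anatomical ordering fails geometry
validation rather than rendering nonsense.

## Segmentation

The study's segmentation algorithm is described only as "semiautomatic", so
the procedure here is the package's own design. Per column of the
box-smoothed image (7 axial × 3 lateral pixels — the narrow lateral window
keeps steeply sloped peripheral interfaces sharp), the intensity profile is
split into tissue runs above an Otsu-derived background threshold, with runs
shorter than 5 pixels absorbed as speckle flips. The run sequence reads
anatomically: the first run is the cornea; a deeper run whose mean intensity
exceeds 1.3× the median corneal level is the iris body (its posterior edge
is the pigment epithelium, and everything below is shadow); otherwise the
first deep run is the lens and the last is the retina, whose anterior edge
is the ILM. The lens opacification front never crosses the tissue threshold,
so an opacified lens stays one run. Each boundary is then refined to
sub-pixel precision as the centroid of the axial gradient (lag-6 difference)
over the contiguous support around the strongest appropriately-signed peak.
Optional user seed points (the "semiautomatic" element) override the
assignment with the gradient peak nearest the seeded depth.

Per surface, a robust arc fit with outlier rejection at 3 median absolute
deviations (with a 0.75-pixel floor so sub-pixel systematics on noiseless
images are not flagged) cleans the traces, and any column violating the
anatomical depth ordering is discarded — ordering is enforced by the
`SurfaceSet` validity, never merely assumed. Missing surfaces are reported
per label in the failure slot. The corneal vertex is the minimal-depth point
of the (median-smoothed) anterior corneal trace, ties broken at the lateral
midpoint; the AP axis is the vertical line through it.

## Refraction correction

`dewarp()` inverts the image formation exactly: layer by layer, each deeper
surface point is relocated along the refracted probing ray with geometric
segment length equal to the optical-path increment divided by the layer's
index, using surface normals from circular arcs fitted to the already
corrected shallower interface (`fitInterface()`: algebraic circle fit with
robust trimming; collinear traces fall back to a straight-line model, and
degenerate shallow-arc fits fall back to the osculating circle of a
quadratic fit). The iris pigment epithelium is corrected through the cornea
into the aqueous like the anterior lens surface. Points that experience
total internal reflection, or whose shallower surfaces are missing, are
excluded with a reason and the correction continues. On the AP axis the
correction reduces to division by the index (166.6 µm of corneal optical
path / 1.40 = 119 µm), and the drop indices (1.344/1.342/1.337/1.333 for
1000/500/250/100 mOsmol/kg) differ pairwise by less than 0.82 %, which is
why a single constant index stack is used regardless of the hydration state.

## Biometry

Axial distances are evaluated at the AP axis from each surface's fitted arc
(pooling the whole trace; exact on noiseless phantoms, noise-averaging
otherwise), except where the corrected trace collapses laterally (the
focused retina), where the cluster median is used. LSI is measured on the
*uncorrected* image — the average runs along the A-scan, which is natively
sampled in optical path — from the anterior lens boundary down to 0.15 of
the optical lens thickness (the anterior capsule-to-nucleus span; the exact
window is not quantified in the source and is configurable), averaged over a
±10-column band centred on the AP axis to keep speckle variance of the mean
small. IC fits a quadratic to each wing (falling back to the raw trace when
the wing is clearly not quadratic), anchors the contact landmark at the
intersection with the anterior lens arc, takes the signed extreme
perpendicular distance from the root–contact chord (+ toward the cornea),
and averages the wings; a missing contact falls back to the iris tip and
flags the record.

## Dynamics

The baseline of each parameter is the arithmetic mean of the five repeat
acquisitions; series are normalized as percent change (IC as µm change).
Per phase the summary reports the signed peak (ties → earliest), a
least-squares exponential fit `y(t) = y0 + A(1 − exp(−(t−t0)/τ))` with the
start level fixed (reversal phases thereby relax toward 0 %), and the
steady-state time: centred finite differences smoothed over a 3-frame
window, with the first window's rate as the initial rate and the earliest
time the absolute rate drops below 1 % of it. On a densely sampled
exponential this reproduces the closed form `t0 + τ·ln(100)`; on sparse
schedules (1 frame/min) the discrete initial-rate estimate is taken ~1 min
into the phase, which makes the detector conservative — a phase can be at
steady state by the closed form yet report "not reached".

## What the tests do and do not show

All validation runs on phantom data. Recovery of the model-eye dimensions,
the mouse baseline biometry, the calibrated challenge amplitudes (to within
0.2 percentage points, noiselessly) and the control-run stability (mean SD
of normalized fluctuations ≈ 0.3 % under the default noise model, bound
1.5 %) demonstrates that the analysis chain is unbiased with respect to its
own forward model, with problem sizes of one 1687×241 B-scan (mouse),
1700×261 (model eye), 28 frames (Group I) and 17 frames (control). It does
not demonstrate robustness to features real data have and the phantom lacks:
motion, specular vertex reflexes, sensitivity roll-off, layered retinal
substructure, eyelid or tear-film artefacts, or segmentation ambiguity in
closed iridocorneal angles (the hypertonic iris nearly touching the
peripheral cornea is exactly where the phantom's own detection starts to
lose columns). The control-stability metric is computed over the five
normalized curves (CCT, ACD, LT, CRD, LSI); IC is tracked in µm separately.

## Numerical choices and limitations

* Axial pitch 3 µm (optical) and lateral pitch 10 µm for the mouse, 12/40 µm
  for the model eye; image sizes default to fit the full eye plus margins,
  and a too-shallow image is a truncation *error*, not a silent clip.
* Tie-breaks: vertex ties → lateral midpoint; peak-change ties → earliest
  time; collinear interface fits → flat model.
* The posterior lens boundary is taken as the *last* negative step before
  the ILM rather than the first below the lens surface, so the
  opacification front (a weaker interior edge) can never masquerade as the
  lens posterior surface.
* Degenerate inputs: zero-thickness layers, empty LSI windows, flat images,
  all-zero volumes, and out-of-schedule times all raise errors with
  explicit messages.
* Whether the source study corrected whole images or only surface points is
  unstated; this package corrects points only (biometry needs nothing else).
  Whether LSI was computed pre- or post-correction is also unstated; the
  package uses the raw A-scan and documents it.
* Wing averaging for IC is a package choice (the source does not state
  whether one or both wings were reported).
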