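---
title: "Aortic distensibility from probe-tracked 2D ultrasound sweeps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic distensibility from probe-tracked 2D ultrasound sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rupture-risk management of abdominal aortic aneurysms (AAA) leans on the
maximum diameter, yet the mechanical state of the wall — how much the vessel
yields to the pulse pressure — is a more direct expression of its condition.
A freehand sweep of 2D B-mode cross-sections, with an electromagnetic tracker
recording the probe pose for every frame, captures the whole vessel in
seconds. Because the acquisition is not ECG-gated, every frame lands at a
different phase of the cardiac cycle: the pulsatile distortion that normally
corrupts a 3D reconstruction is, here, the signal. This package separates the
anatomical trend along the vessel from the cardiac pulsation at every
cross-section, reconstructs end-diastolic (ED), end-systolic (ES) and
mean-arterial-pressure (MAP) geometries, and converts the ED-to-ES change
plus a cuff pressure measurement into compliance, distensibility and
circumferential strain — locally per cross-section and globally per vessel.

`fit_aorta_sweep()` is the single entry point; it returns a classed object
with `print`, `summary`, `coef` and `plot` methods. Each stage is also an
exported function, so every intermediate object can be produced and
inspected on its own.

## Pipeline and model assumptions

1. **Segmentation** (`segment_sweep`). Frames are despeckled with a Euclidean
   shortening flow (curvature motion, an edge-preserving speckle filter) and
   a 3×3 Gaussian. From the previous frame's ellipse, rays are cast
   ("star" search) and the strongest dark-to-bright step inside a radial
   search band is kept per ray; a direct least-squares ellipse is fitted
   through the accepted edge points and a 5-state Kalman filter (random-walk
   dynamics on centre, semi-axes and rotation) stabilises the track. The
   lumen–wall (or thrombus–wall) interface is thus *modelled as an ellipse*:
   robust where the lateral walls fade, at the price of ignoring
   non-elliptic detail.
2. **Cardiac timing** (`detect_heart_frequency`, `detect_ed_frames`). The
   per-frame lumen area (pixel counting on a rasterised mask) forms an
   area–time signal; its Hann-windowed power spectrum inside the
   physiological band yields the heart frequency, widened by ±0.2 Hz
   (±12 beats/min) to absorb rate drift during breath-hold. Signal minima
   separated by at least the minimal period mark the ED frames.
3. **Geometry** (`build_centerline`, `build_polar_grid`, `envelope_radii`,
   `refit_phase_contours`). ED contour centres are mapped to 3D through the
   tracker poses, splined along cumulative chord length, resampled at
   0.5 mm and smoothed with a 15-sample moving average; each frame's origin
   is the intersection of this centerline with the frame plane. Contours
   become radius samples over equidistant angles, assembled into an
   (angle, time) grid. Per angle, constrained peak detection on the
   radius–time signal anchors the ES envelope; the negated signal gives the
   ED envelope; the MAP radius is their midpoint. Because per-angle
   interpolation can leave local irregularities, each phase contour is
   refit as an ellipse before being mapped back to 3D.
4. **Mechanics** (`correct_brachial_pressure`, `local_mechanics`,
   `global_mechanics`). Cuff pressures are corrected for the known brachial
   bias (diastolic ×0.88, systolic ×1.05) and converted to kPa. Then
   `C = ΔA/ΔP` (or `ΔV/ΔP`), `D = C/A_ED` (or `C/V_ED`) and
   `ε_circ = (l_ES − l_ED)/l_ED`, assuming incompressible, isotropic tissue
   and small strains. Volumes come from a ruled triangulation between
   consecutive contours, closed with end caps, integrated by the divergence
   theorem.
5. **Comparison** (`icp_register`, `compare_geometries`). A sweep geometry is
   rigidly registered to a reference (e.g. a CT segmentation) with 30
   iterations of ICP (SVD alignment, nearest-neighbour correspondence, no
   trimming), resampled into matched ~0.2 mm slices along the vessel axis,
   and scored per slice with the Dice similarity index and the Hausdorff
   distance, summarised as medians with interquartile ranges.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| search band thickness | 2.5 healthy / 7 AAA | mm | frame-to-frame change is pulsatile only in healthy aortas; AAAs also change shape along the sweep |
| `n_rays` | 64 | – | even angular support for the step detector and the conic fit |
| step kernel half-width | 5 samples at 0.1 mm | mm | matches the rendered/expected edge blur; wider kernels blur the localisation |
| edge acceptance | ≥ 0.3 × frame max score | – | drops rays in echo-poor sectors instead of letting them drag the fit |
| ESF iterations / step | 8 / 0.2 | – | enough curvature flow to flatten speckle without visibly eroding a ~10 mm lumen |
| Kalman process SD | 0.3 mm, 0.02 rad | per frame | upper bound on genuine frame-to-frame change at 25 Hz |
| Kalman measurement SD | from fit residuals (floor 0.05 mm) | mm | lets clean fits pass unsmoothed — a fixed large value attenuates the pulsation amplitude and biases distensibility low |
| physiological band | 0.67–2.0 | Hz | 40–120 beats/min |
| `n_angles` | 72 (5°) | – | resolves elliptic cross-sections; coarser grids alias the envelope |
| centerline resampling | 0.5 | mm | the moving-average kernel is defined in samples, so this step fixes the effective smoothing length (recorded in the output) |
| slice spacing / mask pixel | 0.2 / 0.2 | mm | comparison resolution well below the expected disagreement scale |
| mmHg→kPa | 0.1333224 | – | fixed conversion |

The brachial correction is applied multiplicatively (×0.88, ×1.05). A
division variant (÷1.12, ÷0.95) is available behind
`correct_brachial_pressure(variant = "division")`; the multiplicative form
reproduces the bundled volunteer table exactly at printed precision and is
the default.

## The phantom: what it emulates, and what it does not

`phantom_spec()`/`generate_sweep()` build a synthetic tracked sweep with
exact analytic ground truth: a vessel with axially varying base radius
(`aneurysm_profile()` gives a Gaussian bulge), a raised-cosine cardiac
waveform (`w = 0` at ED, `w = 1` at ES, so extrema are unambiguous; a
skewed-systolic option exists), a probe moving at constant speed, per-frame
poses with optional Gaussian position/angle jitter (defaults up to 0.5 mm /
0.5°, consistent with the ~1.5 mm point accuracy of electromagnetic
trackers), and rendered frames with dark lumen, bright wall band,
partial-volume edges (~0.7 px ramp, the transition midpoint exactly on the
true contour), optional lateral signal dropout and multiplicative
speckle-like noise. Ground truth includes per-frame contours, the local
distensibility profile `D(s) = ((1+ε(s))² − 1)/ΔP`, ED/ES volumes, heart
frequency and ED frame indices; identical seeds give bitwise identical
sweeps.

It is *not* a physical ultrasound simulator: no point-spread function, no
scan conversion, no refraction or shadowing from anatomy, no respiration.
Passing tests on the phantom therefore demonstrate that the signal
processing recovers known geometry and mechanics under controlled imaging
physics — not that segmentation will survive every clinical image. The
phantom's noise levels are engineering choices; no published speckle
statistics exist for the scanner class being emulated.

Default study conditions for the end-to-end checks: bulge 8→10 mm radius,
10% distension, 72 beats/min, 3 mm/s probe speed, 14 s sweep at 25 Hz
(350 frames of 96×96 px at 0.5 mm) — about four cardiac cycles per 10 mm of
vessel, the regime in which local estimates are well supported. These sizes
keep the full image pipeline under ~10 s on one CPU while leaving >10 beats
for the envelopes.

## Numerical choices

- **Areas** are pixel counts of rasterised masks (0.1 mm default), the
  convention the circumference/area extraction is defined by. The count is
  exact up to the lattice discrepancy of the contour (~0.01 mm² for a 10 mm
  circle, a few tenths of mm² for elongated ellipses); this cancels almost
  entirely in the ED/ES ratios that make up distensibility. Sub-2-pixel
  radii fall back to the analytic area with a warning.
- **Perimeters** use Ramanujan's second approximation on the fitted ellipse
  (cross-checked against dense polygonal arc length to 0.1%); a mask-derived
  polygonal variant exists, but rasterised perimeters are biased upward, so
  the analytic form is the default.
- **Edge localisation**: the discrete step response peaks half a sample
  before the transition midpoint; the detector compensates and then refines
  by parabolic interpolation of the response peak, giving ~0.01 mm
  localisation on clean edges.
- **Envelope interpolation** between anchors is shape-preserving monotone
  cubic (no overshoot between beats); before the first and after the last
  anchor the envelope extends the nearest anchor value, so the first and
  last cardiac cycle of a sweep have one-sided support and are excluded
  from local accuracy claims. Angles with fewer than two anchors fall back
  to their global min/max and are flagged.
- **Degenerate inputs**: a constant radius–time signal yields coincident
  ED/ES envelopes (flagged); a fit failure inherits the previous contour
  with a warning and more than 10 consecutive failures abort as a lost
  track; planes the centerline never crosses use the orthogonal projection
  of the nearest centerline point, flagged per frame.
- **Ties in the rank-sum test** are handled by mid-ranks inside an exact
  permutation enumeration (up to 2×10⁶ labellings; the 10-vs-9 cohort needs
  92 378); beyond that cap a tie-corrected normal approximation is used and
  flagged. This keeps the test exact for the cohort comparison despite tied
  distensibility values.
- **Volume orientation**: the signed divergence-theorem volume is taken in
  absolute value, so contour orientation cannot flip the sign.

## Design decisions that were genuinely open

- The Kalman measurement covariance follows the per-frame ellipse fit
  residuals rather than a fixed constant. With a fixed 0.5 mm SD the filter
  acts as a low-pass that attenuates the ~1 Hz pulsation by ~10% and biases
  distensibility low by the same order; residual-driven noise keeps clean
  measurements unsmoothed and still damps genuinely noisy ones.
- The in/out split of the search band is symmetric; the band definition
  only states a total thickness.
- Lateral dropout is modelled as the whole image fading to the background
  level in ±30° sectors about the lateral axis, because a dimmed wall alone
  would still leave a detectable lumen–tissue step — fading matches what
  echo dropout looks like and what the acceptance-threshold logic should
  reject.
- Registration in `compare_geometries()` operates on whatever geometries
  are passed; the MAP-state geometry is the recommended input, being the
  time-average shape the reference modality effectively images.
- The two bundled patient rows B2 and B7 are not reproducible from their
  own tabulated pressures and volumes under either pressure-correction
  variant; they are shipped verbatim, flagged as anomalies, and excluded
  from reproduction criteria rather than silently corrected.

## Known limitations

- Elliptical contours cannot follow strongly non-elliptic lumina
  (e.g. around thrombus); this is a modelling choice, not a failure mode.
- Local distensibility is only trustworthy where several cardiac cycles
  fall within a short stretch of vessel; fast probe motion confounds
  anatomical trend with pulsation, inflating ES envelopes near sharp
  calibre changes.
- Rigid registration cannot absorb the non-rigid differences between
  acquisitions taken days apart.
- The exact rank-sum enumeration is exponential; it is capped and falls
  back to the normal approximation for large cohorts.
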