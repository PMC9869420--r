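# aortasweep

Aortic geometry and distensibility from probe-tracked freehand 2D
ultrasound sweeps.

A freehand sweep of 2D B-mode cross-sections with a tracked probe images the
whole abdominal aorta in seconds, but — without ECG gating — every frame
lands at a different phase of the cardiac cycle. This package treats that
pulsatile "distortion" as signal: it segments the lumen–wall interface in
every frame (star–Kalman ellipse tracking), detects the heart frequency and
end-diastolic frames from the lumen area–time signal, separates the
anatomical trend from the pulsation by per-angle envelope detection on a
radius–time grid, and emits end-diastolic (ED), end-systolic (ES) and
mean-arterial-pressure (MAP) 3D geometries. Combined with a brachial cuff
pressure pair (corrected to aortic values: diastolic ×0.88, systolic ×1.05,
in kPa), it computes the mechanical indices

- compliance `C = ΔA/ΔP` (local, mm²/kPa) and `ΔV/ΔP` (global, ml/kPa),
- distensibility `D = C/A_ED` resp. `C/V_ED` (kPa⁻¹),
- circumferential strain `ε_circ = (l_ES − l_ED)/l_ED`,

locally per cross-section and globally per vessel. Sweep-derived geometries
can be registered to a reference segmentation (e.g. CT) with rigid ICP and
scored slice-by-slice with the Dice similarity index and Hausdorff distance.
A synthetic pulsating-vessel phantom with exact analytic ground truth makes
every stage testable without patient data, and the package ships the
reference cohort tables (10 healthy volunteers, AAA patient groups) that the
mechanics can be re-derived from.

Intended users: vascular imaging researchers and biomechanics groups who
want area/volume-based distensibility from tracked 2D ultrasound, and a
reproducible harness to validate each processing stage.

## Worked example

```r
library(aortasweep)

# synthetic tracked sweep: aneurysm bulging 8 -> 10 mm, 10% distension,
# 72 beats/min, probe at 3 mm/s for 14 s (25 Hz)
spec <- phantom_spec(base_radius = aneurysm_profile(8, 10, 21, 8),
                     distension = 0.1, heart_rate = 72, probe_speed = 3,
                     sweep_duration = 14, image_size = 96,
                     pixel_spacing = 0.5, ed_pressure = 10.6,
                     es_pressure = 16.0, seed = 7)
sw  <- generate_sweep(spec)
fit <- fit_aorta_sweep(sw, correct_brachial_pressure(70, 115),
                       vessel_class = "aaa")
summary(fit)
```

```
frames: 350; heart 1.21 Hz; ED frames: 17
V_ED 10.47 ml, V_ES 12.68 ml, C_global 0.281 ml/kPa, D_global 26.8 x 10^-3 kPa^-1
local distensibility: 26.9 +/- 0.9 x10^-3 kPa^-1
circumferential strain: 0.101 +/- 0.003
```

The fit found the phantom's heart rate (72 beats/min = 1.2 Hz), one ED frame
per beat, and ED/ES volumes whose relative difference matches the generated
10% radial distension (`(1.1² − 1) = 0.21 = ΔV/V_ED`); dividing by the
corrected pulse pressure of this cuff pair gives the global distensibility.
The per-station table `fit$local` maps distensibility and strain along the
vessel; `plot(fit)` shows the area–time signal with detected ED frames, one
angle's radius–time signal with its envelopes, and the local distensibility
profile. `write_results(fit, dir)` writes contours (CSV), phase meshes
(PLY) and mechanics reports (CSV/JSON).

Cohort-level reproduction from the bundled tables:

```r
reproduce_tables()
```

```
cohort reproduction (multiplicative pressure correction)
  C_global matched at 2 decimals: 16/17 non-anomalous rows
  D_global matched at integer precision: 17/17 non-anomalous rows
  flagged anomalies (reported, excluded from criteria): B2, B7
  D_global healthy: 79.5 +/- 14.65 x10^-3 kPa^-1; AAA: 29.0 +/- 9.64
  rank-sum p = 2.17e-05 (exact)
  mean AAA circumferential strain: 0.1533
```

A thin command-line wrapper with `simulate` / `segment` / `analyze` /
`compare` / `tables` subcommands is installed at
`system.file("cli", "aortasweep.R", package = "aortasweep")`.

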