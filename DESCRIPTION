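Package: aortasweep
Title: Aortic Geometry and Distensibility from Probe-Tracked 2D Ultrasound Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs end-diastolic, end-systolic and mean-arterial-pressure
    3D geometries of the abdominal aorta from non-ECG-gated, probe-tracked
    freehand sweeps of 2D ultrasound cross-sections, and computes local
    (area-based) and global (volume-based) compliance, distensibility and
    circumferential strain from brachial pulse-pressure measurements. Includes
    star-Kalman ellipse segmentation with edge-preserving despeckling, cardiac
    frequency and end-diastole detection from the lumen area-time signal,
    per-angle envelope detection on the radius-time grid, rigid iterative
    closest point registration with Dice and Hausdorff agreement metrics, a
    synthetic pulsating-vessel phantom with analytic ground truth, and bundled
    reference cohort tables for healthy volunteers and aneurysm patients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
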