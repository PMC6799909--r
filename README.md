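# markermorph

Quantitative morphometry of implanted radiopaque markers in longitudinal CT.

Radiopaque suture markers (barium-sulfate-infused polypropylene) can be tied
to soft tissue during surgery — for example to the rotator cuff tendons
during a repair — and show up on low-dose CT as small bright knots, with
tantalum beads or anchor-tied knots serving as fixed bone markers.
`markermorph` turns sequences of such scans into numbers a clinician or
researcher can use: how far has the repaired tendon retracted, how has the
marker-enclosed area changed, and how repeatable are those measurements?

The package is aimed at imaging researchers validating marker-based
measurement protocols (it ships a synthetic phantom generator with exact
ground truth) and at analysts processing marker-implant studies.

## What it computes

Given CT volumes (NIfTI or NRRD), per-scan bony-landmark annotations, and
approximate marker seed locations, the pipeline:

1. **Localizes markers** — voxels above a Hounsfield threshold (default
   800 HU) are grouped into 26-connected components, size-gated, and each
   marker is fit to the volumetric centroid of its component's voxels:
   `c = (1/N) Σ x_i` over member voxel centres in world mm (intensity
   weighting optional).
2. **Builds anatomical frames** — a scapular frame from the angulus
   acromialis (AA), trigonum spinae (TS) and angulus inferior (AI), and a
   humeral frame from the head centre and epicondyles, all with positive
   lateral/anterior/superior axes.
3. **Registers longitudinal scans** — follow-up scans are mapped into the
   day-of-surgery world frame by a least-squares rigid (Kabsch) fit of the
   scapular landmarks: `R, t = argmin Σ ‖R s_i + t − q_i‖²` over proper
   rotations.
4. **Imputes virtual markers** — software-placed points V1–V4 on the
   lateral edge of the rotator cuff footprint are carried into every scan
   by the rigid transform fitted to the physical bone markers H1–H3.
5. **Measures** — lengths are Euclidean distances between markers; the area
   of a marker quadruple (p1..p4, perimeter order) is the swap-averaged
   piecewise-triangle area,
   `A = ½ [tri(p1p2p3) + tri(p1p3p4) + tri(p2p3p4) + tri(p2p4p1)]` with
   `tri(abc) = ½‖(b−a)×(c−a)‖`; humeral orientation is reported as three
   projected angles (abduction in the coronal plane, internal/external
   rotation in the axial plane, flexion/extension in the sagittal plane).
6. **Summarizes** — repeat-scan *precision* is the mean of per-measurement
   standard deviations (sample SD, n−1) by class; *longitudinal change* is
   final minus baseline per measurement, summarized as mean ± SD per class.

## Worked example

The package bundles two reference tables from published validation work
with this marker system: per-measurement repeat-scan SDs from a cadaveric
shoulder imaged three times with repositioning, and per-timepoint values
from one rotator cuff repair patient imaged over 26 weeks.

```r
library(markermorph)

precision_from_table(reference_precision_table())
#> <precision_summary> pooled precision (mean of repeat-scan SDs):
#>   lengths 0.66 mm | areas 6.97 mm^2 | angles 2.1 deg

longitudinal_from_table(reference_longitudinal_table())
#> <longitudinal_summary> week 0 -> 26
#>   angle                  (angles, n=3): change     4.43 +/- 22.82
#>   anteroposterior        (lengths, n=3): change     3.17 +/- 3.85
#>   area                   (areas, n=3): change   226.57 +/- 32.68
#>   mediolateral           (lengths, n=4): change    19.07 +/- 2.87
```

Reading: measurement precision pooled over 14 tendon lengths is 0.66 mm
(on the order of the 1 mm knot size and the 0.5 × 0.5 × 0.6 mm voxel), over
6 areas 6.97 mm², over 3 humeral orientation angles 2.1°.  In the patient,
the four mediolateral lengths from the footprint to the lateral tendon
markers — the tendon retraction — grew by 19 ± 3 mm over 26 weeks, and the
marker-enclosed areas by about 227 mm².

The same statistics come out of the imaging pipeline.  A full synthetic
run — render three repeat scans of the cadaver marker layout with 20 HU
noise and 0.3 mm repositioning jitter, localize, impute, measure,
summarize:

```r
spec  <- cadaver_phantom_spec(noise_sd = 20, seed = 42)
study <- render_repeat_scans(spec, n_scans = 3, seed = 42)
run_study(study, mode = "precision")
#> <study_result> mode precision, 3 scans, 0 warnings
#> <precision_summary> pooled precision (mean of repeat-scan SDs):
#>   lengths 0.06 mm | areas 0.63 mm^2 | angles 0.0 deg
```

The phantom's pooled length precision (0.06 mm) is far better than the
0.66 mm observed on the bench: the synthetic scan contains no soft-tissue
clutter, no annotation error, and no true arm-position variability — see
the methods vignette (`vignettes/marker-morphometry.Rmd`) for what the
phantom does and does not emulate.

## Command line

```sh
markermorph phantom   --layout patient --seed 1 --out study_dir/
markermorph run       --study study_dir/study.json --mode longitudinal --out report/
markermorph localize  --volume scan.nii.gz --markers markers.json --out obs.json
markermorph summarize --table precision_table.csv --mode precision
```

`run` writes `measurements.csv`, `summary.json`, and a `manifest.json`
with parameters, warnings, and output checksums.

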