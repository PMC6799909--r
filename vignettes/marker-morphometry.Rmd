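---
title: "Marker-based CT morphometry: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based CT morphometry: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermorph)
```

This vignette records the measurement model implemented by `markermorph`,
the conventions and numerical choices behind it, what the synthetic
phantom does and does not emulate, and the package's known limitations.

## The measurement problem

Small radiopaque markers are affixed to soft tissue (suture knots on the
rotator cuff tendons, T1–T8) and to bone (anchor-tied knots or tantalum
beads in the humerus, H1–H3).  Each CT scan yields the 3-D world
coordinates of every marker; geometry on those coordinates gives
clinically interpretable quantities: mediolateral lengths from the tendon
insertion to the tendon markers (tendon retraction), antero-posterior
lengths along a marker row, areas enclosed by marker quadruples, and the
orientation of the humerus relative to the scapula.  Because no physical
marker can be placed on the lateral edge of the tendon footprint, four
*virtual* markers (V1–V4) are defined there in software in a reference
scan and carried into every other scan rigidly with the bone markers.

Marker numbering follows the measurement tables of the validation work:
odd-numbered tendon markers form the lateral row (paired with V1–V4),
even-numbered markers the medial row.

## Coordinate contract

Volumes are stored with a 4×4 affine mapping **0-based voxel indices** to
world millimetres; index (0, 0, 0) is the **centre** of the corner voxel.
Internally all world coordinates are LPS (+x left, +y posterior,
+z superior), the native convention of DICOM-derived CT; NIfTI RAS
affines are flipped on load and restored on write, and NRRD `space`
fields are honoured.  One fixed internal convention removes an entire
class of sign errors; anatomical directions are *never* inferred from
world axes but always derived per subject from landmarks.  Landmarks are
supplied in world mm of their own scan, decoupling annotation from voxel
storage.

## Marker localization

The analyst's marker identification is automated as: threshold at a fixed
Hounsfield value (default **800 HU** — barium-loaded polypropylene is
bright but dimmer than metal; the value separates knots from soft tissue
and trabecular bone and is a configuration knob), group supra-threshold
voxels by **26-connectivity**, and keep components of **3–500 voxels**.
The size gate is the default defence against cortical bone, which also
exceeds the threshold but forms vastly larger components; an explicit
bone mask is unnecessary for the scan geometries handled here.  Each
analyst seed is then matched to the nearest component centroid, greedily
by ascending distance with lexicographic tie-breaks, one-to-one, with a
**10 mm** cap (knots are ~1 mm; the cap tolerates sloppy seeds while
preventing cross-marker capture).  Two seeds competing for a sole
component is an error rather than a silent misassignment.

The marker position is the **volumetric (unweighted) centroid** of its
component's voxel centres; intensity weighting is available but not the
default, since the volumetric centroid is the defined estimand.  On the
clinical voxel grid (0.5 × 0.5 × 0.6 mm) a 1.5 mm knot spans only a few
voxels, so partial-volume information carried by rim voxels matters: the
phantom renders it explicitly, and localization accuracy is validated
against ground truth rather than assumed.

## Anatomical frames

Both frames are right-handed orthonormal triads with anatomical names:

* **Scapula** — lateral = unit(AA − TS); anterior from the (AA, TS, AI)
  plane normal, (AA − TS) × (AI − TS); superior = lateral × anterior,
  anterior re-orthogonalized as superior × lateral.  Origin AA.
* **Humerus** — superior = unit(HH − (ME + LE)/2), where HH is given
  directly or sphere-fit (linear least squares) from ≥ 5 head-surface
  points; anterior = superior × (LE − ME), normalized; lateral completes
  the triad.  Origin HH.

The Gram–Schmidt order is fixed as written, so results are exactly
reproducible.  The construction is equivariant: rigidly moving the
landmarks rigidly moves the frame (tested to 1e-9).

**Side handling.**  A mirrored anatomical triad cannot stay right-handed
with all three axes anatomical, so a convention is required.  Here
lateral and anterior are always anatomical (lateral points away from the
midline on either side); on the **left** side the frame's `superior` axis
is the internal *inferior* direction, preserving
lateral × anterior = superior.  All reported angles are unsigned
projected angles between corresponding axes of two consistently built
frames, so they are unaffected by this choice; direction words
(abduction vs adduction, etc.) are attached from the signed variant.

## Geometry definitions

* **Length**: Euclidean distance, mm.
* **Area**: for a marker quadruple in perimeter order p1→p2→p3→p4, both
  diagonal triangulations are computed — each triangle as half the
  cross-product magnitude of its edge vectors — and averaged.  For planar
  convex quadruples the two triangulations agree (equivalence with the
  shoelace formula is tested to 1e-9); for non-planar marker quadruples
  the swap-average is the defined estimand.  Quadruple order reproduces
  the conventional table row labels verbatim.
* **Humeral orientation**: projected angles onto the scapular coordinate
  planes — superior axes onto the coronal plane (normal = scapular
  anterior) for abduction, medial-lateral axes onto the axial plane
  (normal = scapular superior) for internal/external rotation, superior
  axes onto the sagittal plane (normal = scapular lateral) for
  flexion/extension.  A projection shorter than 1e-6 of its vector's norm
  (a gimbal-like configuration) raises an error rather than returning
  noise.

## Registration and virtual-marker imputation

Longitudinal registration is **landmark-based rigid** (Kabsch/Umeyama
without scaling) on the scapular landmarks, mapping each follow-up scan
into the reference (day-of-surgery) world frame.  Landmark registration
is deterministic and sufficient here because every reported quantity is
either inter-marker (rigid-invariant) or frame-relative; an
intensity-based backend would be an extension, not a correction.  The
SVD determinant correction guarantees a proper rotation — a reflection is
never returned even when it would fit better.  Exactly three
non-collinear points fully determine the rotation, so the H1–H3 triad is
accepted; collinearity is guarded by an off-axis spread threshold of
0.5 mm.  Virtual markers are imputed by applying the rigid fit of
reference-to-current bone markers to the reference virtual positions;
the bone-marker fit RMS is reported as the imputation quality.

## Statistics

Repeat-scan **precision** of a measurement is its sample SD (n − 1) over
repeats; the pooled precision of a class (lengths, areas, angles) is the
unweighted mean of the per-measurement SDs.  The n − 1 convention is
self-consistent with the bundled longitudinal table: the four
mediolateral changes summarize to 19 ± 3 mm with n − 1 (and ± 2 with n).
**Longitudinal change** is final minus baseline per measurement, with
mean ± sample SD per class/group.  Values are kept at full precision
internally; display rounding (lengths/areas to 0.01, angles to 0.1) is
applied only in print methods, using `round()` half-even semantics.

One reference value is knowingly not reproducible: the bundled patient
table's three area changes have mean 227 mm² but sample SD ≈ 33 mm², not
the ± 3 mm² that accompanies the published mean — almost certainly a typo
in the source — so the area-change SD is not asserted anywhere.

## The phantom: what it emulates, and what it does not

`phantom_spec()` renders markers as spheres (default radius 0.75 mm,
2000 HU) over a 40 HU soft-tissue background with a 1200 HU bone
cylinder, on the clinical 0.5 × 0.5 × 0.6 mm grid (default 160 × 160 ×
128 voxels; unit tests use a 128 × 120 × 96 crop of the same layout).
A sphere is the simplest shape with the same centroid contract as a knot
blob; knot geometry adds no testable structure.  Partial volume is
modelled by 3×3×3 supersampled coverage fractions — binary rasterization
would quantize exactly the sub-voxel accuracy under test.  Optional
Gaussian blur and iid Gaussian HU noise follow; all randomness sits
behind one explicit seed and the same spec + seed is bit-reproducible.

Two study generators mirror the two validation protocols:
`render_repeat_scans()` (repositioning jitter: translation SD 0.3 mm per
axis and rotation SD 1° about the scene centre, emulating a specimen
re-approximated to neutral between scans) and `render_longitudinal()`
(per-timepoint cumulative tendon retraction, rigid humeral motion about
a scapular axis through the head centre, and whole-scene repositioning).
The default patient script retracts the four lateral tendon markers by
18/23/18/17 mm (mean 19 mm) along the footprint measurement line — a
displacement collinear with the measured segment translates one-for-one
into the length change, making the scripted retraction an exact ground
truth — with the humerus externally rotated 12–18° at the intermediate
visits and returned to neutral at the endpoints.

What the phantom deliberately does **not** emulate: soft-tissue clutter
and neighbouring bright anatomy, beam hardening and metal artifacts,
landmark annotation error (frames are built from exact landmark ground
truth, which is why phantom angle precision is near zero while the bench
value is 2.1°), marker migration or detachment, and scanner-specific
reconstruction kernels.  Passing phantom tests therefore demonstrates
correctness of the measurement chain — segmentation, centroid fitting,
frame construction, registration, imputation, statistics — not the field
accuracy of any particular scanner protocol.

## Numerical choices and degenerate inputs

* Collinear landmark triads (triangle area < 1 mm²) and collinear point
  sets in rigid fits are errors, not warnings.
* The seed-assignment tie-break (lexicographic by label) makes the
  greedy matching deterministic.
* Degenerate quadrilaterals return area 0; empty components are
  precondition errors.
* Missing markers void only the measurements that reference them; the
  rest of the scan record is computed and the omission is annotated.
* Problem sizes in the validation suite — 128–160-voxel grids, 3 repeat
  scans, 5 seeds, 50 noise replicates, 1000-case property loops — were
  chosen so the full suite exercises every claim at sub-voxel tolerances
  while remaining comfortably runnable on a laptop.

## Known limitations

* Registration is landmark-only; scans without reliable scapular
  landmarks cannot be registered (no intensity/ICP fallback).
* The humeral frame needs the epicondyles, which lie outside a shoulder
  field of view; clinical use relies on their annotation in a
  larger-coverage acquisition or on the direct HH + shaft conventions.
* The segmentation threshold is global and fixed per run; contrast
  variation across scanners is handled by configuration, not adaptively.
* DICOM series are out of scope — volumes must arrive as NIfTI or NRRD.
* Statistics are per-study descriptives; no cohort-level inference.
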