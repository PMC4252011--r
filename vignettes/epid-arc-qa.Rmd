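---
title: "Arc-delivery mechanical QA from portal images: models and methods"
author: "epidArcQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arc-delivery mechanical QA from portal images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A linac gantry carries several hundred kilograms of rotating hardware whose
flex under gravity is not captured by any encoder: the gantry head describes
a slightly non-circular path, the two multileaf-collimator (MLC) carriage
boxes (~36 kg each) shift bodily along the leaf-travel direction, and the
EPID — a 7 kg flat panel on a jointed support arm — sags, twists and tilts
as the gantry rotates. Each effect is small (tenths of a millimetre to a few
millimetres) but systematic, and each matters: carriage sag displaces the
whole treatment field, and EPID sag corrupts any portal-dosimetry or
geometry measurement made with the panel.

`epidArcQA` analyses one arc's worth of megavoltage portal images of a
five ball-bearing phantom and separates these effects per gantry angle. Four
4.8 mm tungsten-carbide balls (a = gun-left, b = gun-right, c = target-left,
d = target-right) are rigidly mounted on the gantry head so that they project
to (±50, ±50) mm at the isocentre plane, inside an 18 × 18 cm² MLC-defined
field; a fifth ball (e) on a rod fixed to the couch is placed at the nominal
isocentre with the room lasers. The head markers rotate with the gantry;
ball e stays put in the room. Everything the method reports is a *relative*
quantity: the image taken at gantry zero is the reference, because machine
calibrations are themselves defined at gantry zero.

### Coordinate conventions

One set of conventions is used everywhere (`R/AllClasses.R`): +X is the
cross-plane axis toward the right (R) field edge, +Y the in-plane axis
toward the gun (G); pixel (1, 1) is the top-left pixel with +Y up the image;
gantry angles follow IEC 61217 normalised to (−180°, 180°]. All public
outputs are mm at the isocentre plane — detector positions are divided by
SDD/1000 using the header SDD — except the SDD change itself, which is a
detector-plane quantity.

## Per-angle analysis model

Let superscript θ denote the image at gantry angle θ and ⟨·⟩ an average over
the named markers.

**Setup-misalignment correction.** If ball e sits (A, B) mm off the true
isocentre (laterally, vertically), its projection traces A·cos θ in X and
B·sin θ in Y over a rotation — pure geometry of a point rotating with the
beam around it. The EPID sag is therefore

    EPID Sag_X(θ) = [e_X(θ) − A cos θ] − e_X(0),
    EPID Sag_Y(θ) = [e_Y(θ) − B sin θ] − e_Y(0).

A and B are estimated by ordinary least squares of the e-marker displacement
on the bases {cos θ − 1} (X) and {sin θ} (Y). Two choices are deliberate:

* *Reference anchoring.* Taken literally, the first equation gives −A at
  θ = 0, contradicting the convention that all series are zero at the
  reference. The correction is therefore applied as A·(cos θ − 1), which
  restores sag(0) = 0 without changing any range or shape statistic. The
  literal form remains available (`epidSag(..., anchor = "literal")`).
* *Identifiability.* A cos θ panel motion in X is mathematically
  indistinguishable from a lateral offset of ball e; likewise sin θ in Y.
  The fit assigns those harmonics to (A, B) by construction. The simulator's
  `MachineModel` validity therefore rejects a `cos1` term in the cross-plane
  EPID-sag curve and a `sin1` term in-plane: those degrees of freedom belong
  to `eMarkerOffset`. This is not a simulator quirk but a property of the
  measurement model itself — a real machine whose panel truly moved as cos θ
  would be reported as a setup offset. Any other harmonic (including sin θ
  cross-plane and cos θ in-plane) is measured faithfully and, over a uniform
  full-circle schedule, is exactly orthogonal to the misalignment basis, so
  no sag "leaks" into A or B.

**Gantry sag** is the mean head-marker displacement minus the EPID sag —
the head markers move with both the head and the panel, ball e with the
panel alone, so the difference isolates the head.

**ΔSDD** comes from magnification: the cross-plane separation between the
left pair (a, c) and right pair (b, d) midpoints scales with the true
source-to-detector distance while the analysis divides by the constant
header SDD, so the separation ratio to the reference gives
ΔSDD = SDD⁰·(ratio − 1).

**Skewness** Ψ is the change of the angle of the line through a head-marker
pair, default (a, b), with (c, d) as a rigid-body cross-check (the two agree
to 0.01° for a rigid rotation).

**Tilt** uses differential magnification: a pitched panel magnifies the
gun-side pair differently from the target-side pair. Each pair yields an
apparent-ΔSDD estimate; the tilt is arctan of their difference over the
in-plane distance between the pair midpoints (pitch, φ_Y), and analogously
with the left/right pairs and in-plane separations (roll, φ_X). A common
SDD change cancels exactly. One published formulation of the roll equation
indexes the pairs as (a, b)/(c, d) with a gun-to-target midpoint distance in
the denominator, which is degenerate (0/0) for a rectangular layout and
inconsistent with the pitch equation; the package defaults to the
geometrically meaningful pairing — roll from the left pair (a, c) versus the
right pair (b, d) over the cross-plane midpoint distance — and keeps the
pairing configurable in `PhantomGeometry`.

**MLC carriage sag** is the marker-centroid-to-edge distance per direction
(L and G as centroid − edge, R and T as edge − centroid, so a positive
change always means the bank moved outward on that side), re-referenced to
gantry zero. Because the markers ride on the head and the leaves on the
carriages, a common-mode shift cancels and only the carriage's bulk motion
— invisible to the per-leaf encoders — remains.

## Image preprocessing and its phase

Two filters run before any measurement:

1. **Conservative smoothing**: a pixel outside the [min, max] envelope of
   its 8-neighbourhood is clamped to the nearer bound. This removes isolated
   noise spikes exactly while leaving ramps, penumbrae and shadow edges
   untouched; it is exactly idempotent.
2. **2 × 2 rank filter, rank 4**: the maximum of each 2 × 2 window, read as
   the 4th order statistic, aligned to the window's top-left corner. It
   suppresses single-pixel dark dropouts, which matters because the
   ball-bearing shadows are themselves dark. Rank 1 (minimum) is selectable
   via `PhantomGeometry`.

A 2 × 2 window has no centre pixel, so the rank filter carries a half-pixel
phase shift toward the bottom-right, and (being a grey-scale dilation) it
advances every 50% edge crossing half a pixel toward the dark side. Both
effects are deterministic and are compensated in the measurement code: pixel
coordinates on the filtered grid are read as index + 0.5, and each field-edge
crossing is moved half a pixel toward the bright side (sign flipped for
rank 1). A second pass of the full chain re-touches only the
intensity-transition bands (< 2% of a noiseless frame).

## Ball-bearing localisation

Detection proceeds in three stages on each image:

1. **Candidates**: matched filtering of the inverted (shadow-positive) image
   with a disc kernel of the isocentre ball's projected radius, restricted
   to the aperture interior; connected regions above 40% of the peak score
   become candidates. Fewer than five is a detection error that reports the
   count found.
2. **Role assignment**: a global translation fit against the nominal layout
   — every candidate/role pairing proposes a translation, the translation
   supported by the most roles wins, and each role takes its nearest
   candidate. Ambiguous assignments and separations deviating more than 25%
   from the layout are errors, not guesses.
3. **Sub-pixel refinement** on the conservatively smoothed image (the rank
   filter re-samples the shadow edge anisotropically, so refinement avoids
   it; candidates found on the filtered grid are carried over with the
   half-pixel phase). An intensity-weighted centroid seeds a *ring
   regression*: with area-weighted rasterisation, a pixel in the shadow's
   edge band has intensity linear in its signed distance to the edge, so for
   transition pixels (normalised depth s between 0.15 and 0.85)

       d_i = r0 + dCol·cos φ_i + dRow·sin φ_i + w·(0.5 − s_i)

   is a linear least-squares problem in the centre offset (dCol, dRow), the
   edge radius r0 and the edge width w. It uses every edge pixel at its
   exact position (no interpolation), absorbs the edge width instead of
   assuming it, and a residual-based rejection pass discards pixels hit by
   surviving noise spikes. On simulated aS1000 frames with 1% Gaussian noise
   this localises a head-marker shadow to roughly a micron at the isocentre
   plane, which is what the tilt and ΔSDD metrics need: both multiply marker
   errors by lever-arm factors of ~15 (100 mm pair separations against a
   1500 mm SDD).

**Field edges**: the open-field plateau and blocked-region baseline are
median estimates inside/outside the nominal aperture; the edge level is
their midpoint (the universal 50% field-edge convention — the original
description does not state a threshold). For the left and right banks the
cross-plane profile of each 5 mm leaf band is crossed at the 50% level by
linear interpolation and the bank edge is the mean of the per-leaf
crossings; gun/target edges use the in-plane profile averaged over the
central third of the aperture. Marker shadows are masked (2 projected
diameters) before profiles are taken. An aperture that is clipped, or more
than 10% off its nominal 180 mm, raises an edge error naming the side.

## The forward simulator

`MachineModel` parameterises every deformation as a low-order harmonic
series in θ — coefficients `sin1..sin3`, `cos1..cos3` evaluated as
sin(kθ) and cos(kθ) − 1, plus an optional `step` term 1(θ < 0) to emulate
the discontinuity around gantry zero seen on real machines. Every curve is
therefore exactly zero at the reference, like the measurements.

`projectMarkers()` produces the *apparent* isocentre-plane marker and edge
positions by construction rather than by composing physical transforms: pair
separations are set from the SDD and tilt terms, pair-line slopes from the
skew, centroids from the gantry-plus-EPID common mode, ball e from the EPID
sag plus the (A, B) signature, and edges from the common mode plus the
carriage curves. The construction is the exact algebraic inverse of the
analysis equations, so running the metrics on projected positions returns
the injected curves to numerical precision (~1e−13 mm in the tests). This
exactness is what makes the simulator a usable oracle: any pipeline error
shows up as itself, not as model mismatch. Second-order physical couplings
that the analysis equations do not model (a skewed panel slightly rotating
the field edges, magnification acting on the edge positions, the kink this
would put into ΔSDD at large skew) are deliberately absent from the
projection; they are below a hundredth of a millimetre at the amplitudes of
interest.

`renderBeamImage()` rasterises: plateau 8000 counts, 5% leaf transmission,
linear penumbra (2.5 mm at the detector), ball shadows as attenuation discs
with area-weighted anti-aliasing (60% central depth), Gaussian noise (1% of
plateau) and bright salt spikes (0.2% of pixels), then 16-bit quantisation.
Panels: `aS1000` (1024 × 768, 0.392 mm pitch — the default) and `aS500`
(512 × 384, 0.784 mm). `simulateArc()` writes one DICOM RT Image per
scheduled angle (a minimal explicit-VR-little-endian writer/reader pair
lives in the package, covering exactly the RT Image tags the method needs)
plus a ground-truth CSV; the noise seed derives from the model seed and the
replicate id, so fixtures are bit-reproducible and replicates share their
truth.

What the simulator *does not* emulate — and therefore what passing tests do
not establish about real data: scatter, beam-energy and detector-response
effects on shadow contrast; leaf-by-leaf position errors and rounded leaf
ends (banks move rigidly); couch and phantom-rod flex; panel-arm vibration
within one frame; cine frame-averaging artefacts (each stored image is taken
as final, as the acquisition software delivers it); and header SDD tracking
the true SDD (the header carries the nominal value, as on the real system,
which is precisely why ΔSDD must be measured from magnification).

### Default machine ("study conditions")

`defaultMachineModel()` encodes deformation scales typical of in-service
clinical machines: in-plane EPID sag range 1.0 mm and cross-plane 0.17 mm
(the panel moves more freely in-plane); gantry sag ranges 0.70/0.42 mm;
ΔSDD up to 1.7 mm; skew range 0.15°; pitch up to 0.10° and roll 0.02°; MLC
carriage ranges 0.82/0.68 mm left/right — extremal near gantry ±90° where
gravity acts along the leaf travel, with the left-bank maximum at −90° —
and 0.34/0.32 mm gun/target; e-ball setup offset (0.8, −0.5) mm.
Gravity-symmetric (in-plane) deformations are cosine-type, cross-plane ones
sine-type. Noise defaults (1% Gaussian, 0.2% salt) represent a
flood-corrected portal image at these monitor-unit levels.

## Statistics and tolerances

`rangeSummary()` reports max − min per metric (the standard per-machine
statistic) with extrema angles; `reproducibility()` the per-angle sample SD
over replicate arcs (angles matched by nearest neighbour within 2°) and its
maximum; `rmsdCompare()` the per-metric RMSD between two series (CW vs CCW,
collimator 0 vs 90) after linear interpolation onto the union of their angle
grids within the common range — series are ordered by the physical IEC
angle, so a CCW series pairs correctly without special handling.
`toleranceCheck()` applies TG-142 non-stereotactic values: EPID and gantry
sag on max |value| per axis (2 mm, 1 mm), ΔSDD on max |value| (5 mm), MLC
carriage on the range per direction (1 mm, a carriage offset being a
systematic field-edge error; the 0.3 mm systematic-leaf-error literature
value is carried as an informational note). Skew and tilt have no TG-142
threshold and are reported unjudged.

## Numerical choices and degenerate inputs

* Reference frame: minimum |gantry angle|, required within 2° of zero
  (cine sampling is ~4°/image); ties go to acquisition order. Series are
  sorted by frame index, so shuffled input is harmless.
* Misalignment fit requires ≥ 8 angles spanning ≥ 270°; pair-based metrics
  raise geometry errors when reference separations or midpoint distances
  fall below 10 mm (denominator protection).
* Series analysis skips images whose detection fails (with a warning per
  image) and aborts below 80% usable images or on a failed reference.
* The beam-axis point on the panel comes from RT Image Position when
  present, else the geometric panel centre.
* A zero-deformation, zero-noise arc analyses to *exactly* zero in every
  metric: each image is then identical, so the (identical) sub-pixel
  systematics cancel in the re-referencing. The noiseless systematic error
  of the pipeline is instead visible under deformation, where sub-pixel
  positions vary: about 1e−4° and a few tenths of a micron RMS.

## Validation problem sizes

The test suite validates the analytic inversion on 37-angle schedules
(< 1e−9 everywhere), the full image pipeline on a 91-image cine arc under
the default machine (RMS recovery within 0.05 mm for lengths and 0.02° for
angles; misalignment amplitudes within 0.02 mm), a noise-free null machine
(≤ 0.02 mm / 0.01° everywhere, all verdicts passing), and the statistics
machinery on three replicates plus a CW/CCW pair of 37-image arcs.
`scripts/acceptance.R` re-runs the same computations from scratch. At these
conditions the tilt metrics sit at the estimator's information bound —
per-image tilt noise is ~0.01°, comparable to the reproducibility reported
for this class of measurement — so tilt ranges below ~0.05° in a report
should be read as noise, not machine motion.

## Known limitations

* The analysis assumes the rectangular default marker layout for the
  simulator's exact inversion; arbitrary (non-degenerate) layouts work for
  measurement but have no analytic oracle.
* Collimator rotation is carried as metadata only; the simulator does not
  re-orient the carriage-sag pattern with the collimator, so collimator
  0-vs-90 comparisons on simulated data measure the statistics machinery,
  not a physical interplay.
* Jaw-defined fields, kV imagers and dosimetric calibration are out of
  scope; exactly five markers are supported.
* DICOM support is limited to single-frame explicit-VR little-endian
  RT Image files carrying the required tags.
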