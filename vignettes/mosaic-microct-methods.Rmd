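---
title: "Methods: wide-field mosaic micro-CT from planning to airway volume"
author: "mosaicCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wide-field mosaic micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mosaicCT)
```

# The problem

High-resolution synchrotron tomography of fresh soft tissue races against
post-mortem degradation: a whole small-animal lung must be imaged in roughly
twenty minutes at micrometre resolution, which a single scan cannot cover.
The approach implemented here tiles the organ with a 3-D mosaic of fast
*wide-field* (extended field of view) scans: each tile is a 360-degree scan
with the rotation axis placed near one edge of the detector, which nearly
doubles the reconstructable diameter per scan and quarters the number of
tiles needed.  Each tile is then a motion-free snapshot; slow tissue motion
appears only *between* tiles and is compensated at the stitching stage by
local, non-rigid displacement fields.  The fused volume is finally segmented
into airways and the airway volume quantified.

`mosaicCT` implements this entire chain and, because beamline data of this
kind is terabyte-scale and not reproducible on a desk, ships a physics-based
acquisition simulator so that every stage is testable end to end against a
known ground truth.

# Mosaic planning and timing

`buildPlan()` lays tiles on a regular lattice with configurable overlap and
orders them column-wise, vertical axis fastest, zigzag along every axis, so
each motion visits an adjacent unmeasured tile.  Serpentine ordering of the
columns in the horizontal plane realises the "nearest unmeasured volume"
rule; any rule with that property would do, and the serpentine is the
simplest deterministic one.

`estimateDuration()` prices the plan with a `TimingModel`: per-scan wall
time (default 9.0 s for a 2000-projection 360-degree scan at 72 deg/s plus
readout overheads), stage motions at constant speed (550 um/s vertical,
220 um/s horizontal) plus a 3 s settle overhead per move, and a one-off
calibration block.  The calibration default of 5 s covers 50 dark and 300
flat frames at 2.5 ms exposure plus shutter/readout overhead; it is recorded
once at plan start, before the first tile.  For the reference 3 x 3 x 7
plan (10.8 mm tiles, 7.2 / 2.75 mm steps) this predicts 63 scans, 54
vertical and 8 horizontal moves and a total just under 21.5 minutes.

`validRegions()` reports the valid-data geometry of a wide-field tile: the
reconstruction is complete inside a circle of the full reconstructed
diameter, and the largest inscribed square has side `diameter/sqrt(2)`
(rounded to whole pixels; for a 3927 px diameter this gives a 2777 px
square, so a 100 px overlap is about 4% of the valid width).  Whether the
often-quoted "30% of the full area" refers to linear or areal overlap is
ambiguous; `overlapMap()` therefore reports overlap extents explicitly, in
mm and pixels, per adjacent pair and in both tiles' local frames.

# The acquisition simulator

The simulator is first-class, tested code; its defaults are the study
conditions all downstream tests run under.

**Phantom** (`makeFoamPhantom()`): a cylindrical tissue "body" containing a
cylindrical "lung" filled with a foam of carved spherical airspaces on a
jittered body-centred-cubic lattice, connected by thin ducts and by a
vertical "trachea" that reaches the top face (so connectivity-based
segmentation has a defined seed), plus three vertical high-attenuation
"bone" rods between lung and body surface.  Lattice pitch follows from the
requested wall thickness and air fraction; a calibration loop rescales the
airspace diameter until the realized air fraction (over the lung region) is
within 5% relative of the target.  Ground truth is exact bookkeeping: the
carved air mask and its voxel count times the voxel volume.

The attenuation map is smoothed with a Gaussian of 1.5 voxels.  This models
the finite system resolution (source size, scintillator, optics) and is
numerically essential: the linear single-material propagation transfer
amplifies spectral content near the Nyquist frequency by a factor of
roughly 900 at the reference optics (21 keV, 0.1 m propagation,
2.75 um pixels), so razor-sharp voxel edges would drive simulated
intensities far outside physical range.  Binary ground-truth masks are kept
unsmoothed; boundary voxels of the attenuation map take partial-volume
values, as they would in any real reconstruction.

**Projection** (`projectParallel()`): discrete line integrals with unit
voxel stepping and bilinear in-slice sampling, about a vertical axis at a
configurable detector offset.  This conserves mass to well under 0.5% for
smooth objects and is exactly linear; it is not a pixel-perfect Radon
transform, which is why reconstruction tests use tolerance bands rather
than exact equality.

**Contrast and illumination** (`applyContrastAndIllumination()`): contact
intensity `exp(-depth)` is edge-enhanced by multiplying its Fourier
spectrum with `1 + (z * delta / mu) |k|^2` — the exact algebraic inverse of
the Paganin retrieval filter, built by the same helper so the frequency
convention (angular, rad/m) cannot drift between the two directions.  The
frame is then multiplied by a drifting incident flat field, and dark offset,
Poisson photon noise (default 5000 counts/pixel at unit transmission) and
Gaussian read noise are added.  Illumination drift is a rank-K model: a
smooth mean flat plus K orthonormal zero-mean spatial patterns with AR(1)
coefficients (default K = 3, 2% RMS, lag-one correlation 0.95), emulating
slow monochromator vibration with a spatial correlation length of a few
pixels.  Full Fresnel wave optics, polychromaticity and detector PSF are
deliberately out of scope: the pipeline reconstructs under the
single-material assumption anyway, and the linearized transfer makes the
retrieval round trip exactly invertible, which pins down the whole
simulator/reconstruction stack numerically.

**Deformation** (`makeDeformationModel()`): a smooth random displacement
field on a coarse control grid, scaled linearly in time (zero at t = 0),
emulating slow post-mortem relaxation between tiles.  The default growth
rate of 0.02 voxels/s gives sub-voxel to few-voxel mismatches over the
minutes-scale separations of a mosaic, matching the observation that
stitching mismatch grows with time separation between tiles.

**Mosaic** (`simulateMosaic()`): each tile warps the phantom at its
predicted start time, keeps the whole phantom in the beam (true local
tomography: rays integrate through material outside the tile's field of
view), projects over 360 degrees and packages the frames with one shared
calibration set and its timestamp.  Complementary projections at theta and
180 + theta carry an extra configurable angular offset (default 0.04565
degrees); the stored angle arrays are the true angles.

# Flat-field correction

`correctStatic()` divides by the mean flat; `fitFlatBasis()` computes the
principal components of the dark-subtracted flat stack through the
frame-space Gram matrix, and `correctDynamic()` fits per-frame drift
coefficients by least squares on a sample-free background region (default:
the 20 outermost detector columns per side) before dividing by the
per-frame effective flat, floored at 1e-6 of its median.  The
margin-based weight estimation is simpler and deterministic compared with
variational estimators, and is sufficient for low-rank drift — *when*
sample-free margins exist.  In a wide-field mosaic whose rays traverse the
whole specimen, corner tiles have no sample-free margin, the least-squares
weights are biased by absorption, and the correction can be badly wrong;
the pipeline therefore defaults to static correction for mosaic tiles and
reserves the dynamic correction for scans with clean margins, where it
demonstrably removes stripe and ring artifacts (see the paired comparison
in the test suite: both the sinogram stripe metric and the reconstructed
ring metric drop by factors of 2-6).

`ringMetric()` quantifies rings as the mean absolute deviation of the
angular-mean radial profile from its 9-sample moving-average baseline;
`stripeMetric()` is the standard deviation of the detrended column means of
the log-sinogram.  Both are deliberately simple, monotone scores used only
for paired comparisons on identical data.

# Phase retrieval

`paganinRetrieve()` is the single-distance single-material retrieval:
divide the frame's spectrum by `1 + (z delta / mu) |k|^2` and take
`-log/mu`.  Parameters default to the empirical values for lung tissue at
21 keV: delta = 2.0e-7, beta = 2.8e-10, giving mu = 4 pi beta / lambda =
59.6 1/m at lambda = 5.904e-11 m.  Frames are reflectively padded (default
width `max(64, 2 sqrt(z delta / mu) / pixel)`, the filter's characteristic
length) to suppress wrap-around from laterally truncated data; with
`padPx = 0` on periodic frames the retrieval is the exact inverse of the
simulator's transfer (round-trip error at machine precision), which is the
property the acceptance suite locks in.

# Reconstruction

`fbpSlice()` implements filtered back-projection with the exact discrete
Ram-Lak kernel (sampling |nu| directly biases the DC response by a few
percent), optional Shepp-Logan apodization, trapezoidal angular weights for
non-uniform angles (halved over full-turn coverage of a full detector), and
linear detector interpolation about a sub-pixel rotation centre.  The
Fourier-regridding reconstruction used at beamlines is replaced by direct
FBP: the properties of interest here are geometric, and FBP is an accepted
equivalent at this scale.  Projections are padded with edge-value cosine
tapers before filtering; zero padding would inject a strong low-frequency
bias for laterally truncated (interior-tomography) projections, which is
the normal situation for mosaic tiles.

`reconstructExtendedFov()` performs the 360-degree offset-axis assembly:
every half-projection is treated as an independent view at its true angle
(stored angle plus the complementary-pair offset for views beyond 180
degrees); for ramp filtering each truncated row is completed across the
axis with its complementary view's data; for back-projection the samples
beyond the rotation centre are discarded (hard cut, the default) or blended
with linear angular-position weights over the doubly-measured band
(`overlapMode = "weight"`).  Output diameter is `2 (cols - center)` pixels.
Against a 180-degree full-field FBP oracle on the same phantom the
assembly's RMSE is within a few percent of the oracle's own, and ignoring
the planted complementary-pair offset measurably degrades it - at desk
scale the offset is worth ~0.1 px at the FOV edge, at the real detector
width ~3 px.

`findCenter()` scans candidate rotation centres, scores each
reconstruction by sharpness, and refines the best by a parabolic fit.  The
sharpness criterion in use at beamlines is not published; negative Shannon
entropy of the grey-level histogram is this package's choice, validated by
planted-axis recovery to well under half a pixel.  `interpolateCenters()`
linearly interpolates per-layer centres between a top and bottom
measurement, compensating the linear drift of the axis position with stage
height; sub-tile centre variation is ignored.

# Non-rigid stitching

The chain is: phase-correlation refinement of each adjacent pair's nominal
offset (`coarsePairwiseShift()`, sub-voxel peak, low-confidence pairs keep
their nominal offset), globally consistent tile positions by
confidence-weighted least squares anchored at the earliest tile
(`globallyPositionTiles()`), block-matching displacement fields per pair
with normalized cross-correlation (`blockMatchField()`; reference = the
earlier-acquired tile, since deformation grows with time separation),
median/MAD outlier rejection plus Gaussian-weighted smoothing
(`filterAndSmoothField()`), sequential warp composition in acquisition
order, and linear-ramp weighted fusion (`blendMosaic()`) that also records
the per-voxel standard deviation of overlapping contributions (population
convention) and a provenance count.  Each tile's blending weight also falls
to zero at the edge of its inscribed circle, the valid region of an
extended-FOV reconstruction.

Displacement fields are regularized aggressively, because a wrong warp is
worse than no warp: fields are skipped on overlaps thinner than one
matching block; dropped when their median non-rigid displacement is below
0.5 voxels (measurement noise at this scale) or when warping fails to
reduce the pair's overlap RMS on a voxel subsample; and the warped fusion
as a whole is kept only if it lowers the global mean overlap standard
deviation relative to rigid fusion.  On genuinely deformed mosaics the
non-rigid path cuts the overlap std roughly in half; on static mosaics it
cleanly falls back to rigid.  Strongly non-linear deformations (e.g. late
local inflation) are outside the model, as they are for the block-matching
framework this emulates.

`artifactStatistics()` reports the fraction of overlap voxels whose std
exceeds a threshold, globally and per axial slice.  The threshold defining
an "artifact voxel" is configuration, with no claim of equivalence to any
real-beamline figure: those depend on the data.

# Segmentation

Four steps, as `segmentAirways()`: (1) `maskBone()` removes bone with a
single global threshold (auto-derived, if not given, as the intermeans
split of the above-tissue values); (2) `isoThresholdSlicewise()` computes a
per-slice iterative intermeans (Ridler-Calvard) threshold inside a
cylindrical mask bounding the lung (auto-fitted to the body outline) and
labels sub-threshold pixels air - air is *below* threshold because
reconstructed attenuation of air is lower than tissue; (3)
`extractConnectedAirways()` keeps only the 26-connected component attached
to the trachea seed (default: the largest component touching the top face -
the seed rule is this package's convention, the original procedure does not
state one); (4) `refineSegmentation()` dilates the mask (default radius 3),
re-thresholds an unsharp-masked copy (Gaussian sigma 2, amount 1.0)
restricted to the dilated region, and reports volume as voxel count times
voxel volume.  The intermeans iteration starts from the mean intensity; a
mid-range start can lock onto the tissue/bone split when bright bone is in
the volume.

The dilation-restricted second pass matters quantitatively: the first
global pass sees unbalanced class populations and biases the threshold into
the air mode, clipping a boundary shell; restricting to air plus adjacent
tissue re-balances the classes and recovers the boundary at the half-level.

# Study conditions, problem sizes, and what passing tests show

Tests and the acceptance script run at desk scale, chosen to keep the whole
suite within minutes on one CPU while preserving the physics that matters:

* The end-to-end smoke mosaic is 2 x 2 x 2 extended-FOV tiles (128 px
  detector, axis at column 24, 208 px reconstructed diameter, 240
  projections per tile) over a 340 x 340 x 88 voxel phantom at 2.75 um.
* Desk-scale tissue attenuation is set to 2800 1/m so that the optical
  depth through the 0.35 mm phantom matches that through a real
  ~25 mm specimen at ~57 1/m; at unscaled attenuation the desk scans would
  be Poisson-noise dominated and every stage would be testing noise.
* Segmentation accuracy is validated on phantoms whose airspaces
  (~15-40 px) sit well above the retrieval filter length (~7 px), which is
  the regime the real procedure operates in - it segments airways, not
  alveolar septa, which are below the resolution limit.  Stage-wise
  recovery is within ~3%, the full pipeline within ~3% at the default
  conditions (the acceptance band is 5% and 10% respectively).

Passing these tests shows the algebra, geometry and statistical behaviour
of every stage is right under a controlled forward model.  It does not show
robustness to effects the simulator excludes: Fresnel fringes beyond the
linear transfer, polychromatic beam hardening, detector afterglow, strongly
non-linear tissue motion, or real anatomical texture.

# Numerical choices and degenerate inputs

* Effective flats are floored at 1e-6 of their median; non-positive
  transmissions are floored with a warning before the logarithm.
* Intermeans iterations stop at 1e-6 absolute change; degenerate
  (single-valued) slices borrow the nearest valid slice's threshold.
* Displacement outliers: |d - median| > 5 MAD per component, with the MAD
  floored at 1e-3 voxels so exact-constant fields still reject gross
  outliers; all-invalid fields return the identity with a warning.
* Flat center-score curves return the range midpoint with a warning;
  maxima on the candidate-range boundary are flagged `at_edge`.
* All randomness flows through named integer seeds; identical seeds give
  bit-identical phantoms, projections and pipeline outputs.

# File formats

Projection sets are stored as a directory of little-endian float64 raw
blocks (`data.raw`, `data_dark.raw`, `data_white.raw`) plus a `meta.json`
carrying angles and acquisition attributes - the usual exchange layout
(projections, darks, whites, theta, attributes) in a dependency-free
container with bit-identical round trips.  Reconstructed tile and fused
volumes are 32-bit TIFF stacks (one page per slice, min/max normalized,
scale recorded in a JSON sidecar with origin, voxel size and timestamp).
Pipeline configurations are YAML.  Units are fixed package-wide:
micrometres for pixels/voxels, millimetres for mosaic space, degrees for
angles, seconds for time.
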