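---
title: "Methods: a software-only mixed-reality orthognathic surgery simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a software-only mixed-reality orthognathic surgery simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosim)
```

`orthosim` re-creates, entirely in software, the computational pipeline of
a mixed-reality orthognathic surgery simulator: a system in which real
plaster dental casts, tracked by a 60 Hz electromagnetic digitizer, drive
the bone segments of a virtual dento-skeletal model reconstructed from CT,
with an acrylic reference splint carrying three 6.0 mm titanium spheres as
the common fiducial between the two worlds. This vignette documents the
models and procedures, the assumptions behind them, the tunable
parameters, and the limitations of the synthetic phantom that stands in
for the physical hardware.

Conventions used throughout: lengths in mm, angles in degrees, a
right-handed world frame with +X toward anatomical left, +Y anterior and
+Z superior. Rotations stream as intrinsic Z-Y'-X'' Euler angles
(azimuth = yaw about +Z, elevation = pitch about the rotated Y, roll about
the twice-rotated X), the convention of the tracker family the pose stream
emulates; the gimbal-lock tie (|elevation| = 90) is resolved by reporting
roll = 0. The source device documentation never states a convention, so
this is a documented assumption, pinned by round-trip property tests.

## The synthetic phantom

The phantom replaces patient, CT scanner, dental 3D scanner and tracker.
Its realism is deliberately *geometric*, not radiological: intensities are
four strictly ordered levels (air 0, soft tissue 40, bone 300, titanium
1000 by default) with no Hounsfield calibration, partial-volume blur, or
beam physics. That is sufficient to exercise thresholding, labeling,
registration, and projection; it does **not** exercise intensity
inhomogeneity, scanner noise, or genuine streak artifacts, so passing
tests bound algorithmic correctness, not robustness to raw clinical data.

* `generate_skull_volume()` builds a 128^3, 1 mm-isotropic CT-like volume
  (both configurable): a soft-tissue head ellipsoid, a cranial vault
  shell, two mirrored orbital rims, a mandible whose body follows the
  ground-truth lower-border curve with two ramus plates and condylar
  heads, and the three splint spheres at titanium intensity. The grid is
  centered so coordinates negate exactly under index reversal; with a zero
  asymmetry offset the volume is therefore *bitwise* mirror symmetric
  about x = 0, which is the ground-truth mid-sagittal plane.
* `generate_dental_arches()` returns the clean "scanned" lower arch (a
  tube along a quartic-like arch curve with per-tooth bumps and the three
  measurement landmarks: lower central incisor, bilateral first molars)
  and its CT counterpart: the same surface moved by a known scan-to-CT
  transform with a configurable fraction of vertices (default 0.3; the
  source system never quantifies artifact extent) displaced by uniform
  noise of +/-2 mm. The artifact-free flag is carried on *both* meshes —
  in reality the usable areas are outlined on the CT and transferred to
  the scan; the phantom provides that correspondence directly, and
  automatic artifact segmentation is out of scope.
* `generate_mandible_mesh()` provides the labeled surface used by the
  osteotomy simulation and the MLB fit; its bottom vertex ring lies
  exactly on the ground-truth quartic. A whole-mandible lateral offset
  emulates a laterally displaced mandible; a ramus-only offset emulates
  asymmetry confined to the ramus.
* `simulate_tracker_stream()` samples a time-parametrized rigid motion at
  60 Hz (1/60 s = 16.6 ms at the device's printed 0.1 ms resolution).
  Positional noise is uniform per axis on (-0.308, 0.136)/sqrt(3) mm so
  that the per-sample Euclidean error stays inside the device's printed
  linear-error band; the device spec gives no angular error, so angular
  noise is Gaussian with sd 0.05 degrees as a documented assumption.
  Every generator takes a single integer seed and is bit-reproducible.

## Fiducial detection

Spheres are detected by thresholding and 3D connected-component labeling
with 26-connectivity (the labeling method itself is all the source system
specifies; the connectivity choice is ours and provably immaterial at the
splint's >20 mm sphere spacing). The default threshold is an Otsu cut
applied twice — once to split soft from dense material, once on the dense
tail to split bone from metal. Candidate components are filtered by
volume within [0.4, 2.5] x the nominal sphere volume and bounding-box
aspect ratio <= 1.5; exactly three must survive, else a structured
detection-count error lists the survivors. Centers are intensity-weighted
centroids with no model-based sphere fit: at 1 mm voxels the centroid
error is below half a voxel, inside the system's ~0.3 mm error budget.
Naming is geometric: the incisal sphere minimizes the summed distance to
the other two; of the molar pair, the smaller +X center is the right one.

## Dental fusion (trimmed ICP)

`icp_register()` aligns the masked scan vertices to the CT dentition by
iterated correspondence + Kabsch fit, discarding the worst 10 % of pairs
per iteration (trim configurable). Correspondence is
point-to-nearest-surface-point, implemented in two phases inside one
iteration budget: nearest-vertex matching first (cheap, finds the basin),
then the closest point on the triangles incident to the nearest vertex.
The refinement matters: pure vertex matching inherits spurious local
minima from the mesh sampling lattice (on the phantom arch these sit
around 3 degrees / 0.9 mm off truth), which surface matching removes.
Because the one-ring search is an approximation of the true closest
point, single iterations can regress slightly; the implementation
therefore keeps the best pose seen so far, reports the non-increasing
sequence of accepted improvements as its residual history, and declares a
phase settled after 10 consecutive iterations without a tolerance-sized
(default 1e-6 mm) improvement. `converged` is honest: with the default
100-iteration budget, large initial misalignments can run out of budget
and say so; at 300 iterations the fit recovers random offsets up to
10 mm / 10 degrees exactly on the phantom. `fuse_dentition()` then removes
the CT's dental-labeled vertices and unions in the transformed scan with
per-vertex provenance labels; no stitching is attempted across the seam
because downstream stages consume labeled points, not watertight surfaces.

## Calibration and the mixed-reality bridge

Digitizing a splint sphere with the bowl-tipped stylus places the tip on
the sphere surface with the stylus long axis (+X of the receiver frame;
the axis choice is ours) through the center, so the center sits
diameter/2 = 3.0 mm ahead of the tip. Three named centers in each frame
give the tracker-to-virtual transform V by Kabsch fit; calibrations with
residual >= 1 mm are rejected. A streamed cast pose P(t) maps to the
virtual segment transform

    V P(t) P(t0)^-1 V^-1

with P(t0) the reference pose captured while the casts occlude the
splint. Conjugating by the *relative* pose is what makes the unknown
cast-to-receiver mounting cancel; the zero-noise round trip
(ground-truth motion -> stream -> calibration -> segment transform ->
landmarks) reproduces ground truth to 1e-9 mm over a full 10 s / 60 Hz
session, which pins the algebra. Streams are processed sample by sample
with no filtering (the source system does not state any).

## Osteotomy simulation

Sagittal splitting ramus osteotomy is abstracted to planar cuts — the real
split surface is curved, but the simulation treats segments as rigid
bodies, which a planar vertex partition captures exactly. Vertices beyond
a cut plane (toward its normal) form the proximal condyle-bearing
segment; everything else, including the un-cut side under a unilateral
scheme, stays in the mobile tooth-bearing distal segment. Triangles
straddling a cut follow their centroid and are dropped if their vertices
end up in different segments (partition correctness, not visual fidelity,
is the contract; vertex conservation is asserted). Plans whose cuts would
strand teeth proximally, or miss the mesh entirely, are rejected. Only
the distal segment ever moves; proximal repositioning strategy is out of
scope, so superimposition comparisons report condylar displacement as a
diagnostic quantity rather than simulating it.

## Diagnostic coordinate frames

The mid-sagittal plane minimizes the "difference between right and left
orbit", operationalized — the source names no metric — as the mean
nearest-neighbour distance from the left orbital point set to the
mirrored right one (centroid distance and Hausdorff are available
options). The optimizer is a deterministic Nelder-Mead simplex over the
normal's two spherical angles plus offset, initialized from the centroid
pair; on noiseless mirrored sets it recovers the plane to < 0.1 degree
and 0.01 mm. The cranial frame takes the plane normal as the left-right
axis, anchors the superior axis to world +Z (the only superior reference
available from orbital data alone; the frame is therefore equivariant
only under motions preserving +Z, and an orientation-ambiguity error is
raised when the plane normal is parallel to +Z), and completes the triad.

The mandibular local frame (MLB) fits a quartic to the lower-border
points after projecting them onto their principal-component plane, with
the in-plane axes oriented so the width axis points toward +X and the
quartic opens upward. The curve is re-expressed about its global minimum
— the arch front — so the constant and linear terms vanish there; the
frame origin sits at that minimum with axes (arch width, anterior,
plane-normal completion). The full axis construction is not given by the
source (only a figure); it is pinned by phantom tests instead. The fit is
the exact least-squares solution (verified against the normal equations
at 1e-9).

Asymmetry is reported as signed landmark distances to the mid-plane
(positive toward anatomical left) and, per left/right region pair, the
symmetric mean nearest-neighbour distance between one side and the
mirrored other — the statistic that localizes asymmetry to the ramus
rather than the tooth-bearing arch on the phantom.

## Virtual cephalometric image

`projection_geometry()` models the cephalostat: point source, film plane
with in-plane axes, and the ear-rod axis, with the central ray running
from the source through the ear-rod point to the film origin. In the
standard lateral setup that makes the ear-rod axis *parallel* to the film
normal, and the constructor enforces exactly that. Default distances are
conventional cephalostat values — 1500 mm source-to-ear-rod, 150 mm
ear-rod-to-film (magnification 1.1) — because the source names the
components but no dimensions. Volume rendering integrates intensity along
each pixel's ray (trilinear interpolation, step = half the minimum voxel
spacing by default; halving the step changes integrals by < 0.5 %). The
integral is linear, not Beer-Lambert: the image is meant for geometric
tracing, where only ray geometry matters, not dosimetry. Mesh rendering
counts surface crossings per ray by perspective rasterization. Images are
written as 16-bit plain-text PGM plus a world-to-film mapping JSON.

## Accuracy protocol and statistics

`run_accuracy_protocol()` emulates the physical accuracy experiment: per
repetition the lower cast is "arbitrarily moved" — operationalized, since
the source gives only the observed distance range, as translations
uniform within +/-10 mm per axis and rotations uniform within +/-10
degrees per axis, which spans the printed 0.19–15.56 mm distance range —
and the three landmark moving distances are measured both on ground truth
("real") and through the full noisy pipeline: noisy stylus digitization,
calibration, a noisy reference + moved pose pair, segment transform,
landmark displacement. The report mirrors the published table layout
(average / sd / min / max per landmark for virtual, real and |difference|)
plus a per-landmark Wilcoxon signed-rank test of virtual against real.

The signed-rank test follows the classical procedure the source's table
footnote names: zero differences dropped, ties mid-ranked, W the smaller
signed-rank sum, exact two-sided p by full 2^n enumeration for n <= 12
and the continuity-corrected normal approximation (with tie-corrected
variance) beyond. Inside the protocol, paired differences below 1e-9 mm
count as zeros so that the zero-noise pipeline — algebraically exact, but
subject to ~1e-15 float rounding — reports the degenerate all-tied case
rather than a meaningless p-value. With device-band noise the mean
absolute virtual-vs-real error lands around 0.2 mm, the same order as the
0.27–0.39 mm the physical system reports; the physical numbers arise from
a hardware experiment and are a plausibility anchor here, not an equality
target (the source itself prints two inconsistent summaries, 0.32/0.31/
0.27 mm in text against 0.39/0.37/0.31 mm in its table, which is a second
reason not to assert equality against either).

## Problem sizes, determinism, degenerate inputs

Default sizes (128^3 volume, ~900-vertex arches, 25-repetition protocol)
run the full demonstration in well under a minute on one CPU; the test
suite, which repeats detection over 20 phantoms and ICP over 20 offsets,
completes in about two minutes. These sizes are the package's chosen
study conditions, and all stochastic stages flow from single integer
seeds, so every artifact is bit-reproducible. Degenerate inputs fail with
typed conditions rather than warnings: collinear point sets for Kabsch
and calibration, < 3 masked ICP vertices, coincident orbital centroids,
sub-3-voxel sphere resolution, cut planes that miss the mesh, empty pose
streams, unknown configuration keys (named in the error), all-zero
Wilcoxon differences.

## Known limitations

* The phantom's metal artifact is labeled vertex noise, not a physical
  streak model; artifact segmentation is assumed given.
* Occlusal contact is not modeled — in the physical system the casts
  themselves provide collision feedback, which has no software
  counterpart here.
* Only rigid multi-segment repositioning is simulated; corticotomy-style
  bone deformation and proximal-segment strategy are out of scope.
* The cranial frame's superior axis relies on world +Z; a tilted
  acquisition would need an external superior reference.
* Accuracy statements transfer to real data only to the extent the
  geometric phantom captures it; they validate the pipeline's algebra and
  numerics, not clinical performance.
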