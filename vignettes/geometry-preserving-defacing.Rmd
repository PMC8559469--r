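---
title: "Geometry-preserving MRI deidentification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-preserving MRI deidentification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(geodeface)
```

# The procedure

`geodeface` deidentifies a T1-weighted anatomical volume in three steps.

**Step 1 — surfaces.** A marker-based priority-flood watershed on the
gradient-magnitude image separates head from background: background markers
are placed on the volume border at sub-threshold intensity, head markers are
the eroded suprathreshold core, and flooding priority is the local gradient
magnitude with deterministic lexicographic tie-breaking. The head mask is
the largest connected component of suprathreshold voxels inside the head
basin, with interior cavities filled. Inside the head, intensities are split
into three clusters (dark skull band, mid scalp, bright brain) by k-means
seeded at fixed quantiles (0.02, 0.35, 0.85) of the interior distribution —
seeding at quantiles makes the clustering deterministic, and the three
cluster means define midpoint thresholds. The brain is the connected
component, at the wide dark/bright midpoint, that contains the conservative
bright core; the skull band is the largest dark component. Skin and skull
surfaces are then extracted as triangulated meshes: Gaussian pre-smoothing
of the binary mask (1 voxel sd), isosurface at 0.5 by marching tetrahedra,
largest component, Taubin smoothing (10 iterations, lambda = 0.5,
mu = -0.53), outward orientation. Marching tetrahedra (six tetrahedra per
cell sharing the main diagonal) is used as the isosurfacing primitive: it
needs no case tables and its output is watertight and consistently oriented
by construction.

A deliberate asymmetry: *cluster estimation* uses the smoothed volume, but
*final mask classification* uses raw voxel intensities against the midpoint
thresholds. Thresholds sit several noise standard deviations from every
tissue mean (the phantom guarantees a 5-sigma separation; see below), so raw
classification is exact with overwhelming probability, depends only on local
data, and — critically — is invariant to what the defacing step later writes
into the facial shell. This is what makes the brain mask of an anonymized
volume *identical* to that of its original, not merely similar. On real
MRI, where partial-volume ramps exist, the smoothing parameter
(`segment_params(smooth_sd = )`) moderates this behaviour and the guarantee
degrades gracefully to high Dice rather than exactness.

**Step 2 — landmarks.** Face and ear control points either come from a
template bundle (volume + labelled points + checksummed manifest) through
intensity-based registration, or are supplied manually (Slicer FCSV or
JSON; FCSV coordinates are interpreted per the file's declared coordinate
system and converted to RAS, with LPS assumed — Slicer's default — when the
declaration is missing). Registration estimates the template-to-subject
affine in stages: intensity-centroid initialization, translation,
translation+anisotropic scale, rigid+scale, then a full affine refinement
at a finer resolution level, each by Nelder-Mead with restarts on a metric
that averages intensity and gradient-magnitude correlations. Scale is
committed before rotation is admitted because, on near-ellipsoidal heads,
scale and rotation trade off in a shallow metric valley and the coarse level
can alias toward a spuriously rotated optimum; for the same reason the final
affine stage refines from both the rotated and the rotation-free bases and
keeps whichever the fine level prefers. An optional demons-style dense
refinement (`mode = "affine+demons"`) runs on a coarsened grid with matched
filtering of both volumes and clamped sampling (edge fill values otherwise
destabilize the update). Transferred points are finally projected onto the
subject's extracted skin mesh, which enforces the on-surface invariant
regardless of registration quality — residual registration error appears
only as tangential placement error, which the acceptance analysis bounds at
5 mm on an inflated-head pair. Projections beyond 15 mm are flagged; if more
than half the points are flagged the transfer aborts and manual points are
recommended.

**Step 3 — masking.** The skull-to-skin shell is computed by voxelizing the
skin and outer-skull meshes (parity-counting scanline voxelization in index
space) and taking their set difference: voxels inside the skin but outside
the outer skull. The active mask is the union of Euclidean balls around the
control points (default radius 25 mm for face points, 20 mm for ears — the
defaults fully cover the default phantom's nose and ear protrusions)
intersected with the shell. Active voxels are replaced by draws *with
replacement* from the exact multiset of shell intensities; voxels strictly
outside the skin surface are zeroed (configurable: `--zero-exterior
global|off`); every other voxel is copied bitwise. Draws are assigned in
increasing linear voxel order under `set.seed(seed)`, so output is bitwise
reproducible and independent of iteration order. Voxel centres lying exactly
on the skin isosurface count as inside and are preserved.

Two interpretation choices the masking rule leaves open: the mask reaches
inward to the **outer** skull surface (not the inner), and one **global**
shell intensity distribution is used rather than local neighbourhoods.
Both are the simplest readings consistent with the procedure; geodesic
surface patches and spatially correlated fill are documented extensions,
not implemented.

# The synthetic phantom

`make_phantom()` builds the study object all tests run on: four strictly
nested ellipsoids (brain, inner skull, outer skull, skin) with T1-like
contrast — background 10, skull 40, scalp 100, brain 130 (arbitrary units),
additive Gaussian noise sd 5. The inner-skull-to-brain gap stands in for
CSF and shares the skull's dark intensity, as CSF is dark on T1. A nose
(15 mm protrusion) and two ears (12 mm) are rendered as scalp-intensity
half-ellipsoids protruding from the skin, so the face mask has nontrivial
geometry to remove; feature protrusions are part of the ground-truth label
volume and tracked as separate masks for replacement audits. The default
grid is 128^3 at 1.5 mm isotropic — full-pipeline runs stay under a minute —
and the head centre sits 8 mm posterior of the grid centre so the nose fits
the field of view with a one-voxel margin (validated at spec construction).
Ground truth is analytic: surfaces are isosurfaces of the exact quadratic
fields sampled on the grid (no mesh smoothing — the field is smooth, and
smoothing can fold the sharp nose/ear union creases into
self-intersections), and landmarks lie exactly on the skin.

Two invariants of the spec are enforced at construction: strict per-axis
nesting of the ellipsoids, and tissue means separated by at least five
noise standard deviations. The second is the contrast guarantee that makes
raw-intensity classification exact (above): with a minimum 30-unit gap and
sd 5, every midpoint threshold is at least 3 sigma from the nearest tissue
mean, and misclassified voxels are isolated speckles removed by
largest-component and hole-filling steps.

What the phantom does *not* emulate: partial-volume ramps at tissue
boundaries (each voxel carries exactly one compartment's mean), bias
fields, Rician noise, anatomical asymmetry and real cranial topology.
Passing tests on phantoms therefore demonstrate the pipeline's geometric
correctness and its conservation/determinism contracts, not segmentation
robustness on clinical data.

`degrade_like()` produces the two competitor surrogates used by the
evaluation tests: `blank-face` zeroes facial *surface tissue* (background
and scalp compartments) within the face control-point regions, emulating
template-cut defacing — deliberately sparing the brain compartment, which
the balls geometrically clip on this phantom; `blur-face` Gaussian-blurs
the full region in place, emulating blurring defacers. At kernel sds up to
about 12 voxels blurring degrades geometry but not topology; at 16 voxels
(24 mm) it destroys the dark skull band, collapsing the inner-skull
reconstruction and shrinking the outer-skull region far outside its
reference volume — the regime the ordering tests use as the "large kernel",
mirroring how blurring-based defacing breaks watershed reconstructions in
practice.

# Evaluation metrics

`jaccard()` is the intersection-over-union of two voxel masks (defined as 1
when both are empty). `hausdorff()` samples each surface densely —
all vertices plus `n_samples` (default 10^4) area-weighted face-interior
points from a deterministic low-discrepancy sequence — and takes the
maximum exact point-to-triangle distance to the other mesh, accelerated by
a uniform spatial grid; vertex-only evaluation would systematically
underestimate. `screen_usability()` is a reproducible proxy for visual
inspection: *failed* = extraction error or non-watertight mesh; *distorted*
= more than one component, genus above zero, self-intersecting, or enclosed
volume outside the reference range (default +/- 25% of the corresponding
surface of the subject's own original volume); *usable* otherwise. The
self-intersection test ignores contacts shallower than 1e-4 mm: raw
marching-tetrahedra surfaces contain micro-sliver triangles where the
isosurface grazes a lattice point, and their apparent contacts are
numerical noise, not distortion. A human rater might classify borderline
meshes differently; the thresholds are configurable.

`compare_pair()` reproduces the full comparison protocol on any
original/deidentified pair: brain-mask Jaccard using the package's own
watershed segmentation applied identically to both volumes (a deliberate,
self-contained substitute for external skull-stripping toolboxes),
usability screening of the four re-extracted surfaces, and per-surface
Hausdorff distances computed only where the surface is usable in both
members — the same conditional design as the original analysis.
`report_stats()` wraps the standard paired tests (Wilcoxon signed-rank with
Holm correction, McNemar) over batched results.

# Numerical choices and degenerate inputs

* Watershed flooding uses a binary heap keyed by (priority, linear index):
  ties break lexicographically, so results are identical across platforms.
* k-means is seeded at fixed quantiles and run with Lloyd iterations —
  deterministic, no random restarts.
* Uniform-intensity or contrast-free volumes abort segmentation with a
  diagnostic error rather than returning garbage masks; empty masks,
  non-nested surfaces and empty shells are geometry errors.
* Mesh extraction returns defective meshes *flagged* (feeding the usability
  screen) rather than erroring, because a distorted reconstruction is an
  outcome the evaluation is designed to measure.
* Volumes are never resampled: all computation runs on the native grid, in
  world millimetres, with canonical (RAS) axis ordering obtained by
  permutation and flips only.
* Output NIfTI headers are regenerated from the volume's own geometry; no
  descriptive fields or extensions are copied from any source file. Header
  hygiene of *inputs* remains the user's responsibility, but outputs cannot
  inherit identifying metadata.

# Problem sizes used in the shipped checks

The test suite exercises unit properties on 64^3 phantoms at 3.2 mm and
the end-to-end properties on the default 128^3 grid at 1.5 mm;
registration checks run on 112^3 grids at 2 mm, where an inflated-head
pair (all radii +10%) bounds landmark-transfer error. Hausdorff estimates
use 10^4 surface samples. These sizes were chosen so a full run completes
in minutes on a single CPU while keeping every geometric tolerance
voxel-scale.

# Known limitations

* The watershed is a self-contained marker-based implementation, not a
  re-creation of the hybrid template-deformation algorithm used by
  Freesurfer-based pipelines; what the shipped checks establish is geometric
  fidelity on phantoms, and no bit-compatibility with any external tool is
  claimed.
* Registration is affine (optionally demons-refined) and relies on the
  skin projection to absorb residual error; strongly non-affine anatomy
  (paediatric, pathological) should use manual points or a
  population-specific template via `make_template()`.
* The fill is i.i.d. per voxel: its histogram matches the shell exactly,
  but it carries no spatial correlation, so masked regions look like
  textureless noise up close.
* DICOM assembly, BIDS management, 4D series and header scrubbing beyond
  the geometric-only write are out of scope.
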