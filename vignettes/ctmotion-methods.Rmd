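---
title: "Measuring load-induced tibial implant displacement from paired CT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring load-induced tibial implant displacement from paired CT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctmotion)
```

## The measurement problem

After total knee arthroplasty, loosening of the tibial component is the most
common reason for revision surgery, and static imaging is a poor detector of
it. A load-based alternative acquires two CT scans of the same leg, one under
a valgus and one under a varus bending moment, and asks how far the implant
moved relative to the tibia between the two load states: a well-fixed implant
moves with the bone, a loose one moves measurably against it.

The catch is that the applied moment also bends the tibia itself. A rigid
registration of the *whole* tibia onto a deformed version of itself settles
on a compromise pose, and that registration mismatch shows up as spurious
implant displacement. `ctmotion` implements the full measurement pipeline
*and* the comparison that quantifies this effect: implant displacement
evaluated against the whole tibia (deformation-inflated) versus against only
the proximal 20% of the tibia (deformation-reduced), plus the
proximal-vs-distal displacement of the tibia itself, which is a direct
measure of the bone's deformation.

## The pipeline

For one valgus/varus pair, `analyze_pair()` runs:

1. **Segmentation** (`region_grow`, `levelset_refine`): threshold-connected
   region growing from a seed voxel (empirical thresholds, about 3500 for
   the metal implant and 1600 for the cortical bone in CT-like intensity
   units), refined by a Laplacian level set that pulls the boundary onto
   image-Laplacian zero crossings (intensity edges) under mean-curvature
   regularisation.
2. **Meshing** (`extract_mesh`): iso-surfacing of the binary mask at level
   0.5 on a tetrahedral decomposition of each voxel cell. The Kuhn 6-tet
   decomposition tiles the grid consistently, so shared edge vertices weld
   into a watertight surface with none of the ambiguous-case cracks of the
   classic cube-table formulation. Normals are area-weighted face normals,
   oriented outward.
3. **Double contour** (`build_double_contour`): the gray-level image is
   sampled at +0.3 mm and -0.3 mm along each vertex normal; the two offset
   point sets with their stored reference gray values are the registration
   feature. The +-0.3 mm straddle places samples on both flanks of the
   cortical edge gradient, which is what gives the correlation metric its
   sub-voxel sensitivity.
4. **Clipping** (`clip_segments`): the tibia's long axis is its principal
   vertex axis; length runs from the implant-plateau level to the most
   distal vertex; the proximal and distal segments are the top and bottom
   20% of that length, cut by planes perpendicular to the axis.
5. **Registration** (`register`): Nelder-Mead simplex maximisation of the
   Pearson correlation between the stored contour grays and the target
   image sampled at the transformed contour points, over the 6-parameter
   rigid space (tx, ty, tz, phix, phiy, phiz; Euler sequence y, x, z). Each
   object (implant, whole tibia, proximal segment, distal segment) is
   registered independently from the segmentation image into the second
   image, giving its absolute displacement matrix.
6. **Kinematics** (`relative_displacement`, `build_local_cs`, `to_local`,
   `decompose`): the relative displacement of object i with respect to
   object j is `M(i,j) = Mj^-1 Mi`; it is invariant to any common rigid
   motion of the specimen, which is why arbitrary repositioning between
   scans is harmless. Results are expressed in an implant-anchored local
   coordinate system and decomposed into three translations, three
   rotations, and their root-sum-square magnitudes, plus mTRE (mean
   per-point displacement) and MTPM (maximum per-point displacement) for
   the implant.

### The automatic implant coordinate system

`build_local_cs()` casts a regular axial grid of rays down onto the implant
mesh; the first intersections sample the plateau surface. The origin is the
centroid of these points. The inertia tensor of the point set gives the
axes: for a plate-like lamina the largest-eigenvalue eigenvector is the
plateau normal (local z, oriented proximally), the smallest-eigenvalue
eigenvector is the long in-plane axis (medial-lateral, local x, signed
toward the lateral side by the `side` argument, since laterality cannot be
inferred from geometry alone), and y = z x x points posterior-anterior.
Displacements are reported about the plateau centroid; translations are
therefore origin-dependent (MTPM is the upper envelope over origin
choices), while rotations are origin-free.

### Euler convention

The rotation sequence is y, then x, then z about the fixed axes:
`R = Rz(phiz) Rx(phix) Ry(phiy)`. The decomposition reads `phix` from
`R[3,2]`, is exact away from `|phix| = 90` degrees, and flags gimbal
proximity (absorbing `phiy` by convention). The convention is isolated in
`params_to_matrix()` / `matrix_to_params()` so it is swappable; whether the
sequence should be read as intrinsic rather than fixed-axis is genuinely
open, but any consistent choice leaves all magnitudes and invariants
unchanged and only relabels the decomposed components at the sub-degree
displacements measured here.

## The digital phantom

Real valgus/varus CT datasets of implanted cadaver legs are not publicly
available, so validation runs on a synthetic tibia-plus-implant phantom
(`phantom_spec`, `build_geometry`, `voxelize`) with exactly known ground
truth. Its features, and why they are there:

- **Tubular bone, bright cortex (2900 units) over darker trabecular
  interior (300), flared proximal metaphysis.** The canonical empirical
  thresholds (1600 cortex, 3500 implant) then fall at the blurred edge
  midpoints, so threshold masks localise the true surfaces, as an
  empirically tuned threshold does on a real scanner.
- **Tri-lobed (roughly triangular) shaft cross-section.** A perfect surface
  of revolution would leave rotation about the bone axis invisible to any
  intensity metric; a real tibia is triangular. Amplitude 12% of the local
  radius.
- **Implant = elliptical plateau (ML halfwidth > AP halfwidth, so the
  inertia axes are unambiguous) with a posterior flat cut, plus a short
  metaphyseal stem with a medial-lateral keel plate.** The posterior cut
  and keel mirror real tibial tray design and are what makes implant roll
  well-determined; the stem ends inside the flared metaphysis so that its
  blur halo stays clear of the inner cortical wall.
- **Rendering:** each voxel takes its class intensity; boundary voxels are
  supersampled 5x5x5 for partial-volume realism; a Gaussian point-spread
  blur of one voxel sigma emulates the reconstruction kernel and keeps the
  rendering band-limited at the sampling resolution (without it the
  aliased class boundaries displace the correlation optimum); Gaussian
  noise is added last. A fixed seed gives bit-identical volumes.
- **Bending** (`apply_bending`): rotation about a y-parallel (coronal
  bending) axis at the top of the distal segment. The field has three
  zones: the distal 20% is unmoved, the angle ramps linearly over the
  mid-shaft, and the proximal 20% - with the implant riding on it - moves
  by the exact rigid end rotation. Keeping both end segments rigid makes
  the proximal-vs-distal and implant-vs-proximal ground-truth matrices
  exact by construction; the true spatial distribution of deformation in a
  loaded tibia is not known beyond being concentrated proximally, and the
  linear ramp is one admissible choice. Valgus uses +theta and varus -theta, so
  the net relative bend between the states is 2 theta; bends above 10
  degrees are rejected as outside the small-deformation regime.
- **Loose implants** are an extra rigid transform of the implant relative
  to the proximal bone in the varus state; **repositioning** between scans
  is an arbitrary global rigid pose per state (repeat scans default to
  uniform jitter of +-20 mm and +-10 degrees, a generous envelope for
  manual repositioning inside a scanner bore).

What the phantom does *not* emulate: metal streak artefacts (beam
hardening, photon starvation), spatially varying noise, anatomy beyond the
tibia (fibula, femur, soft tissue), inter-subject shape variation, and any
actual mechanics of the 20 Nm load (bending is imposed geometrically).
Passing phantom experiments therefore demonstrates the correctness and
precision of the *measurement chain*, not robustness to artefact-laden
clinical scans.

## Experiments

- `methodological_error()` re-implements the repeat-scan experiment: each
  of n unloaded scans serves in turn as segmentation source and its objects
  are registered to the other n-1 scans, giving n(n-1) apparent relative
  displacements per object pair (90 for n = 10) whose ground truth is
  exactly zero. Mean = accuracy, SD = precision, and the maximum absolute
  apparent displacement is kept as a conservative benchmark.
- `deformation_experiment()` recovers the imposed bend from the
  proximal-vs-distal displacement.
- `fixed_vs_loose_comparison()` contrasts fixed and loose groups per metric
  (translation and rotation magnitude, mTRE, MTPM) and per reference
  (whole vs proximal): group summaries, overlap counts (loose cases not
  exceeding the fixed maximum), a paired Wilcoxon signed-rank test of
  whole-vs-proximal, and a Mann-Whitney U test against the methodological
  error. Both tests use exact small-sample p-values where tie-free, no
  normality is assumed, no multiplicity correction is applied, and the
  working significance level is 0.05.

## Numerical choices

- **Optimizer**: Nelder-Mead with initial steps of 1 mm / 1 degree (angles
  in degrees keep the six parameters comparably scaled), rotation
  parameterised about the contour centroid to reduce translation-rotation
  coupling (the reported matrix is centre-independent), a relative metric
  tolerance of 1e-10 with a budget of 2000 evaluations per start, and a
  second-stage polish that restarts the simplex at a tenth of the step
  size. Seeded random restarts (up to 3, +-1 mm / 1 degree) trigger only
  while the best correlation is below 0.9: a converged registration of a
  rigid object sits far above that, a mildly deformed whole tibia near
  0.95, and a capture failure far below.
- **Initialisation**: registration starts from `coarse_prealign()`, which
  matches the centroids and long principal axes of the supra-threshold
  voxel clouds of the two scans (identical cloud definitions on both
  sides) and resolves the residual roll about the long axis by scoring a
  +-20 degree candidate fan with the metric. This covers the +-20 mm /
  +-10 degree repositioning regime comfortably.
- **Out-of-volume samples** are flagged invalid and excluded from the
  correlation rather than clamped (clamping would bias boundary poses);
  inside the optimizer the metric is additionally scaled down when fewer
  than half the points remain valid, so the simplex backs away from poses
  that push the contour out of the image.
- **Level set**: evolution runs on the mask bounding box (the narrow band
  cannot leave it), with the image pre-smoothed by one binomial pass, time
  step 0.2 voxel, curvature weight 0.2, and 10 iterations in the pipeline
  default; a Dice sanity bound against the input guards against leakage.
- **Desk scale**: the validation experiments run at 0.9 mm voxels
  (128 x 128 x 320), half the 0.45 mm acquisition resolution the phantom
  spec defaults to; unit tests use 1.5 mm renderings of the same geometry.
  Registration accuracy statements in the test-suite are tied to these
  scales.

## Accuracy: absolute versus relative

Two different error scales appear in the tests, and the distinction is the
method's own. The *absolute* pose recovery of a small object like the
implant is limited by rendering consistency between two discretised views
(about 0.15 mm at 0.9 mm voxels), while the large, feature-rich tibia
recovers to about a hundredth of a voxel. The *relative* displacement of
two objects registered into the same target - the quantity the method
actually reports - cancels the shared part of those errors and lands near
0.01 mm / 0.02 degrees in the repeat-scan experiment. This is why the methodological error of such measurements is properly
characterised via repeat-scan relative displacements rather than absolute
poses.

## Known limitations

- The proximal-segment reference trades deformation error against noise:
  smaller objects register less precisely, so precision with the proximal
  tibia is expected to be somewhat worse than with the whole tibia even as
  accuracy improves. The segment length that optimises the trade-off is an
  open question; `clip_segments(fraction = ...)` exposes it.
- "Clipping at 20%" can be read as end segments exactly 20% long or as
  everything beyond the 20% cut; the package uses 20%-long end segments,
  adjustable via `fraction`.
- An optional exclusion margin for artefact-prone bone next to the plateau
  is not implemented since the phantom has no artefacts; on clinical data
  the cortex threshold and the level-set weights would need retuning.
- MTPM and mTRE depend on mesh vertex density; marching-cubes vertices are
  near-uniform on the surface, which mitigates but does not remove this.
- `mesh_subset` clipping keeps whole triangles, so segment boundaries are
  ragged at the one-triangle scale; cut planes are exact for vertices.
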