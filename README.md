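# ctmotion

CT-based measurement of load-induced tibial implant displacement after
total knee arthroplasty.

Loosening of the tibial component is the leading reason for knee revision
surgery, and static imaging detects it poorly. A load-based protocol scans
the leg twice — under a valgus and under a varus bending moment — and
measures how far the implant moved relative to the tibia between the two
states. `ctmotion` implements that measurement chain in R: segmentation of
implant and cortical bone (threshold-connected region growing + Laplacian
level-set refinement), marching-cubes surface meshing, a double-contour
gray-value feature (samples at ±0.3 mm along the surface normals), rigid
registration by Nelder–Mead maximisation of the gray-value correlation in
the 6-parameter space (tx, ty, tz, φx, φy, φz; Euler sequence y, x, z), and
relative-displacement kinematics

    M(i,j) = Mj⁻¹ Mi                (relative displacement, global CS)
    M_local = M_CS⁻¹ M(i,j) M_CS    (expressed in the implant local CS)

with the local coordinate system built automatically from the inertia
principal axes of the implant plateau (z distoproximal, x lateral,
y posterior–anterior, origin at the plateau centroid). Displacements are
decomposed into three translations and three rotations with root-sum-square
magnitudes, plus the clinical scalar summaries mTRE (mean target
registration error) and MTPM (maximum total point motion).

The scientific point of the package is the deformation comparison: the
applied moment bends the tibia, so implant displacement measured against
the **whole** tibia is inflated by the registration mismatch of a deformed
bone, while measuring against only the **proximal 20%** of the tibia
largely removes the effect. The package quantifies both, plus the
proximal-vs-distal tibia displacement that measures the deformation itself.

Real loaded-knee CT datasets are not publicly available, so the package
ships a first-class digital phantom: a tri-lobed tubular bone with cortical
shell and flared metaphysis carrying a keeled, posterior-cut tibial
component, rendered with partial-volume supersampling, a scanner-like
point-spread blur and optional noise, bent by an exactly known coronal
rotation field, with exact ground-truth displacement matrices for every
object pair. See `vignette("ctmotion-methods")` for the model, parameters
and limitations.

## Worked example

Simulate one valgus/varus pair with a net relative bend of 0.64° and a
well-fixed implant, then run the full measurement (coarse 1.5 mm rendering;
runs in under a minute):

```r
library(ctmotion)
spec <- phantom_spec(voxel_spacing = 1.5, fov_mm = c(114, 114, 288))
pair <- generate_load_pair(
  spec, bend_angle = 0.32,   # per-state bend; net relative bend 0.64 deg
  global_poses = list(valgus = params_to_matrix(c(3, -2, 5, 2, -3, 4)),
                      varus  = params_to_matrix(c(-4, 1, -6, -2, 5, -3))))
analysis <- analyze_pair(pair$valgus, pair$varus,
  experiment_config(registration = registration_control(seed = 1)))
print(analysis$results[["prox-vs-distal"]])
print(analysis$results[["implant-vs-whole"]])
print(analysis$results[["implant-vs-prox"]])
```

```
<displacement_result> prox-vs-distal
  t = (-1.700, 0.213, -0.060) mm  |t| = 1.715 mm
  phi = (-0.071, -0.656, 0.007) deg  |phi| = 0.660 deg
<displacement_result> implant-vs-whole
  t = (-0.136, -0.009, 0.040) mm  |t| = 0.142 mm
  phi = (0.030, -0.061, -0.311) deg  |phi| = 0.319 deg
  mTRE = 0.142 mm, MTPM = 0.189 mm
<displacement_result> implant-vs-prox
  t = (0.013, -0.007, 0.003) mm  |t| = 0.015 mm
  phi = (0.018, -0.021, -0.371) deg  |phi| = 0.372 deg
  mTRE = 0.042 mm, MTPM = 0.087 mm
```

Reading the output: the proximal-vs-distal displacement recovers the
imposed deformation (0.660° measured vs 0.64° imposed, dominated by the −x
translation and −y rotation of coronal bending). The implant is fixed, yet
against the whole tibia it *appears* to translate 0.142 mm — that is the
deformation-inflation artifact; against the proximal tibia the apparent
translation collapses to 0.015 mm. (At this coarse demonstration
resolution the sub-voxel keel leaves implant roll, φz, noisier than the
translations; the half-resolution experiments in the test-suite run at
0.9 mm.)

The repeat-scan error experiment and the fixed-vs-loose group comparison
follow the same pattern:

```r
scans <- generate_repeat_scans(spec, n = 4, seed = 11)
methodological_error(scans$volumes)        # accuracy/precision, zero truth
fixed_vs_loose_comparison(fixed, loose)    # overlap counts + rank tests
```

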