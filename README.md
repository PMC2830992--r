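# stackcarve

Build **generic (population-averaged) 3D anatomical models** from grayscale
voxel image stacks.

Morphometric studies often need a single "average" 3D model of an anatomical
structure for a group of subjects — e.g. the mean shape of a bone across a
scanned cohort — to quantify shape differences between groups (sex, strain,
treatment). Producing one from raw μ-CT or MRI stacks traditionally requires
slice-by-slice manual segmentation of every subject. `stackcarve` implements
the alternative workflow of *virtual dissection plus iterative intensity-based
registration*:

1. **Cut** each subject's voxel volume with geometric instruments — plane,
   sphere, box, or a user-drawn curve — recorded in a replayable text script,
   so only the sub-model of interest keeps its intensities (everything else is
   set to 0).
2. **Register** all subject stacks to a reference with a three-stage protocol:
   versor **rigid** → **affine** → cubic **B-spline** free-form deformation,
   each stage minimizing the mean-square intensity metric
   `MSE(T) = (1/N) Σᵢ (F(xᵢ) − M(T(xᵢ)))²`
   with trilinear interpolation of the moving image `M` at the mapped
   fixed-grid points `T(xᵢ)`.
3. **Average** the registered, binarized stacks voxel-wise and binarize the
   average at the **global median** of its nonzero intensities; the binarized
   average becomes the refined reference for the next, more flexible stage.
4. **Extract** the generic surface with marching cubes at that same global
   median isovalue, yielding both a volumetric and a triangle-mesh generic
   model.

The transform families use center-based conventions: rigid
`X' = R(V)(X − C) + C + T` with `V` a unit quaternion (versor); affine
`X' = A(X − C) + C + T` with a full 3×3 matrix `A` (12 parameters); B-spline
`X' = X + D(X)` with `D` the tensor-product cubic B-spline interpolation of
displacement vectors on a coarse control lattice. All transforms can be saved
as JSON and the dense deformation field exported as a vector image for
downstream shape-variation analyses.

Validation statistics from the workflow's literature are included:

* **sharpness ratio** — fraction of nonzero voxels of an averaged stack that
  are exactly 255 (all subjects agree); misalignment blurs the average, so the
  ratio rises from the rigid to the deformable stage;
* **Dice index** — `2|A∩B|/(|A|+|B|)` between binary models, used to show the
  generic model barely depends on which subject seeded the protocol;
* **voxel RMSE** — used to verify the averaged model is a *centroid*: every
  subject is closer (in RMSE) to the averaged model than to any other subject.

Because real μ-CT cohorts are rarely shareable, the package ships a synthetic
population generator (`population_spec()`, `generate_population()`): a
mandible-like compound-ellipsoid base shape warped per subject by sampled
rigid + affine + smooth B-spline perturbations with stored ground truth, so
every pipeline stage is testable against known answers.

## Worked example

Build the generic model of a synthetic 8-subject cohort (64³ voxels,
rotations ≤ 10°, translations ≤ 3 voxels, anisotropic scaling 0.95–1.05,
smooth deformations ≤ 2 voxels):

```r
library(stackcarve)

pop <- generate_population(population_spec(n_subjects = 8, seed = 11))
res <- iterative_average(pop$subjects, averaging_protocol(reference_index = 1))
print(res)
#> <averaging_result>
#>   reference subject: 1
#>   stage 1 (rigid): sharpness ratio 0.6989
#>   stage 2 (affine): sharpness ratio 0.8072
#>   stage 3 (bspline): sharpness ratio 0.8551
#>   generic threshold: 255

write_mesh(res$generic_mesh, "generic.ply")
```

The sharpness ratio climbing from 0.70 (rigid) through 0.81 (affine) to 0.86
(B-spline) shows each protocol stage removing residual misalignment: after
the deformable stage 86% of the voxels touched by any subject are unanimous.
The generic threshold is the global median of the final averaged stack, used
both to binarize the generic volume and as the marching-cubes isovalue for
`res$generic_mesh`.

Cutting is scripted rather than interactive:

```r
script <- parse_cut_script("
  PLANE 0 0 40 0 0 1        # drop everything above z = 40
  SPHERE 12 12 12 6         # carve out a ball
")
sub <- apply_cuts(read_stack("subject1.nrrd"), script)
```

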