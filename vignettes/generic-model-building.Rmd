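---
title: "Building generic anatomical models by virtual cutting and iterative registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building generic anatomical models by virtual cutting and iterative registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

A *generic model* is a single 3D representation of the mean shape of an
anatomical structure across a population of scanned subjects. `stackcarve`
builds one from grayscale voxel stacks in four steps: virtual dissection
(geometric cutting of each subject's volume down to the sub-model of
interest), iterative intensity-based registration of all sub-model stacks to
a progressively refined reference, voxel-wise intensity averaging, and
marching-cubes surface extraction of the averaged stack.

The method assumes the structure of interest has an approximately
**homogeneous intensity**: after cutting, each stack carries a single
foreground intensity (255) against a 0 background. This is what justifies
driving all three registration stages with the plain mean-square metric

$$\mathrm{MSE}(T) \;=\; \frac{1}{N}\sum_{i \in \Omega}
  \bigl(F(x_i) - M(T(x_i))\bigr)^2,$$

where $F$ is the fixed (reference) stack, $M$ the moving subject stack
interpolated trilinearly, and $\Omega$ the set of fixed-grid voxel centers
whose mapped position $T(x_i)$ falls inside the moving domain. Multi-modal
metrics (mutual information and relatives) are deliberately out of scope.

## Transform families

All transforms act on physical coordinates (spacing and origin applied),
with center-based conventions:

* **rigid (versor)** — $X' = R(V)(X - C) + C + T$, six parameters (a unit
  quaternion's three free components and a translation). The rotation center
  $C$ is the fixed image's intensity-weighted center of mass and is not
  optimized.
* **affine** — $X' = A(X - C) + C + T$, twelve parameters; initialized from
  the rigid stage ($A \leftarrow R$).
* **B-spline free-form deformation** — $X' = X + D(X)$, with $D$ the
  tensor-product *cubic* B-spline interpolant of displacement vectors on a
  coarse control lattice covering the fixed domain with a one-cell margin.
  When the stage is initialized from a previous linear stage $T_0$, the total
  mapping is $T(x) = T_0(x + D(x))$; the deformation refines alignment in
  fixed space before the linear map carries the point into the subject.

The *pull-back* (resampling) convention is used throughout: the optimized
transform maps **fixed-space points into moving space**, and the moving
stack is interpolated there. This is the standard convention of the
registration toolkits this protocol family comes from, stated explicitly
here because it fixes the direction of every ground-truth comparison in the
tests (a recovered transform approximates the *inverse* of the perturbation
used to synthesize the moving image).

## The iterative protocol

1. One subject (chosen by index, or at random under a seed) is binarized and
   becomes the stage-1 reference. Every subject is rigidly registered to it,
   resampled onto the reference grid, binarized at 127.5 and averaged.
2. The average is binarized at the **global median of its nonzero
   intensities** and becomes the refined reference; the affine stage repeats
   the procedure with each subject initialized from its rigid transform.
3. The deformable stage repeats it again (optionally several times).
4. The generic volume is the final average binarized at its global median,
   and the generic mesh is the marching-cubes isosurface of the final
   average at that threshold.

Two details are deliberate choices where the workflow's description is open:

* **Reference refinement**: later stages register to the *binarized averaged
  stack* of the previous stage, not to the original seed subject — the
  reference is iteratively refined.
* **One interpolation per stage**: at stage $k$ each subject is resampled
  from its *original* stack through the composed mapping, rather than
  resampling the already-resampled stack again, which would accumulate
  interpolation blur in the very quantity (average sharpness) the protocol
  is judged by.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `registration_options(pyramid_levels)` | 2 | ×2 downsampled level first; enlarges the capture range of gradient descent on near-binary images |
| `max_iterations` | 200/level | regular-step gradient descent cap (rigid/affine) |
| `initial_step`, `min_step` | 2, 1e-4 | step lengths in scaled units (≈ voxels of boundary motion); the step halves when the descent direction reverses or a trial move fails, and the run stops below `min_step` |
| parameter scaling | half-diagonal | rotation (radians) and affine matrix entries are scaled by the fixed image's half-diagonal so one scaled unit moves the volume boundary by about one voxel — the critical, usually unstated, choice that makes one step length meaningful for all parameters |
| `register_bspline(grid_spacing)` | extent/4, ≥ 4 voxels | control-point spacing of the deformation lattice |
| `bspline_max_iterations`, `bspline_pgtol` | 80, 1e-5 | L-BFGS-B budget for the deformable stage, using the analytic metric gradient with respect to the lattice coefficients |
| `averaging_protocol(bspline_repeats)` | 1 | number of deformable refinement passes |
| binarization of registered stacks | 127.5 | inputs are binary, so only interpolation produces intermediate values; the midpoint is the natural cut |

**Why extent/4 for the control lattice.** With near-binary volumes the
metric only constrains a one-voxel shell at the model boundary; the interior
is flat. A lattice much finer than the true shape variation can contort the
interior while fitting the shell ("overfitting" the boundary): in recovery
experiments with a known 5³-lattice warp of 2-voxel amplitude, lattices at
one half to one quarter of the image extent recover the warp to a 0.23–0.25
voxel mean foreground residual, while an extent/8 lattice leaves a 4-voxel
interior residual despite a lower metric. The coarse default is therefore a
regularization choice, not a cost compromise.

# Numerical choices and conventions

* **Global median threshold**: the median of the *nonzero* intensities of an
  averaged stack. Including the background (overwhelmingly 0 in a cut
  anatomical stack) would drag the median to 0 and degenerate binarization.
  For an even count the lower middle element is returned, so the threshold
  is always an attained intensity; binarization is inclusive (`>=` → 255).
* **Voxel geometry**: arrays are indexed `[z, y, x]`; physical vectors are
  `(x, y, z)`; voxel `(i, j, k)` sits at `origin + (i·sx, j·sy, k·sz)`;
  indices are 0-based in all formulas. Cut scripts store physical
  coordinates, so they survive resampling.
* **Cut membership** is decided at the voxel center, with the plane boundary
  (distance exactly 0) counted as removed; flipping a plane's normal
  complements the mask except on the boundary set.
* **Curve cuts** formalize screen-space drawing: the dots are interpolated
  by a natural cubic spline in the projection plane orthogonal to an
  explicit `view_direction`, polygonized at 256 segments, and extruded along
  the view axis. Closed curves remove their interior (even–odd rule); open
  curves are extended beyond the end dots along the end tangents and remove
  the *left* side of the directed curve (sign of the 2D cross product of the
  nearest segment's tangent with the point offset), so reversing the dot
  order selects the other side — matching the counterclockwise/clockwise
  behavior of the interactive tool the format emulates. Self-intersecting
  open curves are rejected rather than guessed at.
* **Isosurface extraction** links the marching-cubes edge crossings of each
  cell into closed loops by pairing crossings on each face, resolving
  four-crossing faces with the asymptotic decider (the sign of the bilinear
  saddle value, identical from both sides of a face), so the mesh is
  watertight and topology-consistent; loops are fan-triangulated and
  oriented against the local trilinear gradient. Vertices coincide with
  classic marching-cubes edge intersections.
* **Degenerate isovalue**: when the cohort aligns so well that the global
  median equals the stack maximum (every above-median voxel unanimous), the
  averaged stack has no strictly interior isovalue at the threshold; the
  generic mesh then falls back to the 127.5 isosurface of the binarized
  generic volume.
* **The "averaged model" in RMSE comparisons** is the real-valued averaged
  stack. Binarizing at a median of 255 erodes the model to the unanimity
  region, which biases RMSE upward against every subject; the voxel-wise
  average is the object whose centroid property ("every subject is closer to
  the average than to any other subject") is both meaningful and, in the
  synthetic experiments, satisfied for all subjects. Dice-based comparisons
  always use binarized volumes.
* **Determinism**: registration has no stochastic component (all fixed
  voxels are sampled, no random restarts), so pipeline outputs are a pure
  function of inputs, options and the seed used for synthesis or a random
  reference choice.

# The synthetic cohort: what it emulates, and what it does not

`generate_population()` emulates a small-rodent morphometrics cohort: 8
subjects per group on a 64³ unit-spacing grid. The base shape is a binary
compound ellipsoid (an elongated body plus three process-like lobes, a
single 6-connected component filling a few percent of the grid, echoing a
mandible sub-model). Each subject is the base seen through a sampled
perturbation: rotation up to 10°, translation up to 3 voxels, anisotropic
scaling 0.95–1.05 with mild (±0.02) shear, and a smooth deformation sampled
as uniform random 3-vectors (≤ 2 voxels) on a 5³ control lattice interpolated
with the same cubic B-spline basis the deformable registration optimizes —
a deliberate choice that makes ground-truth recovery well-posed. Optional
salt noise flips background voxels to 255 at a given rate (default 0).

What passing tests on this cohort *do* show: the cutting, registration,
averaging and metric machinery is internally correct (brute-force oracles),
recovers known transforms to sub-voxel accuracy, and reproduces the
qualitative signatures of the workflow — the monotone sharpness pattern
across stages, near-invariance of the generic model to the reference choice
after neutral alignment, and the centroid property.

A caveat on the reference-invariance Dice at desk scale: the Dice cost of a
fixed sub-voxel boundary discrepancy grows with the surface-to-volume ratio
of the model, i.e. inversely with its linear size. On the 64³ cohort the two
generics agree to about 0.2 voxel-layers of symmetric difference, which
reads as Dice ≈ 0.95 for a structure ~40 voxels long; the same physical
agreement on a full-resolution anatomical stack (structures hundreds of
voxels long) reads as Dice > 0.97. The test suite asserts the
full-resolution figure and therefore flags this scale effect rather than
hiding it.

What they do *not* show: performance on real μ-CT data, whose intensity
profile is not binary (partial-volume effects, beam hardening, multi-tissue
contrast), whose anatomical variation is not drawn from the B-spline family
being optimized, and whose grids are two orders of magnitude larger. The
64³ / 8-subject scale used in the tests and the acceptance script is the
package's chosen desk-scale study size; the algorithms themselves are
size-agnostic.

# Known limitations

* Mean-squares only: structures without an approximately homogeneous
  intensity (e.g. multi-region organs) would need multi-label handling or a
  different metric, both out of scope.
* The deformable stage offers no diffeomorphic guarantee; amplitude limits
  in the synthetic generator (≤ grid/8) are what keep sampled warps from
  folding.
* No interactive cutting or rendering: cut scripts replay a dissection, they
  do not help author one.
* Mesh output is raw marching cubes — no smoothing, decimation or
  quadrangular remeshing.
* The surface-area fidelity of marching cubes holds for smoothly sampled
  (partial-volume) boundaries; on strictly binary data any marching-cubes
  variant overestimates the area of curved surfaces by several percent
  (staircase effect), although enclosed volume stays within a fraction of a
  percent of the voxel count.
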