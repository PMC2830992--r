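#' Synthetic phantom population specification
#'
#' Describes a cohort of mandible-like phantom subjects with known ground
#' truth, standing in for a scanned population. Each subject is the base
#' shape seen through a sampled rigid + affine + smooth B-spline
#' perturbation. The defaults mirror a small-rodent morphometrics cohort:
#' 8 subjects per group on a 64^3 unit-spacing grid, rotations up to 10
#' degrees, translations up to 3 voxels, anisotropic scaling 0.95--1.05,
#' mild shear, and smooth deformations up to 2 voxels sampled on a 5^3
#' control lattice.
#'
#' @param n_subjects number of subjects.
#' @param shape grid dim `(nz, ny, nx)`.
#' @param spacing voxel spacing `(x, y, z)`.
#' @param rotation_deg max rotation angle (degrees).
#' @param translation_vox max |translation| per axis (voxels).
#' @param scale_range anisotropic per-axis scale factor range.
#' @param shear_max max off-diagonal affine entry.
#' @param deform_amp_vox max smooth-deformation control coefficient
#'   (voxels); rejected if above 1/8 of the grid (would fold space).
#' @param deform_grid control points per axis for the deformation field.
#' @param noise_rate salt-noise probability per background voxel.
#' @param seed integer; fixes the population bit-exactly.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_subjects = 8L, shape = c(64L, 64L, 64L),
                            spacing = c(1, 1, 1), rotation_deg = 10,
                            translation_vox = 3, scale_range = c(0.95, 1.05),
                            shear_max = 0.02, deform_amp_vox = 2,
                            deform_grid = 5L, noise_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, rotation_deg >= 0, translation_vox >= 0,
            shear_max >= 0, deform_amp_vox >= 0, noise_rate >= 0)
  if (deform_amp_vox > min(shape) / 8)
    stop("deformation amplitude above grid/8 would fold space")
  structure(list(n_subjects = as.integer(n_subjects),
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 rotation_deg = rotation_deg,
                 translation_vox = translation_vox,
                 scale_range = scale_range, shear_max = shear_max,
                 deform_amp_vox = deform_amp_vox,
                 deform_grid = as.integer(deform_grid),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "population_spec")
}

#' Base anatomical phantom shape
#'
#' A binary, single-component, elongated compound-ellipsoid blob (a main
#' ellipsoid body plus three process-like lobes), emulating a mandible-like
#' bone sub-model. Fills roughly 2--30% of the grid, leaving enough margin
#' for the perturbations of [generate_population()].
#'
#' @param spec a [population_spec()].
#' @return A binary byte [stack_volume()].
#' @export
make_base_shape <- function(spec = population_spec()) {
  g <- voxel_grid(spec$shape, spec$spacing)
  pts <- voxel_centers(g)
  ext <- (spec$shape[3:1] - 1) * spec$spacing # (x, y, z)
  ctr <- g$origin + ext / 2
  u <- sweep(pts, 2, ctr, "-")
  # main elongated body
  ax <- ext * c(0.30, 0.14, 0.11)
  f <- rowSums(sweep(u, 2, ax, "/")^2)
  inside <- f <= 1
  # three lobes: two "processes" near one end, one at the other
  lobes <- list(list(c(0.26, 0.06, 0.08), c(0.10, 0.07, 0.06)),
                list(c(0.26, -0.05, -0.06), c(0.10, 0.06, 0.07)),
                list(c(-0.30, 0.02, 0.02), c(0.09, 0.08, 0.06)))
  for (lb in lobes) {
    off <- lb[[1]] * ext
    axl <- lb[[2]] * ext
    fl <- rowSums(sweep(sweep(u, 2, off, "-"), 2, axl, "/")^2)
    inside <- inside | (fl <= 1)
  }
  arr <- array(ifelse(inside, 255, 0), dim = spec$shape)
  stack_volume(arr, spec$spacing, g$origin, role = "byte")
}

#' Count 6-connected foreground components
#'
#' @param v a binary [stack_volume()].
#' @export
connected_components <- function(v) {
  stopifnot(is_stack_volume(v))
  lab <- cpp_label6(v$data > 0, dim(v$data))
  max(lab)
}

sample_subject_transform <- function(spec, grid) {
  ext <- (spec$shape[3:1] - 1) * spec$spacing
  ctr <- grid$origin + ext / 2
  # rigid: random axis, angle uniform in [0, max]
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, spec$rotation_deg) * pi / 180
  tr <- stats::runif(3, -spec$translation_vox, spec$translation_vox) *
    spec$spacing
  rigid <- rigid_transform(rotation_vector_to_versor(axis * ang),
                           translation = tr, center = ctr)
  # affine: anisotropic scale + shear about the grid center
  A <- diag(stats::runif(3, spec$scale_range[1], spec$scale_range[2]))
  A[upper.tri(A) | lower.tri(A)] <-
    stats::runif(6, -spec$shear_max, spec$shear_max)
  affine <- affine_transform(A, translation = c(0, 0, 0), center = ctr)
  # smooth deformation: coarse control lattice of random displacements
  ng <- spec$deform_grid
  coef <- array(stats::runif(ng^3 * 3, -spec$deform_amp_vox,
                             spec$deform_amp_vox) * rep(spec$spacing,
                                                        each = ng^3),
                dim = c(ng, ng, ng, 3))
  csp <- ext / (ng - 3) # interior lattice covers the domain with margin
  bsp <- bspline_transform(coef, grid_origin = grid$origin - csp,
                           grid_spacing = csp)
  list(rigid = rigid, affine = affine, bspline = bsp)
}

#' Generate a synthetic phantom population
#'
#' Each subject is the base shape resampled through its ground-truth
#' mapping `T = rigid o affine o (x + D(x))` (subject space to base
#' space), binarized at 127.5, with optional salt noise. All randomness is
#' driven by `spec$seed`, so a spec reproduces its population bit-exactly.
#'
#' @param spec a [population_spec()].
#' @return list with `base` (the base volume), `subjects` (list of binary
#'   volumes) and `ground_truth` (per-subject rigid/affine/bspline
#'   components plus the composed transform).
#' @export
generate_population <- function(spec = population_spec()) {
  base <- make_base_shape(spec)
  g <- grid_of(base)
  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  gts <- vector("list", spec$n_subjects)
  zero_mag <- spec$rotation_deg == 0 && spec$translation_vox == 0 &&
    all(spec$scale_range == 1) && spec$shear_max == 0 &&
    spec$deform_amp_vox == 0
  for (i in seq_len(spec$n_subjects)) {
    gt <- sample_subject_transform(spec, g)
    composed <- compose_transform_keep(gt$rigid,
                                       compose_transform_keep(gt$affine,
                                                              gt$bspline))
    vol <- if (zero_mag) base else
      binarize(resample(base, composed, g), 127.5)
    if (spec$noise_rate > 0) {
      bg <- which(vol$data == 0)
      flip <- bg[stats::runif(length(bg)) < spec$noise_rate]
      d <- vol$data
      d[flip] <- 255
      vol <- stack_volume(d, vol$spacing, vol$origin, role = "byte")
    }
    gt$composed <- composed
    subjects[[i]] <- vol
    gts[[i]] <- gt
  }
  names(subjects) <- names(gts) <- sprintf("S%d", seq_len(spec$n_subjects))
  list(base = base, subjects = subjects, ground_truth = gts, spec = spec)
}

#' Write a population to disk as a pipeline-ready fixture
#'
#' NRRD volumes plus ground-truth transform JSON files.
#'
#' @param population result of [generate_population()].
#' @param dir output directory.
#' @export
write_fixture <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(population$base, file.path(dir, "base.nrrd"))
  for (nm in names(population$subjects)) {
    write_stack(population$subjects[[nm]],
                file.path(dir, paste0(nm, ".nrrd")))
    save_transform(population$ground_truth[[nm]]$composed,
                   file.path(dir, paste0(nm, "_truth.json")))
  }
  invisible(dir)
}

#' Anti-aliased solid sphere phantom
#'
#' A voxelized sphere whose intensity ramps linearly from 255 to 0 across
#' a one-voxel shell at the boundary (partial-volume weighting), the
#' natural voxelization for isosurface work: the 127.5 isosurface then
#' interpolates onto the true sphere rather than onto a staircase.
#'
#' @param radius sphere radius (physical units).
#' @param shape grid dim `(nz, ny, nx)`.
#' @param spacing voxel spacing.
#' @param binary if `TRUE`, threshold at 127.5 to get a strict binary ball.
#' @return A [stack_volume()].
#' @export
sphere_phantom <- function(radius = 10, shape = c(32L, 32L, 32L),
                           spacing = c(1, 1, 1), binary = FALSE) {
  g <- voxel_grid(shape, spacing)
  ext <- (shape[3:1] - 1) * spacing
  ctr <- g$origin + ext / 2
  pts <- voxel_centers(g)
  d <- sqrt(rowSums(sweep(pts, 2, ctr, "-")^2))
  vals <- 255 * pmin(pmax(radius - d + 0.5, 0), 1)
  v <- stack_volume(array(vals, dim = shape), spacing, g$origin, role = "real")
  if (binary) binarize(v, 127.5) else v
}
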