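#' Voxelwise intensity average of binary stacks
#'
#' Arithmetic mean of corresponding voxel intensities across registered
#' binary stacks; the result is kept real-valued (no rounding), so a voxel
#' where all subjects agree has mean exactly 255.
#'
#' @param stacks list of >= 2 binary [stack_volume()]s on one grid.
#' @return A real [stack_volume()].
#' @export
average_stacks <- function(stacks) {
  if (length(stacks) < 2) stop("need at least 2 stacks to average")
  g <- grid_of(stacks[[1]])
  acc <- array(0, dim = g$shape)
  for (s in stacks) {
    stopifnot(is_stack_volume(s))
    if (!same_grid(s, g)) stop("stacks are on different grids")
    acc <- acc + s$data
  }
  stack_volume(acc / length(stacks), g$spacing, g$origin, role = "real")
}

#' Averaging protocol description
#'
#' @param reference_index which subject seeds the protocol (stage-1
#'   reference); a seeded random choice, mirroring how a reference subject
#'   is typically drawn in practice, is available via
#'   `reference_index = "random"` plus a seed.
#' @param stages ordered subset of `c("rigid", "affine", "bspline")`;
#'   must start with `"rigid"`, and `"bspline"` may only follow
#'   `"affine"`.
#' @param bspline_repeats how many times the deformable stage runs
#'   (each repeat re-registers against the refreshed average).
#' @param opts registration options shared by all stages.
#' @return An `averaging_protocol` object.
#' @export
averaging_protocol <- function(reference_index = 1L,
                               stages = c("rigid", "affine", "bspline"),
                               bspline_repeats = 1L,
                               opts = registration_options()) {
  stages <- match.arg(stages, c("rigid", "affine", "bspline"),
                      several.ok = TRUE)
  if (stages[1] != "rigid") stop("protocol stages must begin with rigid")
  bs <- which(stages == "bspline")
  if (length(bs) > 0 && !any(stages[seq_len(bs[1] - 1)] == "affine"))
    stop("bspline stage requires a preceding affine stage")
  if (any(duplicated(stages)))
    stop("list each stage once; use `bspline_repeats` to repeat the deformable stage")
  structure(list(reference_index = reference_index, stages = stages,
                 bspline_repeats = as.integer(bspline_repeats), opts = opts),
            class = "averaging_protocol")
}

#' Run one registration stage of the averaging protocol
#'
#' Registers every subject stack to the reference (each initialized from
#' its previous-stage transform), resamples it from the *original* subject
#' stack through the composed mapping onto the reference grid (one
#' interpolation per stage, avoiding accumulated blur), binarizes at 127.5
#' and averages.
#'
#' @param stacks list of byte [stack_volume()]s (original subject stacks).
#' @param reference binary [stack_volume()] (current reference).
#' @param model `"rigid"`, `"affine"` or `"bspline"`.
#' @param inits optional list of per-subject initial transforms.
#' @param opts registration options.
#' @return list with `stacks` (resampled binarized), `results`
#'   (per-subject `registration_result`s), `average` (real volume).
#' @export
run_stage <- function(stacks, reference, model = c("rigid", "affine", "bspline"),
                      inits = NULL, opts = registration_options()) {
  model <- match.arg(model)
  results <- vector("list", length(stacks))
  resampled <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    init <- if (!is.null(inits)) inits[[i]] else NULL
    res <- switch(model,
                  rigid = register_rigid(reference, stacks[[i]],
                                         init = init, opts = opts),
                  affine = register_affine(reference, stacks[[i]],
                                           init = init, opts = opts),
                  bspline = register_bspline(reference, stacks[[i]],
                                             init = init, opts = opts))
    if (!res$converged)
      warning("subject ", i, " ", model,
              " registration did not converge; keeping best-found transform")
    results[[i]] <- res
    resampled[[i]] <- binarize(resample(stacks[[i]], res$transform,
                                        grid_of(reference)), 127.5)
  }
  list(stacks = resampled, results = results,
       average = average_stacks(resampled))
}

#' Iterative reference-refinement averaging
#'
#' The full generic-model construction: a chosen subject seeds the
#' protocol as the stage-1 reference; every subject is registered to it
#' (rigid), the registered binarized stacks are averaged, and the average
#' binarized at its global median becomes the refined reference for the
#' next, more flexible stage (affine, then B-spline, optionally repeated).
#' After the final stage the generic volume is the final average binarized
#' at its global median, and the generic mesh is the marching-cubes
#' isosurface of the final average at that same threshold.
#'
#' @param stacks list of >= 2 byte [stack_volume()]s (cut sub-model
#'   stacks).
#' @param protocol an [averaging_protocol()].
#' @param seed optional seed used only when
#'   `protocol$reference_index == "random"`.
#' @return An `averaging_result`: per-stage averages, sharpness ratios and
#'   transforms, plus `generic_volume`, `generic_mesh` and `threshold`.
#' @export
iterative_average <- function(stacks, protocol = averaging_protocol(),
                              seed = NULL) {
  if (length(stacks) < 2) stop("need at least 2 subject stacks")
  ref_idx <- protocol$reference_index
  if (identical(ref_idx, "random")) {
    if (!is.null(seed)) set.seed(seed)
    ref_idx <- sample.int(length(stacks), 1)
  }
  stopifnot(ref_idx >= 1, ref_idx <= length(stacks))
  stage_list <- protocol$stages
  if ("bspline" %in% stage_list && protocol$bspline_repeats > 1) {
    stage_list <- c(stage_list,
                    rep("bspline", protocol$bspline_repeats - 1L))
  }
  if ("bspline" %in% protocol$stages && protocol$bspline_repeats == 0)
    stage_list <- setdiff(stage_list, "bspline")
  reference <- binarize(stacks[[ref_idx]], 127.5)
  inits <- NULL
  stage_out <- list()
  for (s in seq_along(stage_list)) {
    model <- stage_list[s]
    st <- run_stage(stacks, reference, model, inits = inits,
                    opts = protocol$opts)
    inits <- lapply(st$results, function(r) r$transform)
    sharp <- sharpness_ratio(st$average)
    stage_out[[s]] <- list(model = model, average = st$average,
                           transforms = inits, sharpness = sharp,
                           metrics = vapply(st$results, function(r)
                             r$final_metric, numeric(1)),
                           stacks = st$stacks)
    reference <- binarize(st$average, global_median_threshold(st$average))
  }
  final_avg <- stage_out[[length(stage_out)]]$average
  thr <- global_median_threshold(final_avg)
  generic_volume <- binarize(final_avg, thr)
  if (sum(generic_volume$data) == 0)
    stop("degenerate result: generic volume is empty")
  # marching cubes needs a strictly interior isovalue; when the subjects are
  # so well aligned that the median is the maximum intensity (or the stack
  # minimum), fall back to the surface of the binarized generic volume
  rng <- range(final_avg$data)
  generic_mesh <- if (thr > rng[1] && thr < rng[2])
    extract_surface(final_avg, thr)
  else extract_surface(generic_volume, 127.5)
  structure(list(stages = stage_out,
                 stage_models = vapply(stage_out, `[[`, "", "model"),
                 sharpness = vapply(stage_out, `[[`, numeric(1), "sharpness"),
                 reference_index = ref_idx,
                 threshold = thr,
                 generic_volume = generic_volume,
                 generic_mesh = generic_mesh),
            class = "averaging_result")
}

#' @export
print.averaging_result <- function(x, ...) {
  cat("<averaging_result>\n")
  cat("  reference subject:", x$reference_index, "\n")
  for (i in seq_along(x$stage_models))
    cat(sprintf("  stage %d (%s): sharpness ratio %.4f\n", i,
                x$stage_models[i], x$sharpness[i]))
  cat(sprintf("  generic threshold: %.4g\n", x$threshold))
  invisible(x)
}

#' Final-stage registered subject stacks
#'
#' Convenience accessor for the per-subject binarized stacks registered
#' through the full protocol (used for the centroid-property RMSE check).
#'
#' @param result an `averaging_result`.
#' @export
registered_stacks <- function(result) {
  stopifnot(inherits(result, "averaging_result"))
  result$stages[[length(result$stages)]]$stacks
}
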