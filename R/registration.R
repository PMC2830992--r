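#' Resample a moving volume through a transform
#'
#' Pull-back resampling: for every voxel center `x` of the output grid the
#' transform maps `x` into the moving volume's physical space and the
#' moving intensity is interpolated trilinearly at `t(x)`. Points mapping
#' outside the moving domain get intensity 0.
#'
#' @param moving a [stack_volume()].
#' @param t a transform (see [transforms]); it maps output-grid (fixed)
#'   points into moving space.
#' @param grid output [voxel_grid()] (or a volume whose grid is used).
#' @return A [stack_volume()] on `grid`.
#' @export
resample <- function(moving, t, grid) {
  stopifnot(is_stack_volume(moving))
  if (is_stack_volume(grid)) grid <- grid_of(grid)
  pts <- transform_points(t, voxel_centers(grid))
  vox <- sweep(sweep(pts, 2, moving$origin, "-"), 2, moving$spacing, "/")
  vals <- cpp_sample_trilinear(as.numeric(moving$data), dim(moving$data), vox)
  arr <- array(vals, dim = grid$shape)
  role <- if (moving$role == "byte" && all(arr == round(arr))) "byte" else "real"
  stack_volume(arr, grid$spacing, grid$origin, role = role)
}

#' Mean-square intensity metric
#'
#' Mean of squared intensity differences `(fixed(x) - moving(t(x)))^2` over
#' the fixed-grid voxels whose mapped position lies inside the moving
#' domain. This is the similarity measure driving all three registration
#' stages (appropriate for volumes carrying a single homogeneous foreground
#' intensity).
#'
#' @param fixed,moving [stack_volume()] objects.
#' @param t transform mapping fixed-space points into moving space
#'   (default identity).
#' @return single non-negative number.
#' @export
mean_square_metric <- function(fixed, moving, t = identity_transform()) {
  stopifnot(is_stack_volume(fixed), is_stack_volume(moving))
  res <- metric_eval(fixed, moving, t)
  if (res$n == 0) stop("zero overlap between fixed grid and moving domain")
  res$metric
}

metric_eval_grad <- function(fixed, moving, t) {
  lm <- linear_map_or_null(t)
  cpp_mse_linear_grad(as.numeric(fixed$data), dim(fixed$data),
                      fixed$origin, fixed$spacing,
                      as.numeric(moving$data), dim(moving$data),
                      moving$origin, moving$spacing, lm$L, lm$b)
}

metric_eval <- function(fixed, moving, t) {
  lm <- linear_map_or_null(t)
  if (!is.null(lm)) {
    return(cpp_mse_linear(as.numeric(fixed$data), dim(fixed$data),
                          fixed$origin, fixed$spacing,
                          as.numeric(moving$data), dim(moving$data),
                          moving$origin, moving$spacing, lm$L, lm$b))
  }
  # generic path for nonlinear / composed transforms
  pts <- transform_points(t, voxel_centers(grid_of(fixed)))
  vox <- sweep(sweep(pts, 2, moving$origin, "-"), 2, moving$spacing, "/")
  d <- dim(moving$data)
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[3] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[1] - 1
  vals <- cpp_sample_trilinear(as.numeric(moving$data), d, vox)
  diffs <- (as.numeric(fixed$data)[inside] - vals[inside])^2
  list(metric = if (any(inside)) mean(diffs) else NA_real_,
       n = sum(inside), sum = sum(diffs))
}

#' Registration options
#'
#' @param pyramid_levels number of resolution levels (1 = full resolution
#'   only); each extra level halves the resolution. Two levels enlarge the
#'   capture range of the gradient-descent optimizers.
#' @param max_iterations per-level iteration cap for the regular-step
#'   gradient descent.
#' @param initial_step initial step length in scaled parameter units
#'   (approximately voxels of boundary motion).
#' @param min_step convergence threshold on the step length.
#' @param grad_delta finite-difference half-step (scaled units) for the
#'   rigid/affine metric gradient.
#' @param bspline_max_iterations iteration cap for the limited-memory
#'   quasi-Newton (L-BFGS-B) deformable stage.
#' @param bspline_pgtol projected-gradient tolerance for L-BFGS-B.
#' @return list of options.
#' @export
registration_options <- function(pyramid_levels = 2L, max_iterations = 200L,
                                 initial_step = 2, min_step = 1e-4,
                                 grad_delta = 0.1,
                                 bspline_max_iterations = 80L,
                                 bspline_pgtol = 1e-5) {
  list(pyramid_levels = as.integer(pyramid_levels),
       max_iterations = as.integer(max_iterations),
       initial_step = initial_step, min_step = min_step,
       grad_delta = grad_delta,
       bspline_max_iterations = as.integer(bspline_max_iterations),
       bspline_pgtol = bspline_pgtol)
}

make_result <- function(transform, final_metric, initial_metric, iterations,
                        converged, trace) {
  structure(list(transform = transform, final_metric = final_metric,
                 initial_metric = initial_metric, iterations = iterations,
                 converged = converged, trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> metric %.4g -> %.4g in %d iterations (%s)\n",
    x$initial_metric, x$final_metric, x$iterations,
    if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

check_registration_inputs <- function(fixed, moving) {
  stopifnot(is_stack_volume(fixed), is_stack_volume(moving))
  if (sum(fixed$data) == 0) stop("degenerate input: fixed volume is all zero")
  if (sum(moving$data) == 0) stop("degenerate input: moving volume is all zero")
}

# Regular-step gradient descent with step halving, operating on scaled
# parameters u = par * scales (one scaled unit ~ one voxel of boundary
# motion). Analytic gradient via `gr` (falls back to central differences
# when NULL); the step is halved whenever a trial move fails to decrease
# the metric, and the run stops when the step drops below `min_step` or
# the iteration cap is hit.
regular_step_descent <- function(fn, par, scales, opts, gr = NULL) {
  u <- par * scales
  f <- fn(u / scales)
  trace <- f
  step <- opts$initial_step
  iter <- 0L
  h <- opts$grad_delta
  p <- length(u)
  tiny_gains <- 0L
  g_prev <- NULL
  while (iter < opts$max_iterations && step >= opts$min_step) {
    iter <- iter + 1L
    if (!is.null(gr)) {
      g <- gr(u / scales) / scales
    } else {
      g <- numeric(p)
      for (q in seq_len(p)) {
        e <- numeric(p); e[q] <- h
        g[q] <- (fn((u + e) / scales) - fn((u - e) / scales)) / (2 * h)
      }
    }
    gn <- sqrt(sum(g^2))
    if (gn < 1e-300) break
    # relax the step when the descent direction reverses (regular-step rule)
    if (!is.null(g_prev) && sum(g * g_prev) < 0) step <- step / 2
    g_prev <- g
    accepted <- FALSE
    while (step >= opts$min_step) {
      u_try <- u - step * g / gn
      f_try <- fn(u_try / scales)
      if (f_try < f) {
        rel_gain <- (f - f_try) / max(f, 1e-12)
        u <- u_try; f <- f_try
        accepted <- TRUE
        trace <- c(trace, f)
        tiny_gains <- if (rel_gain < 1e-8) tiny_gains + 1L else 0L
        break
      }
      step <- step / 2
    }
    if (!accepted || tiny_gains >= 3L) break
  }
  list(par = u / scales, value = f, iterations = iter,
       converged = step < opts$min_step || iter < opts$max_iterations ||
         tiny_gains >= 3L,
       trace = trace)
}

build_pyramid <- function(v, levels) {
  pyr <- vector("list", levels)
  pyr[[levels]] <- v
  if (levels > 1) {
    for (l in rev(seq_len(levels - 1))) {
      if (all(dim(pyr[[l + 1]]$data) >= 8L)) {
        pyr[[l]] <- downsample_volume(pyr[[l + 1]], 2L)
      } else {
        pyr[[l]] <- pyr[[l + 1]]
      }
    }
  }
  pyr
}

#' Rigid (versor) registration
#'
#' Intensity-based rigid registration with the mean-square metric, linear
#' interpolation and a regular-step gradient descent on the six parameters
#' (rotation vector, translation). The rotation center is fixed at the
#' fixed image's foreground center of mass; rotation parameters are scaled
#' by the fixed image's half-diagonal so one scaled unit moves the volume
#' boundary by about one voxel.
#'
#' @param fixed,moving [stack_volume()] objects.
#' @param init optional initial `rigid_transform`.
#' @param opts see [registration_options()].
#' @return A `registration_result` holding a `rigid_transform`.
#' @export
register_rigid <- function(fixed, moving, init = NULL,
                           opts = registration_options()) {
  check_registration_inputs(fixed, moving)
  C <- if (!is.null(init)) init$center else center_of_mass(fixed)
  par <- if (!is.null(init)) {
    c(versor_to_rotation_vector(init$versor), init$translation)
  } else c(0, 0, 0, 0, 0, 0)
  halfdiag <- half_diagonal(fixed)
  scales <- c(rep(halfdiag, 3), rep(1, 3))
  pyr_f <- build_pyramid(fixed, opts$pyramid_levels)
  pyr_m <- build_pyramid(moving, opts$pyramid_levels)
  total_iter <- 0L
  res <- NULL
  for (l in seq_len(opts$pyramid_levels)) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    lvl_opts <- level_opts(opts, fx)
    fn <- function(p) {
      t <- rigid_transform(rotation_vector_to_versor(p[1:3]), p[4:6], C)
      metric_eval(fx, mv, t)$metric
    }
    gr <- function(p) {
      t <- rigid_transform(rotation_vector_to_versor(p[1:3]), p[4:6], C)
      res <- metric_eval_grad(fx, mv, t)
      if (res$n == 0) return(numeric(6))
      Gc <- res$G - res$gb %o% C
      Ms <- rotation_matrix_derivs(p[1:3])
      gr_rot <- vapply(Ms, function(M) sum(M * Gc), numeric(1))
      -2 / res$n * c(gr_rot, res$gb)
    }
    res <- regular_step_descent(fn, par, scales, lvl_opts, gr = gr)
    par <- res$par
    total_iter <- total_iter + res$iterations
  }
  t_final <- rigid_transform(rotation_vector_to_versor(par[1:3]), par[4:6], C)
  init_metric <- metric_eval(fixed, moving,
                             if (!is.null(init)) init else identity_transform())$metric
  final_metric <- metric_eval(fixed, moving, t_final)$metric
  if (!is.finite(final_metric) || final_metric > init_metric) {
    # keep the better of initial vs found (optimizer contract)
    t_final <- if (!is.null(init)) init else rigid_transform(center = C)
    final_metric <- init_metric
  }
  make_result(t_final, final_metric, init_metric, total_iter, res$converged,
              res$trace)
}

half_diagonal <- function(v) {
  ext <- (dim(v$data)[3:1] - 1) * v$spacing
  sqrt(sum(ext^2)) / 2
}

level_opts <- function(opts, fx) {
  o <- opts
  o$initial_step <- opts$initial_step * min(fx$spacing)
  o$min_step <- opts$min_step
  o$grad_delta <- opts$grad_delta * min(fx$spacing)
  o
}

#' Affine registration
#'
#' Regular-step gradient descent over the 12 affine parameters (matrix and
#' translation), typically initialized from the rigid stage's result; the
#' matrix entries are scaled by the fixed image's half-diagonal.
#'
#' @inheritParams register_rigid
#' @param init optional `rigid_transform` or `affine_transform` used as the
#'   starting point (its center is reused).
#' @return A `registration_result` holding an `affine_transform`.
#' @export
register_affine <- function(fixed, moving, init = NULL,
                            opts = registration_options()) {
  check_registration_inputs(fixed, moving)
  if (!is.null(init)) {
    C <- init$center
    A0 <- if (inherits(init, "rigid_transform")) quat_to_matrix(init$versor)
    else init$matrix
    par <- c(as.numeric(A0), init$translation)
  } else {
    C <- center_of_mass(fixed)
    par <- c(as.numeric(diag(3)), 0, 0, 0)
  }
  halfdiag <- half_diagonal(fixed)
  scales <- c(rep(halfdiag, 9), rep(1, 3))
  pyr_f <- build_pyramid(fixed, opts$pyramid_levels)
  pyr_m <- build_pyramid(moving, opts$pyramid_levels)
  total_iter <- 0L
  res <- NULL
  for (l in seq_len(opts$pyramid_levels)) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    lvl_opts <- level_opts(opts, fx)
    fn <- function(p) {
      t <- affine_transform(matrix(p[1:9], 3, 3), p[10:12], C)
      metric_eval(fx, mv, t)$metric
    }
    gr <- function(p) {
      t <- affine_transform(matrix(p[1:9], 3, 3), p[10:12], C)
      res <- metric_eval_grad(fx, mv, t)
      if (res$n == 0) return(numeric(12))
      Gc <- res$G - res$gb %o% C
      -2 / res$n * c(as.numeric(Gc), res$gb)
    }
    res <- regular_step_descent(fn, par, scales, lvl_opts, gr = gr)
    par <- res$par
    total_iter <- total_iter + res$iterations
  }
  t_final <- affine_transform(matrix(par[1:9], 3, 3), par[10:12], C)
  init_t <- if (!is.null(init)) init else identity_transform()
  init_metric <- metric_eval(fixed, moving, init_t)$metric
  final_metric <- metric_eval(fixed, moving, t_final)$metric
  if (!is.finite(final_metric) || final_metric > init_metric) {
    A0 <- if (is.null(init)) diag(3) else if (inherits(init, "rigid_transform"))
      quat_to_matrix(init$versor) else init$matrix
    t_final <- affine_transform(A0, if (is.null(init)) c(0, 0, 0) else
      init$translation, C)
    final_metric <- init_metric
  }
  make_result(t_final, final_metric, init_metric, total_iter, res$converged,
              res$trace)
}

#' B-spline deformable registration
#'
#' Cubic B-spline free-form deformation optimized with a limited-memory
#' quasi-Newton method (L-BFGS-B) using the analytic metric gradient with
#' respect to the control-point displacement coefficients. The total
#' mapping is `T(x) = init(x + D(x))`: the deformation acts in fixed space
#' and is chained through the (linear) initial transform from the previous
#' protocol stage. If `init` is itself nonlinear the moving volume is
#' pre-resampled through it once and the deformation is optimized against
#' that resampled stack, while the returned transform still composes with
#' the original `init`.
#'
#' @inheritParams register_rigid
#' @param init optional transform from the previous stage.
#' @param grid_spacing control-point spacing (physical units); default one
#'   quarter of the fixed-image extent per axis, floored at 4 voxels. A
#'   coarse lattice regularizes the deformation: with near-binary volumes
#'   the metric only constrains the boundary shell, and a lattice much
#'   finer than the true shape variation can overfit it.
#' @return A `registration_result`; its transform is a `bspline_transform`
#'   or, when `init` is given, a `composed_transform` `init o (x + D(x))`.
#' @export
register_bspline <- function(fixed, moving, init = NULL, grid_spacing = NULL,
                             opts = registration_options()) {
  check_registration_inputs(fixed, moving)
  g <- grid_of(fixed)
  ext <- (g$shape[3:1] - 1) * g$spacing
  if (is.null(grid_spacing)) {
    grid_spacing <- pmax(ext / 4, 4 * g$spacing)
  } else {
    grid_spacing <- rep_len(as.numeric(grid_spacing), 3)
    if (any(grid_spacing < 4 * g$spacing))
      stop("`grid_spacing` below the 4-voxel stability floor")
  }
  # control lattice covering the domain with a one-cell margin
  m <- pmax(ceiling(ext / grid_spacing), 1)
  csp <- ext / m
  corigin <- g$origin - csp
  cdim <- as.integer(m + 3) # control points along (x, y, z)
  cdim_zyx <- cdim[3:1]
  # linear part of the initial transform (identity if none);
  # nonlinear init -> pre-resample the moving stack through it
  mov_opt <- moving
  lin_init <- if (is.null(init)) list(L = diag(3), b = c(0, 0, 0))
  else linear_map_or_null(init)
  if (is.null(lin_init)) {
    mov_opt <- resample(moving, init, g)
    lin_init <- list(L = diag(3), b = c(0, 0, 0))
  }
  ncoef <- prod(cdim_zyx) * 3L
  coef0 <- numeric(ncoef)
  # optim() calls fn and gr separately at the same point; evaluate the
  # metric and its gradient in one C++ pass and cache the pair
  cache <- new.env(parent = emptyenv())
  eval_both <- function(cf) {
    if (!is.null(cache$cf) && identical(cache$cf, cf)) return(cache$res)
    res <- cpp_mse_bspline(as.numeric(fixed$data), dim(fixed$data),
                           fixed$origin, fixed$spacing,
                           as.numeric(mov_opt$data), dim(mov_opt$data),
                           mov_opt$origin, mov_opt$spacing, cf, cdim_zyx,
                           corigin, csp, lin_init$L, lin_init$b, TRUE)
    cache$cf <- cf
    cache$res <- res
    res
  }
  fn <- function(cf) eval_both(cf)$metric
  gr <- function(cf) eval_both(cf)$grad
  init_metric <- fn(coef0)
  fit <- stats::optim(coef0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = opts$bspline_max_iterations,
                                     pgtol = opts$bspline_pgtol,
                                     factr = 1e6))
  final_metric <- fit$value
  coefs <- fit$par
  # a run that hit the iteration cap but clearly improved the metric is
  # still a usable (converged-enough) deformation
  converged <- fit$convergence == 0 || final_metric < init_metric
  if (!is.finite(final_metric) || final_metric > init_metric) {
    coefs <- coef0
    final_metric <- init_metric
    converged <- FALSE
  }
  bsp <- bspline_transform(array(coefs, dim = c(cdim_zyx, 3L)), corigin, csp)
  t_final <- if (is.null(init)) bsp else compose_transform_keep(init, bsp)
  make_result(t_final, final_metric, init_metric, fit$counts[1], converged,
              c(init_metric, final_metric))
}

# composition that always returns a composed_transform wrapper (the
# B-spline inner part must stay evaluable as x + D(x))
compose_transform_keep <- function(outer, inner) {
  structure(list(outer = outer, inner = inner),
            class = c("composed_transform", "sc_transform"))
}
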