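#' Spatial transforms
#'
#' Three transform families are used by the registration protocol, all with
#' center-based conventions and physical `(x, y, z)` coordinates:
#'
#' * rigid (versor): `X' = R(V) (X - C) + C + T` with `V` a unit quaternion;
#' * affine: `X' = A (X - C) + C + T` with `A` a general 3x3 matrix;
#' * B-spline free-form deformation: `X' = X + D(X)` where `D` is the
#'   tensor-product cubic B-spline interpolation of displacement vectors on
#'   a coarse control-point grid.
#'
#' `composed_transform(outer, inner)` applies `inner` first:
#' `T(X) = outer(inner(X))`.
#'
#' @name transforms
NULL

# --- quaternion / rotation helpers ----------------------------------------

#' @rdname transforms
#' @param versor unit quaternion `c(w, x, y, z)` (normalized on input), or
#'   see [rotation_vector_to_versor()].
#' @param translation,center length-3 numeric vectors.
#' @return the transform object.
#' @export
rigid_transform <- function(versor = c(1, 0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  versor <- as.numeric(versor)
  if (length(versor) != 4L) stop("`versor` must be a length-4 quaternion")
  nrm <- sqrt(sum(versor^2))
  if (nrm < 1e-12) stop("degenerate quaternion")
  if (abs(nrm - 1) > 1e-9) versor <- versor / nrm
  structure(list(versor = versor, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("rigid_transform", "sc_transform"))
}

#' @rdname transforms
#' @param matrix a 3x3 matrix (affine part).
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("affine_transform", "sc_transform"))
}

#' @rdname transforms
#' @param coefficients numeric array dim `(ncz, ncy, ncx, 3)` of control
#'   point displacement vectors (components ordered x, y, z).
#' @param grid_origin,grid_spacing control-grid geometry, `(x, y, z)` order.
#' @export
bspline_transform <- function(coefficients, grid_origin, grid_spacing) {
  if (length(dim(coefficients)) != 4L || dim(coefficients)[4] != 3L)
    stop("`coefficients` must be an array (ncz, ncy, ncx, 3)")
  if (any(dim(coefficients)[1:3] < 4L))
    stop("control grid needs >= 4 points per axis for cubic B-splines")
  structure(list(coefficients = coefficients,
                 grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing)),
            class = c("bspline_transform", "sc_transform"))
}

#' @rdname transforms
#' @param outer,inner transforms; the composition maps `X` to
#'   `outer(inner(X))`.
#' @export
compose_transform <- function(outer, inner) {
  stopifnot(inherits(outer, "sc_transform"), inherits(inner, "sc_transform"))
  lo <- linear_map_or_null(outer)
  li <- linear_map_or_null(inner)
  if (!is.null(lo) && !is.null(li)) {
    # closed-form composition of two linear maps
    L <- lo$L %*% li$L
    b <- as.numeric(lo$L %*% li$b + lo$b)
    if (inherits(outer, "rigid_transform") && inherits(inner, "rigid_transform")) {
      # with center 0 the translation equals the affine offset b
      q <- quat_multiply(outer$versor, inner$versor)
      return(rigid_transform(q, translation = b, center = c(0, 0, 0)))
    }
    return(affine_transform(L, translation = b, center = c(0, 0, 0)))
  }
  structure(list(outer = outer, inner = inner),
            class = c("composed_transform", "sc_transform"))
}

#' Identity transform
#' @export
identity_transform <- function() rigid_transform()

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_multiply <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

#' Convert a rotation vector (axis * angle, radians) to a versor
#' @param r length-3 rotation vector.
#' @export
rotation_vector_to_versor <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) return(c(1, 0, 0, 0))
  axis <- r / theta
  c(cos(theta / 2), sin(theta / 2) * axis)
}

#' Convert a versor to a rotation vector
#' @param q unit quaternion `c(w, x, y, z)`.
#' @export
versor_to_rotation_vector <- function(q) {
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(c(0, 0, 0))
  theta <- 2 * atan2(s, q[1])
  theta * q[2:4] / s
}

rotation_angle_deg <- function(t) {
  q <- t$versor
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

# linear map (L, b) with X' = L X + b, or NULL if the transform is nonlinear
linear_map_or_null <- function(t) {
  if (inherits(t, "rigid_transform")) {
    R <- quat_to_matrix(t$versor)
    list(L = R, b = as.numeric(t$center + t$translation - R %*% t$center))
  } else if (inherits(t, "affine_transform")) {
    list(L = t$matrix,
         b = as.numeric(t$center + t$translation - t$matrix %*% t$center))
  } else NULL
}

#' Apply a transform to physical points
#'
#' @param t a transform.
#' @param pts an N x 3 matrix of `(x, y, z)` points (a length-3 vector is
#'   accepted for a single point).
#' @return matrix of mapped points (or length-3 vector for single-point
#'   input).
#' @export
transform_points <- function(t, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  out <- transform_points_impl(t, pts)
  if (single) as.numeric(out) else out
}

transform_points_impl <- function(t, pts) {
  UseMethod("transform_points_impl")
}

#' @export
transform_points_impl.rigid_transform <- function(t, pts) {
  lm <- linear_map_or_null(t)
  sweep(pts %*% t(lm$L), 2, lm$b, "+")
}

#' @export
transform_points_impl.affine_transform <- transform_points_impl.rigid_transform

#' @export
transform_points_impl.bspline_transform <- function(t, pts) {
  d <- cpp_bspline_disp(as.numeric(t$coefficients), dim(t$coefficients)[1:3],
                        t$grid_origin, t$grid_spacing, pts)
  pts + d
}

#' @export
transform_points_impl.composed_transform <- function(t, pts) {
  transform_points_impl(t$outer, transform_points_impl(t$inner, pts))
}

#' B-spline displacement at points
#'
#' Evaluates the displacement field `D(X)` of a B-spline transform (zero
#' for points outside the control grid's support only if the supporting
#' coefficients are zero).
#'
#' @param t a `bspline_transform`.
#' @param pts N x 3 physical points.
#' @return N x 3 matrix of displacement vectors.
#' @export
bspline_displacement <- function(t, pts) {
  stopifnot(inherits(t, "bspline_transform"))
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  cpp_bspline_disp(as.numeric(t$coefficients), dim(t$coefficients)[1:3],
                   t$grid_origin, t$grid_spacing, pts)
}

#' Dense displacement field of a B-spline transform
#'
#' Evaluates the deformation vector at every voxel center of `grid`,
#' returning an array dim `(nz, ny, nx, 3)` (components ordered x, y, z)
#' with geometry attributes, writable as a vector NRRD via [write_stack()]'s
#' underlying NRRD writer (`write_displacement_field()`).
#'
#' @param t a `bspline_transform`.
#' @param grid a [voxel_grid()] or [stack_volume()].
#' @export
dense_displacement_field <- function(t, grid) {
  if (is_stack_volume(grid)) grid <- grid_of(grid)
  pts <- voxel_centers(grid)
  d <- bspline_displacement(t, pts)
  arr <- array(d, dim = c(grid$shape, 3L))
  attr(arr, "spacing") <- grid$spacing
  attr(arr, "origin") <- grid$origin
  arr
}

#' @rdname dense_displacement_field
#' @param field array as returned by [dense_displacement_field()].
#' @param path output `.nrrd` path.
#' @export
write_displacement_field <- function(field, path) {
  write_nrrd(field, path)
  invisible(path)
}

# --- serialization ---------------------------------------------------------

transform_to_list <- function(t) {
  if (inherits(t, "rigid_transform")) {
    list(kind = "rigid", versor = t$versor, translation = t$translation,
         center = t$center)
  } else if (inherits(t, "affine_transform")) {
    list(kind = "affine", matrix = as.numeric(t$matrix),
         translation = t$translation, center = t$center)
  } else if (inherits(t, "bspline_transform")) {
    list(kind = "bspline", grid_size = dim(t$coefficients)[1:3],
         grid_origin = t$grid_origin, grid_spacing = t$grid_spacing,
         coefficients = as.numeric(t$coefficients))
  } else if (inherits(t, "composed_transform")) {
    list(kind = "composed", outer = transform_to_list(t$outer),
         inner = transform_to_list(t$inner))
  } else stop("unknown transform class")
}

transform_from_list <- function(x) {
  switch(x$kind,
         rigid = rigid_transform(x$versor, x$translation, x$center),
         affine = affine_transform(matrix(x$matrix, 3, 3), x$translation,
                                   x$center),
         bspline = bspline_transform(array(x$coefficients,
                                           dim = c(x$grid_size, 3L)),
                                     x$grid_origin, x$grid_spacing),
         composed = structure(list(outer = transform_from_list(x$outer),
                                   inner = transform_from_list(x$inner)),
                              class = c("composed_transform", "sc_transform")),
         stop("unknown transform kind: ", x$kind))
}

#' Save / load transforms as JSON text files
#'
#' All parameters round-trip at full double precision.
#'
#' @param t a transform.
#' @param path file path.
#' @export
save_transform <- function(t, path) {
  json <- jsonlite::toJSON(transform_to_list(t), digits = NA, auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  transform_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @export
print.sc_transform <- function(x, ...) {
  if (inherits(x, "rigid_transform")) {
    cat(sprintf("<rigid_transform> angle %.3f deg, translation (%s)\n",
                rotation_angle_deg(x),
                paste(signif(x$translation, 4), collapse = ", ")))
  } else if (inherits(x, "affine_transform")) {
    cat("<affine_transform>\n")
    print(signif(x$matrix, 5))
    cat("  translation:", paste(signif(x$translation, 4), collapse = ", "), "\n")
  } else if (inherits(x, "bspline_transform")) {
    cat(sprintf("<bspline_transform> control grid %s, max |coef| %.3f\n",
                paste(dim(x$coefficients)[1:3], collapse = "x"),
                max(abs(x$coefficients))))
  } else {
    cat("<composed_transform>\n")
  }
  invisible(x)
}

# Partial derivatives of the rotation matrix with respect to the rotation
# vector (exact closed form; for |r| -> 0 the limit is the skew generator).
rotation_matrix_derivs <- function(r) {
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
                             3, 3)
  theta2 <- sum(r^2)
  if (theta2 < 1e-16) {
    return(lapply(1:3, function(k) skew(diag(3)[, k])))
  }
  R <- quat_to_matrix(rotation_vector_to_versor(r))
  lapply(1:3, function(k) {
    ek <- diag(3)[, k]
    v <- r[k] * r + as.numeric(crossprod_vec(r, (diag(3) - R) %*% ek))
    (skew(v) / theta2) %*% R
  })
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
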