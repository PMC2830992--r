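#' Volumetric image stacks
#'
#' A `stack_volume` is a 3D scalar voxel grid with physical geometry. The
#' data array is indexed `[z, y, x]` (slice, row, column) with dim
#' `(nz, ny, nx)`; `spacing` and `origin` are length-3 vectors in `(x, y, z)`
#' order. The physical coordinate of (0-based) voxel `(i, j, k)` along
#' `(x, y, z)` is `origin + c(i, j, k) * spacing`. Byte volumes hold
#' intensities in 0--255; real volumes (averaged stacks) hold fractional
#' intensities in the same range.
#'
#' @param data numeric 3D array, dim `(nz, ny, nx)`.
#' @param spacing positive length-3 numeric, physical voxel size `(x, y, z)`.
#' @param origin length-3 numeric, physical position of voxel `(0, 0, 0)`.
#' @param role `"byte"` (integer intensities 0--255) or `"real"`.
#' @return A `stack_volume` object.
#' @export
stack_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         role = c("byte", "real")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all volume axes must have length >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  storage.mode(data) <- "double"
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie within [0, 255]")
  if (role == "byte" && any(data != round(data)))
    stop("byte volume has non-integer intensities; use role = \"real\"")
  structure(list(data = data, spacing = spacing, origin = origin, role = role),
            class = "stack_volume")
}

#' @export
print.stack_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<stack_volume> %d x %d x %d (z,y,x), %s\n", d[1], d[2], d[3],
              x$role))
  cat(sprintf("  spacing (x,y,z): %s   origin: %s\n",
              paste(signif(x$spacing, 6), collapse = " "),
              paste(signif(x$origin, 6), collapse = " ")))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.stack_volume <- function(x) dim(x$data)

is_stack_volume <- function(x) inherits(x, "stack_volume")

#' Voxel grid geometry
#'
#' A `voxel_grid` describes the geometry of a volume (shape, spacing,
#' origin) without the data, shared by resampling and mask operations.
#'
#' @param shape integer length-3, array dim `(nz, ny, nx)`.
#' @param spacing,origin as in [stack_volume()].
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers (nz, ny, nx)")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param v a `stack_volume`.
#' @export
grid_of <- function(v) voxel_grid(dim(v$data), v$spacing, v$origin)

same_grid <- function(a, b, tol = 1e-9) {
  ga <- if (is_stack_volume(a)) grid_of(a) else a
  gb <- if (is_stack_volume(b)) grid_of(b) else b
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

#' Physical coordinates of all voxel centers
#'
#' Returns an N x 3 matrix of `(x, y, z)` physical coordinates in the
#' array's element order (z varies fastest, then y, then x).
#'
#' @param grid a `voxel_grid` or `stack_volume`.
#' @return numeric matrix with N = prod(shape) rows.
#' @export
voxel_centers <- function(grid) {
  if (is_stack_volume(grid)) grid <- grid_of(grid)
  n <- grid$shape # (nz, ny, nx)
  z <- grid$origin[3] + (seq_len(n[1]) - 1) * grid$spacing[3]
  y <- grid$origin[2] + (seq_len(n[2]) - 1) * grid$spacing[2]
  x <- grid$origin[1] + (seq_len(n[3]) - 1) * grid$spacing[1]
  cbind(x = rep(x, each = n[1] * n[2]),
        y = rep(rep(y, each = n[1]), times = n[3]),
        z = rep(z, times = n[2] * n[3]))
}

#' Binarize a volume at an intensity threshold
#'
#' Voxels with intensity greater than or equal to `threshold` become 255,
#' all others 0 (the threshold itself is inclusive).
#'
#' @param v a `stack_volume`.
#' @param threshold intensity in (0, 255].
#' @return A byte `stack_volume` with values in {0, 255}.
#' @export
binarize <- function(v, threshold) {
  stopifnot(is_stack_volume(v))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 255)
    stop("`threshold` must be a single intensity in (0, 255]")
  out <- array(ifelse(v$data >= threshold, 255, 0), dim = dim(v$data))
  stack_volume(out, v$spacing, v$origin, role = "byte")
}

#' Global median threshold of an averaged stack
#'
#' The median intensity of the foreground (intensity > 0) voxels, used to
#' binarize averaged image stacks and as the isovalue for surface
#' extraction of the generic model. Background voxels, which are 0 by
#' construction after cutting and registration, are excluded so the
#' threshold falls inside the model's intensity distribution. For an even
#' count the lower middle value is taken, so the threshold is always an
#' attained intensity.
#'
#' @param v a `stack_volume` with at least one voxel > 0.
#' @return A single intensity value.
#' @export
global_median_threshold <- function(v) {
  stopifnot(is_stack_volume(v))
  vals <- v$data[v$data > 0]
  if (length(vals) == 0)
    stop("degenerate input: volume has no voxel with intensity > 0")
  sort(vals)[ceiling(length(vals) / 2)]
}

#' Foreground center of mass (physical coordinates)
#'
#' Intensity-weighted centroid, used as the default center of rotation for
#' registration.
#'
#' @param v a `stack_volume` with nonzero total intensity.
#' @return length-3 numeric `(x, y, z)`.
#' @export
center_of_mass <- function(v) {
  stopifnot(is_stack_volume(v))
  w <- as.numeric(v$data)
  tot <- sum(w)
  if (tot <= 0) stop("degenerate input: volume is all zero")
  pts <- voxel_centers(grid_of(v))
  colSums(pts * w) / tot
}

#' Downsample a volume by block averaging
#'
#' Each axis is reduced by `factor` using block means; spacing scales by
#' `factor` and the origin moves to the center of the first block. Used for
#' the multi-resolution registration pyramid.
#'
#' @param v a `stack_volume`.
#' @param factor integer >= 2.
#' @return A real `stack_volume`.
#' @export
downsample_volume <- function(v, factor = 2L) {
  stopifnot(is_stack_volume(v), factor >= 2)
  f <- as.integer(factor)
  d <- dim(v$data)
  nd <- pmax(d %/% f, 1L)
  # crop to a multiple of f, then block mean
  cr <- v$data[seq_len(nd[1] * min(f, d[1])),
               seq_len(nd[2] * min(f, d[2])),
               seq_len(nd[3] * min(f, d[3])), drop = FALSE]
  fz <- min(f, d[1]); fy <- min(f, d[2]); fx <- min(f, d[3])
  a <- array(cr, dim = c(fz, nd[1], fy, nd[2], fx, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  stack_volume(out, v$spacing * c(fx, fy, fz),
               v$origin + v$spacing * (c(fx, fy, fz) - 1) / 2,
               role = "real")
}
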