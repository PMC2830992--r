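#' Cutting instruments
#'
#' Four geometric instruments remove unwanted regions of a voxel model so
#' that only the sub-model of interest remains. All coordinates are
#' physical `(x, y, z)`, so cut scripts stay valid across resampled grids.
#'
#' * `plane_cut(center, normal)`: removes the closed half-space
#'   `dot(x - center, normal) >= 0` (the normal points toward the removed
#'   side; points exactly on the plane are removed).
#' * `sphere_cut(center, radius)`: removes `|x - center| <= radius`.
#' * `box_cut(planes)`: six half-spaces whose *intersection* is removed.
#' * `curve_cut(dots, view_direction, closed)`: a user-drawn curve on the
#'   screen projection along `view_direction`. The dots are interpolated by
#'   a natural cubic spline in the projection plane and the cut surface is
#'   the curve extruded along the view axis. A closed curve removes the
#'   enclosed region (even-odd rule); an open curve is extended along its
#'   end tangents and removes the region to the *left* of the directed
#'   curve, so dots placed counterclockwise remove the upper/left part and
#'   reversing the dot order selects the other side.
#'
#' @param center,normal,dots,view_direction physical coordinates
#'   (`(x, y, z)`); `normal` and `view_direction` are normalized (an error
#'   if further than 1e-3 from unit length).
#' @param radius physical length >= 0.
#' @param planes list of exactly 6 `plane_cut` objects.
#' @param closed logical flag; closed curves need >= 3 dots.
#' @name cutting
NULL

unitize <- function(v, what) {
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > 1e-3)
    stop(what, " must be a unit vector (|v| = ", signif(n, 6), ")")
  v / n
}

#' @rdname cutting
#' @export
plane_cut <- function(center, normal) {
  structure(list(center = as.numeric(center),
                 normal = unitize(as.numeric(normal), "plane normal")),
            class = c("plane_cut", "cut_record"))
}

#' @rdname cutting
#' @export
sphere_cut <- function(center, radius) {
  radius <- as.numeric(radius)
  if (radius < 0) stop("sphere radius must be >= 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = c("sphere_cut", "cut_record"))
}

#' @rdname cutting
#' @export
box_cut <- function(planes) {
  if (length(planes) != 6L || !all(vapply(planes, inherits, TRUE, "plane_cut")))
    stop("a box cut needs exactly 6 plane cuts")
  structure(list(planes = planes), class = c("box_cut", "cut_record"))
}

#' @rdname cutting
#' @export
curve_cut <- function(dots, view_direction, closed = FALSE) {
  dots <- matrix(as.numeric(dots), ncol = 3)
  if (nrow(dots) < 2L) stop("a curve cut needs at least 2 dots")
  if (closed && nrow(dots) < 3L) stop("a closed curve needs at least 3 dots")
  structure(list(dots = dots,
                 view_direction = unitize(as.numeric(view_direction),
                                          "view direction"),
                 closed = isTRUE(closed)),
            class = c("curve_cut", "cut_record"))
}

#' @rdname cutting
#' @param records list of cut records, in the order they were applied.
#' @export
cut_script <- function(records = list()) {
  if (!all(vapply(records, inherits, TRUE, "cut_record")))
    stop("all elements must be cut records")
  structure(list(records = records), class = "cut_script")
}

#' @export
print.cut_script <- function(x, ...) {
  cat(sprintf("<cut_script> %d record(s)\n", length(x$records)))
  for (r in x$records) cat(" -", class(r)[1], "\n")
  invisible(x)
}

#' Parse / write cut scripts
#'
#' Text format, one record per line, whitespace separated, `#` comments:
#' \preformatted{
#' PLANE cx cy cz nx ny nz
#' SPHERE cx cy cz r
#' BOX_BEGIN
#'   PLANE ... (exactly six)
#' BOX_END
#' CURVE open|closed vx vy vz n d1x d1y d1z ... dnx dny dnz
#' }
#'
#' @param text character scalar or vector of lines.
#' @return A [cut_script()].
#' @export
parse_cut_script <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  records <- list()
  box_planes <- NULL
  perr <- function(i, msg) stop("cut script line ", i, ": ", msg, call. = FALSE)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) next
    kind <- toupper(tok[1])
    nums <- suppressWarnings(as.numeric(tok[-1]))
    rec <- NULL
    if (kind == "PLANE") {
      if (length(nums) != 6 || any(is.na(nums)))
        perr(i, "PLANE needs 6 numbers (center, normal)")
      n <- nums[4:6]
      nn <- sqrt(sum(n^2))
      if (abs(nn - 1) > 1e-3) perr(i, "plane normal is not unit length")
      if (abs(nn - 1) > 1e-9)
        warning("normalizing near-unit plane normal on line ", i)
      rec <- plane_cut(nums[1:3], n / nn)
    } else if (kind == "SPHERE") {
      if (length(nums) != 4 || any(is.na(nums)))
        perr(i, "SPHERE needs 4 numbers (center, radius)")
      if (nums[4] < 0) perr(i, "negative sphere radius")
      rec <- sphere_cut(nums[1:3], nums[4])
    } else if (kind == "BOX_BEGIN") {
      if (!is.null(box_planes)) perr(i, "nested BOX_BEGIN")
      box_planes <- list()
      next
    } else if (kind == "BOX_END") {
      if (is.null(box_planes)) perr(i, "BOX_END without BOX_BEGIN")
      if (length(box_planes) != 6) perr(i, "box needs exactly 6 planes")
      records[[length(records) + 1L]] <- box_cut(box_planes)
      box_planes <- NULL
      next
    } else if (kind == "CURVE") {
      mode <- tolower(tok[2])
      if (!mode %in% c("open", "closed")) perr(i, "CURVE mode must be open|closed")
      nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
      if (length(nums) < 4 || any(is.na(nums))) perr(i, "malformed CURVE record")
      vdir <- nums[1:3]
      ndots <- nums[4]
      if (ndots != round(ndots) || ndots < 2) perr(i, "bad dot count")
      if (length(nums) != 4 + 3 * ndots) perr(i, "dot count mismatch")
      dots <- matrix(nums[-(1:4)], ncol = 3, byrow = TRUE)
      rec <- tryCatch(curve_cut(dots, vdir, closed = mode == "closed"),
                      error = function(e) perr(i, conditionMessage(e)))
    } else {
      perr(i, paste0("unknown record kind '", tok[1], "'"))
    }
    if (!is.null(box_planes)) {
      if (!inherits(rec, "plane_cut")) perr(i, "only PLANE allowed inside BOX")
      box_planes[[length(box_planes) + 1L]] <- rec
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (!is.null(box_planes)) stop("unterminated BOX_BEGIN")
  cut_script(records)
}

#' @rdname parse_cut_script
#' @param s a [cut_script()].
#' @export
write_cut_script <- function(s) {
  stopifnot(inherits(s, "cut_script"))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- character(0)
  for (r in s$records) {
    if (inherits(r, "plane_cut")) {
      lines <- c(lines, paste("PLANE", fmt(r$center), fmt(r$normal)))
    } else if (inherits(r, "sphere_cut")) {
      lines <- c(lines, paste("SPHERE", fmt(r$center), fmt(r$radius)))
    } else if (inherits(r, "box_cut")) {
      lines <- c(lines, "BOX_BEGIN",
                 vapply(r$planes, function(p)
                   paste("PLANE", fmt(p$center), fmt(p$normal)), ""),
                 "BOX_END")
    } else if (inherits(r, "curve_cut")) {
      lines <- c(lines, paste("CURVE", if (r$closed) "closed" else "open",
                              fmt(r$view_direction), nrow(r$dots),
                              fmt(as.numeric(t(r$dots)))))
    }
  }
  paste(lines, collapse = "\n")
}

#' Removal mask of a cut on a voxel grid
#'
#' Evaluates the cut's removal predicate at every voxel center, returning a
#' logical array (`TRUE` = removed). Membership is decided at the voxel
#' center with no partial-volume treatment.
#'
#' @param cut a cut record.
#' @param grid a [voxel_grid()] or [stack_volume()].
#' @return logical array with the grid's dim.
#' @export
removal_mask <- function(cut, grid) {
  if (is_stack_volume(grid)) grid <- grid_of(grid)
  pts <- voxel_centers(grid)
  m <- removal_predicate(cut, pts, grid)
  array(m, dim = grid$shape)
}

removal_predicate <- function(cut, pts, grid) UseMethod("removal_predicate")

#' @export
removal_predicate.plane_cut <- function(cut, pts, grid) {
  as.numeric(sweep(pts, 2, cut$center, "-") %*% cut$normal) >= 0
}

#' @export
removal_predicate.sphere_cut <- function(cut, pts, grid) {
  d2 <- rowSums(sweep(pts, 2, cut$center, "-")^2)
  d2 <= cut$radius^2
}

#' @export
removal_predicate.box_cut <- function(cut, pts, grid) {
  m <- rep(TRUE, nrow(pts))
  for (p in cut$planes) m <- m & removal_predicate(p, pts, grid)
  m
}

# orthonormal basis of the plane orthogonal to the (unit) view direction,
# chosen deterministically
view_basis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * v) * v
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  cbind(u, w)
}

# natural cubic spline through the projected dots, polygonized
polygonize_curve <- function(dots2, closed, n_seg = 256L) {
  nd <- nrow(dots2)
  if (closed) {
    # periodic parameterization: wrap the dots, spline over one period
    pts <- rbind(dots2, dots2[1, , drop = FALSE])
    tt <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    if (tail(tt, 1) == 0) stop("degenerate curve: coincident dots")
    s <- seq(0, tail(tt, 1), length.out = n_seg + 1L)[-(n_seg + 1L)]
    x <- stats::spline(tt, pts[, 1], xout = s, method = "periodic")$y
    y <- stats::spline(tt, pts[, 2], xout = s, method = "periodic")$y
    cbind(x, y)
  } else {
    tt <- c(0, cumsum(sqrt(rowSums(diff(dots2)^2))))
    if (tail(tt, 1) == 0) stop("degenerate curve: coincident dots")
    s <- seq(0, tail(tt, 1), length.out = n_seg)
    x <- stats::spline(tt, dots2[, 1], xout = s, method = "natural")$y
    y <- stats::spline(tt, dots2[, 2], xout = s, method = "natural")$y
    cbind(x, y)
  }
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- (p4[1]-p3[1])*(p1[2]-p3[2]) - (p4[2]-p3[2])*(p1[1]-p3[1])
  d2 <- (p4[1]-p3[1])*(p2[2]-p3[2]) - (p4[2]-p3[2])*(p2[1]-p3[1])
  d3 <- (p2[1]-p1[1])*(p3[2]-p1[2]) - (p2[2]-p1[2])*(p3[1]-p1[1])
  d4 <- (p2[1]-p1[1])*(p4[2]-p1[2]) - (p2[2]-p1[2])*(p4[1]-p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

check_self_intersection <- function(poly) {
  n <- nrow(poly) - 1L
  for (a in seq_len(n - 1L)) {
    if (a + 2L > n) next
    for (b in seq(a + 2L, n)) {
      if (segments_intersect(poly[a, ], poly[a + 1L, ],
                             poly[b, ], poly[b + 1L, ]))
        stop("self-intersecting open cutting curve is not supported")
    }
  }
}

#' @export
removal_predicate.curve_cut <- function(cut, pts, grid) {
  B <- view_basis(cut$view_direction)
  p2 <- pts %*% B           # projected voxel centers
  d2 <- cut$dots %*% B      # projected dots
  if (cut$closed) {
    poly <- polygonize_curve(d2, closed = TRUE)
    point_in_polygon(p2, poly)
  } else {
    poly <- polygonize_curve(d2, closed = FALSE)
    # extend beyond the end dots along the end tangents so the curve
    # partitions the whole projection plane
    span <- max(dist_range(p2), dist_range(poly)) * 4 + 1
    t0 <- poly[1, ] - poly[2, ]
    t1 <- poly[nrow(poly), ] - poly[nrow(poly) - 1L, ]
    t0 <- t0 / sqrt(sum(t0^2)); t1 <- t1 / sqrt(sum(t1^2))
    ext <- rbind(poly[1, ] + t0 * span, poly,
                 poly[nrow(poly), ] + t1 * span)
    check_self_intersection(ext)
    left_of_polyline(p2, ext)
  }
}

dist_range <- function(m) {
  r1 <- range(m[, 1]); r2 <- range(m[, 2])
  sqrt((r1[2] - r1[1])^2 + (r2[2] - r2[1])^2)
}

# even-odd crossing test, vectorized over points
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# TRUE where the point lies to the left of the directed polyline (sign of
# the 2D cross product of the nearest segment's tangent with the point
# offset)
left_of_polyline <- function(pts, poly) {
  n <- nrow(poly) - 1L
  px <- pts[, 1]; py <- pts[, 2]
  best_d2 <- rep(Inf, nrow(pts))
  out <- logical(nrow(pts))
  for (s in seq_len(n)) { # vectorized over points, looped over segments
    ax <- poly[s, 1]; ay <- poly[s, 2]
    ex <- poly[s + 1L, 1] - ax; ey <- poly[s + 1L, 2] - ay
    el2 <- ex^2 + ey^2
    if (el2 == 0) next
    tt <- ((px - ax) * ex + (py - ay) * ey) / el2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- ax + tt * ex; qy <- ay + tt * ey
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      out[upd] <- (ex * (py[upd] - qy[upd]) - ey * (px[upd] - qx[upd])) >= 0
    }
  }
  out
}

#' Apply a cut script to a volume
#'
#' Sets every voxel inside the union of the records' removal masks to 0;
#' all other voxels are unchanged. The result does not depend on the order
#' of the records.
#'
#' @param v a byte [stack_volume()].
#' @param s a [cut_script()] (or a single cut record).
#' @return A [stack_volume()] on the same grid.
#' @export
apply_cuts <- function(v, s) {
  stopifnot(is_stack_volume(v))
  if (inherits(s, "cut_record")) s <- cut_script(list(s))
  stopifnot(inherits(s, "cut_script"))
  g <- grid_of(v)
  removed <- array(FALSE, dim = g$shape)
  for (r in s$records) removed <- removed | removal_mask(r, g)
  out <- v$data
  out[removed] <- 0
  stack_volume(out, v$spacing, v$origin, role = v$role)
}
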