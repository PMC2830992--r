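test_that("cut script parsing maps fields and round-trips", {
  s <- parse_cut_script("PLANE 0 0 5 0 0 1")
  expect_length(s$records, 1L)
  expect_s3_class(s$records[[1]], "plane_cut")
  expect_equal(s$records[[1]]$center, c(0, 0, 5))
  expect_equal(s$records[[1]]$normal, c(0, 0, 1))

  txt <- paste(
    "# a four-record script",
    "PLANE 1 2 3 1 0 0",
    "SPHERE 4 5 6 2.5",
    "BOX_BEGIN",
    "PLANE 0 0 0 1 0 0", "PLANE 10 0 0 -1 0 0",
    "PLANE 0 0 0 0 1 0", "PLANE 0 10 0 0 -1 0",
    "PLANE 0 0 0 0 0 1", "PLANE 0 0 10 0 0 -1",
    "BOX_END",
    "CURVE open 0 0 1 3 0 0 0 5 5 0 10 0 0",
    sep = "\n")
  s2 <- parse_cut_script(txt)
  expect_length(s2$records, 4L)
  rt <- parse_cut_script(write_cut_script(s2))
  expect_equal(rt, s2)
})

test_that("malformed cut script lines are rejected with line numbers", {
  expect_error(parse_cut_script("SPHERE 1 2 3 -1"), "line 1")
  expect_error(parse_cut_script("PLANE 1 2 3 0 0"), "6 numbers")
  expect_error(parse_cut_script("WEDGE 1 2 3"), "unknown record kind")
  expect_error(parse_cut_script("PLANE 0 0 0 0 0 2"), "unit")
  expect_error(parse_cut_script("BOX_BEGIN\nPLANE 0 0 0 1 0 0\nBOX_END"),
               "6 planes")
  # near-unit normals are normalized with a warning
  expect_warning(parse_cut_script("PLANE 0 0 0 0 0 1.0000004"), "normalizing")
})

test_that("plane masks match the exhaustive voxel-center oracle", {
  g <- voxel_grid(c(4, 4, 4))
  cut <- plane_cut(center = c(1.5, 1.5, 1.5), normal = c(0, 0, 1))
  m <- removal_mask(cut, g)
  for (k in 0:3) for (j in 0:3) for (i in 0:3) {
    expect_identical(m[k + 1, j + 1, i + 1], k >= 1.5)
  }
  # flipping the normal complements the mask except on-plane voxels
  m2 <- removal_mask(plane_cut(c(1.5, 1.5, 1.5), c(0, 0, -1)), g)
  expect_false(any(m & m2)) # plane at z=1.5 passes between voxel centers
  expect_true(all(m | m2))
  # voxels exactly on the plane are removed by both orientations
  cut_on <- plane_cut(c(0, 0, 2), c(0, 0, 1))
  m3 <- removal_mask(cut_on, g)
  m4 <- removal_mask(plane_cut(c(0, 0, 2), c(0, 0, -1)), g)
  expect_true(all(m3[3, , ]) && all(m4[3, , ]))
})

test_that("sphere and box masks follow their geometric predicates", {
  g <- voxel_grid(c(5, 5, 5))
  # zero-radius sphere at a voxel center removes exactly that voxel
  m <- removal_mask(sphere_cut(c(2, 3, 1), 0), g)
  expect_equal(sum(m), 1L)
  expect_true(m[2, 4, 3]) # (z=1, y=3, x=2) -> indices (k+1, j+1, i+1)
  # box equals the intersection of its six plane masks
  planes <- list(plane_cut(c(1, 0, 0), c(1, 0, 0)),
                 plane_cut(c(3, 0, 0), c(-1, 0, 0)),
                 plane_cut(c(0, 1, 0), c(0, 1, 0)),
                 plane_cut(c(0, 3, 0), c(0, -1, 0)),
                 plane_cut(c(0, 0, 1), c(0, 0, 1)),
                 plane_cut(c(0, 0, 3), c(0, 0, -1)))
  mb <- removal_mask(box_cut(planes), g)
  inter <- Reduce(`&`, lapply(planes, removal_mask, grid = g))
  expect_identical(mb, inter)
})

test_that("random plane/sphere masks equal brute-force predicates", {
  for (seed in 1:20) {
    set.seed(seed)
    shp <- sample(4:12, 3, replace = TRUE)
    g <- voxel_grid(shp, spacing = runif(3, 0.5, 2))
    pts <- voxel_centers(g)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    ctr <- runif(3, 0, 8)
    mp <- removal_mask(plane_cut(ctr, n), g)
    oracle_p <- array((pts - rep(ctr, each = nrow(pts))) %*% n >= 0,
                      dim = shp)
    expect_identical(mp, oracle_p)
    r <- runif(1, 0.5, 6)
    ms <- removal_mask(sphere_cut(ctr, r), g)
    oracle_s <- array(sqrt(rowSums(sweep(pts, 2, ctr, "-")^2)) <= r,
                      dim = shp)
    expect_identical(ms, oracle_s)
  }
})

test_that("closed curve masks agree with a winding-number oracle", {
  g <- voxel_grid(c(3, 16, 16))
  # closed square-ish curve viewed along z
  dots <- rbind(c(4, 4, 0), c(11, 4, 0), c(11, 11, 0), c(4, 11, 0))
  cut <- curve_cut(dots, view_direction = c(0, 0, 1), closed = TRUE)
  m <- removal_mask(cut, g)
  # the mask is an extruded prism: identical for every z slice
  expect_identical(m[1, , ], m[3, , ])
  # oracle: winding number against the same polygonized spline
  poly <- stackcarve:::polygonize_curve(dots[, 1:2], closed = TRUE)
  pts <- voxel_centers(g)
  oracle <- winding_inside(pts[, 1], pts[, 2], poly)
  # points lying exactly on the curve (the dots themselves) have an
  # arbitrary boundary convention; compare everywhere else
  mind <- vapply(seq_len(nrow(pts)), function(r)
    min((poly[, 1] - pts[r, 1])^2 + (poly[, 2] - pts[r, 2])^2), numeric(1))
  off_curve <- mind > 1e-12
  expect_identical(as.logical(m)[off_curve], as.logical(oracle)[off_curve])
  # the dot centroid is removed; far corners are kept
  expect_true(m[1, 8, 8])
  expect_false(m[1, 1, 1])
})

test_that("open collinear curves reduce to plane cuts", {
  g <- voxel_grid(c(4, 8, 8))
  # dots along +y at x = 3.5, viewed along z: the directed curve runs
  # toward +y, so its left side is x < 3.5
  dots <- rbind(c(3.5, 1, 0), c(3.5, 3, 0), c(3.5, 6, 0))
  cut <- curve_cut(dots, view_direction = c(0, 0, 1), closed = FALSE)
  m <- removal_mask(cut, g)
  plane_equiv <- removal_mask(plane_cut(c(3.5, 0, 0), c(-1, 0, 0)), g)
  expect_identical(m, plane_equiv)
  # reversing the dot order selects the other side
  m_rev <- removal_mask(curve_cut(dots[3:1, ], c(0, 0, 1), FALSE), g)
  expect_identical(m_rev, !m)
})

test_that("self-intersecting open curves are rejected", {
  dots <- rbind(c(0, 0, 0), c(10, 10, 0), c(10, 0, 0), c(0, 10, 0))
  cut <- curve_cut(dots, c(0, 0, 1), closed = FALSE)
  expect_error(removal_mask(cut, voxel_grid(c(2, 12, 12))),
               "self-intersecting")
})

test_that("apply_cuts zeroes the union of masks and nothing else", {
  v <- random_byte_volume(c(6, 6, 6), seed = 5)
  expect_identical(apply_cuts(v, cut_script())$data, v$data)
  u <- stack_volume(array(200, c(6, 6, 6)))
  cut <- sphere_cut(c(2.5, 2.5, 2.5), 2)
  out <- apply_cuts(u, cut)
  m <- removal_mask(cut, grid_of(u))
  expect_true(all(out$data[m] == 0))
  expect_true(all(out$data[!m] == 200))
  # order independence and idempotence with two overlapping cuts
  c1 <- sphere_cut(c(2, 2, 2), 2)
  c2 <- plane_cut(c(0, 0, 3), c(0, 0, 1))
  ab <- apply_cuts(v, cut_script(list(c1, c2)))
  ba <- apply_cuts(v, cut_script(list(c2, c1)))
  seq_ <- apply_cuts(apply_cuts(v, c1), c2)
  expect_identical(ab$data, ba$data)
  expect_identical(ab$data, seq_$data)
  expect_identical(apply_cuts(ab, cut_script(list(c1, c2)))$data, ab$data)
  # cutting never increases any voxel intensity
  expect_true(all(ab$data <= v$data))
})
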