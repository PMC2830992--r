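test_that("transform_point evaluates the mapping formulas exactly", {
  expect_equal(transform_points(identity_transform(), c(1, 2, 3)), c(1, 2, 3))
  # 90 degrees about z: (1,0,0) -> (0,1,0)
  t90 <- rigid_transform(rotation_vector_to_versor(c(0, 0, pi / 2)))
  expect_equal(transform_points(t90, c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  # the center is a fixed point of the rotation: X = C maps to X + T
  tc <- rigid_transform(rotation_vector_to_versor(c(0.3, -0.2, 0.9)),
                        translation = c(1, 2, 3), center = c(5, 6, 7))
  expect_equal(transform_points(tc, c(5, 6, 7)), c(6, 8, 10),
               tolerance = 1e-12)
  a2 <- affine_transform(2 * diag(3))
  expect_equal(transform_points(a2, c(1, 2, 3)), c(2, 4, 6))
  # zero-coefficient B-spline is the identity
  b0 <- bspline_transform(array(0, c(5, 5, 5, 3)), c(-1, -1, -1), c(4, 4, 4))
  pts <- matrix(runif(30, 0, 8), 10, 3)
  expect_equal(transform_points(b0, pts), pts)
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(2)
  t <- rigid_transform(rotation_vector_to_versor(rnorm(3)),
                       translation = rnorm(3), center = rnorm(3))
  pts <- matrix(rnorm(60), 20, 3)
  out <- transform_points(t, pts)
  expect_equal(as.numeric(dist(out)), as.numeric(dist(pts)),
               tolerance = 1e-9)
})

test_that("composition matches sequential application", {
  t <- rigid_transform(rotation_vector_to_versor(c(0, 0.4, 0)), c(1, 1, 0))
  expect_equal(transform_points(compose_transform(identity_transform(), t),
                                c(2, 3, 4)),
               transform_points(t, c(2, 3, 4)), tolerance = 1e-12)
  # two translations add
  tr <- function(u) rigid_transform(translation = u)
  comp <- compose_transform(tr(c(1, 2, 3)), tr(c(-4, 0, 2)))
  expect_equal(transform_points(comp, c(0, 0, 0)), c(-3, 2, 5),
               tolerance = 1e-12)
  # random rigid pairs, pointwise
  set.seed(3)
  for (rep in 1:5) {
    a <- rigid_transform(rotation_vector_to_versor(rnorm(3)), rnorm(3),
                         rnorm(3))
    b <- rigid_transform(rotation_vector_to_versor(rnorm(3)), rnorm(3),
                         rnorm(3))
    ab <- compose_transform(a, b)
    expect_s3_class(ab, "rigid_transform")
    pts <- matrix(rnorm(300), 100, 3)
    expect_equal(transform_points(ab, pts),
                 transform_points(a, transform_points(b, pts)),
                 tolerance = 1e-9)
  }
})

test_that("transforms round-trip through JSON losslessly", {
  t1 <- rigid_transform(rotation_vector_to_versor(c(0.12345678901234,
                                                    -0.4, 0.7)),
                        translation = c(pi, -exp(1), 1 / 3),
                        center = c(31.5, 31.5, 31.5))
  t2 <- affine_transform(matrix(rnorm(9), 3, 3), rnorm(3), rnorm(3))
  set.seed(8)
  t3 <- bspline_transform(array(rnorm(5^3 * 3), c(5, 5, 5, 3)),
                          c(-4, -4, -4), c(8, 8, 8))
  t4 <- compose_transform(t2, stackcarve:::compose_transform_keep(t1, t3))
  for (t in list(t1, t2, t3, t4)) {
    path <- file.path(tempdir(), "t.json")
    save_transform(t, path)
    r <- load_transform(path)
    pts <- matrix(seq(-5, 40, length.out = 30), 10, 3)
    expect_equal(transform_points(r, pts), transform_points(t, pts),
                 tolerance = 1e-13)
  }
  # parameter-level identity for the simple kinds
  save_transform(t1, file.path(tempdir(), "t1.json"))
  r1 <- load_transform(file.path(tempdir(), "t1.json"))
  expect_equal(r1$versor, t1$versor)
  expect_equal(r1$translation, t1$translation)
  expect_equal(r1$center, t1$center)
})

test_that("dense displacement fields evaluate the B-spline basis", {
  g <- voxel_grid(c(6, 6, 6))
  b0 <- bspline_transform(array(0, c(5, 5, 5, 3)), c(-2, -2, -2),
                          c(3.5, 3.5, 3.5))
  f <- dense_displacement_field(b0, g)
  expect_true(all(f == 0))
  # single nonzero coefficient: the field is that coefficient times the
  # tensor-product basis weight, checked against a direct basis evaluation
  coef <- array(0, c(5, 5, 5, 3))
  coef[3, 3, 3, 1] <- 2.5
  bs <- bspline_transform(coef, c(-2, -2, -2), c(3.5, 3.5, 3.5))
  pt <- c(2.2, 3.1, 1.7) # interior of the lattice support
  cubicB <- function(t) { # uniform cubic B-spline basis, support [-2, 2]
    t <- abs(t)
    ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
           ifelse(t < 2, (2 - t)^3 / 6, 0))
  }
  w <- prod(cubicB((pt - (c(-2, -2, -2) + 2 * 3.5)) / 3.5))
  d <- bspline_displacement(bs, pt)
  expect_equal(as.numeric(d), c(2.5 * w, 0, 0), tolerance = 1e-12)
  # displacement-field resampling equals transform resampling
  v <- sphere_phantom(2, c(6, 6, 6), binary = TRUE)
  field <- dense_displacement_field(bs, g)
  pts <- voxel_centers(g) + matrix(field, ncol = 3)
  vox <- sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")
  via_field <- stackcarve:::cpp_sample_trilinear(as.numeric(v$data),
                                                 dim(v$data), vox)
  via_transform <- resample(v, bs, g)
  expect_equal(array(via_field, dim = g$shape), via_transform$data,
               tolerance = 1e-6)
  # field writes to a vector NRRD and reads back
  p <- file.path(tempdir(), "field.nrrd")
  write_displacement_field(field, p)
  rf <- stackcarve:::read_nrrd(p)
  expect_equal(dim(rf), dim(field))
  expect_equal(as.numeric(rf), as.numeric(field))
})
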