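test_that("stack_volume validates geometry and intensity invariants", {
  expect_error(stack_volume(array(0, c(2, 2)), role = "byte"), "3D")
  expect_error(stack_volume(array(-1, c(2, 2, 2))), "within")
  expect_error(stack_volume(array(300, c(2, 2, 2))), "within")
  expect_error(stack_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(stack_volume(array(0.5, c(2, 2, 2)), role = "byte"),
               "non-integer")
  v <- stack_volume(array(0.5, c(2, 2, 2)), role = "real")
  expect_s3_class(v, "stack_volume")
})

test_that("binarize uses an inclusive threshold and is idempotent", {
  v <- stack_volume(array(c(0, 100, 150, 200), c(1, 2, 2)))
  b <- binarize(v, 150)
  expect_equal(as.numeric(b$data), c(0, 0, 255, 255))
  # all-zero stays all-zero at any threshold
  z <- stack_volume(array(0, c(3, 3, 3)))
  expect_true(all(binarize(z, 10)$data == 0))
  # idempotence for a range of second thresholds
  for (t2 in c(1, 127.5, 200, 255)) {
    expect_equal(binarize(b, t2)$data, b$data)
  }
  expect_error(binarize(v, 0), "threshold")
  expect_error(binarize(v, 256), "threshold")
})

test_that("global median threshold matches a sort-and-pick oracle", {
  v <- stack_volume(array(c(0, 51, 102, 153, 0, 0), c(1, 2, 3)))
  expect_equal(global_median_threshold(v), 102)
  u <- stack_volume(array(c(0, 200, 200, 200), c(1, 2, 2)))
  expect_equal(global_median_threshold(u), 200)
  for (seed in 1:10) {
    r <- random_byte_volume(c(6, 7, 5), seed = seed)
    nz <- sort(r$data[r$data > 0])
    oracle <- nz[ceiling(length(nz) / 2)]
    expect_equal(global_median_threshold(r), oracle)
    # permutation invariance
    set.seed(seed + 1000)
    perm <- array(sample(as.numeric(r$data)), dim = dim(r$data))
    expect_equal(global_median_threshold(stack_volume(perm)),
                 oracle)
  }
  expect_error(global_median_threshold(stack_volume(array(0, c(2, 2, 2)))),
               "degenerate")
})

test_that("NRRD and MetaImage round-trips are voxel-exact for byte volumes", {
  v <- random_byte_volume(c(5, 6, 7), seed = 3, spacing = c(0.5, 1, 2))
  for (ext in c("nrrd", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_stack(v, path)
    r <- read_stack(path)
    expect_identical(r$data, v$data)
    expect_equal(r$spacing, v$spacing)
    expect_equal(r$origin, v$origin)
    expect_equal(r$role, "byte")
  }
})

test_that("real averaged volumes round-trip through NRRD at full precision", {
  set.seed(4)
  v <- stack_volume(array(runif(4^3, 0, 255), c(4, 4, 4)), role = "real")
  path <- file.path(tempdir(), "real.nrrd")
  write_stack(v, path)
  expect_identical(read_stack(path)$data, v$data)
  expect_error(write_stack(v, tempdir(), format = "slice-dir"), "real-valued")
})

test_that("slice directories read in natural numeric order", {
  dirp <- file.path(tempdir(), "slices_nat")
  dir.create(dirp, showWarnings = FALSE)
  on.exit(unlink(dirp, recursive = TRUE))
  # slice s2 must come before s10 despite lexicographic order
  a <- matrix(10 / 255, 4, 4); b <- matrix(20 / 255, 4, 4)
  png::writePNG(a, file.path(dirp, "s2.png"))
  png::writePNG(b, file.path(dirp, "s10.png"))
  v <- read_stack(dirp)
  expect_equal(dim(v$data), c(2L, 4L, 4L))
  expect_equal(unique(as.numeric(v$data[1, , ])), 10)
  expect_equal(unique(as.numeric(v$data[2, , ])), 20)
})

test_that("slice-dir write/read round-trips and rejects mixed dimensions", {
  v <- random_byte_volume(c(4, 8, 8), seed = 9)
  dirp <- file.path(tempdir(), "slices_rt")
  on.exit(unlink(dirp, recursive = TRUE))
  write_stack(v, dirp, format = "slice-dir")
  expect_length(list.files(dirp, pattern = "png$"), 4L)
  r <- read_stack(dirp)
  expect_identical(r$data, v$data)
  png::writePNG(matrix(0, 3, 3), file.path(dirp, "slice_9999.png"))
  expect_error(read_stack(dirp), "mixed")
  expect_error(read_stack(file.path(tempdir(), "empty_dir_x")), "not found")
})

test_that("block-mean downsampling halves the grid and recenters the origin", {
  v <- stack_volume(array(rep(c(0, 255), each = 4), c(2, 2, 2)))
  d <- downsample_volume(v, 2L)
  expect_equal(dim(d$data), c(1L, 1L, 1L))
  expect_equal(as.numeric(d$data), mean(v$data))
  expect_equal(d$spacing, c(2, 2, 2))
  expect_equal(d$origin, c(0.5, 0.5, 0.5))
})
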