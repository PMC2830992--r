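test_that("the base shape is a single connected blob of sane size", {
  spec <- population_spec()
  base <- make_base_shape(spec)
  expect_equal(connected_components(base), 1L)
  frac <- mean(base$data > 0)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.30)
  expect_true(all(base$data %in% c(0, 255)))
  expect_identical(make_base_shape(spec)$data, base$data)
})

test_that("population generation is a pure function of spec and seed", {
  spec <- population_spec(n_subjects = 3, shape = c(32, 32, 32),
                          seed = 5)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  for (i in 1:3) expect_identical(p1$subjects[[i]]$data, p2$subjects[[i]]$data)
  p3 <- generate_population(population_spec(n_subjects = 3,
                                            shape = c(32, 32, 32), seed = 6))
  expect_false(identical(p1$subjects[[1]]$data, p3$subjects[[1]]$data))
})

test_that("zero-magnitude populations reproduce the base exactly", {
  spec <- population_spec(n_subjects = 2, shape = c(32, 32, 32),
                          rotation_deg = 0, translation_vox = 0,
                          scale_range = c(1, 1), shear_max = 0,
                          deform_amp_vox = 0, seed = 1)
  pop <- generate_population(spec)
  for (s in pop$subjects) expect_identical(s$data, pop$base$data)
})

test_that("subjects reproduce from the base through their ground truth", {
  spec <- population_spec(n_subjects = 3, shape = c(32, 32, 32),
                          translation_vox = 2, seed = 9)
  pop <- generate_population(spec)
  for (i in seq_along(pop$subjects)) {
    rebuilt <- binarize(resample(pop$base,
                                 pop$ground_truth[[i]]$composed,
                                 grid_of(pop$base)), 127.5)
    expect_identical(rebuilt$data, pop$subjects[[i]]$data)
  }
})

test_that("excessive deformation amplitudes are rejected", {
  expect_error(population_spec(shape = c(32, 32, 32), deform_amp_vox = 10),
               "fold")
})

test_that("salt noise flips only background voxels at the given rate", {
  spec <- population_spec(n_subjects = 2, shape = c(32, 32, 32),
                          noise_rate = 0.01, seed = 3)
  clean <- generate_population(population_spec(n_subjects = 2,
                                               shape = c(32, 32, 32),
                                               noise_rate = 0, seed = 3))
  noisy <- generate_population(spec)
  added <- noisy$subjects[[1]]$data - clean$subjects[[1]]$data
  expect_true(all(added %in% c(0, 255)))
  rate <- sum(added == 255) / sum(clean$subjects[[1]]$data == 0)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("fixtures round-trip through disk", {
  spec <- population_spec(n_subjects = 2, shape = c(24, 24, 24), seed = 4)
  pop <- generate_population(spec)
  dirp <- file.path(tempdir(), "fixture_pop")
  on.exit(unlink(dirp, recursive = TRUE))
  write_fixture(pop, dirp)
  s1 <- read_stack(file.path(dirp, "S1.nrrd"))
  expect_identical(s1$data, pop$subjects[[1]]$data)
  t1 <- load_transform(file.path(dirp, "S1_truth.json"))
  pts <- matrix(runif(30, 0, 23), 10, 3)
  expect_equal(transform_points(t1, pts),
               transform_points(pop$ground_truth[[1]]$composed, pts),
               tolerance = 1e-12)
})
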