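test_that("sharpness ratio counts unanimity voxels exactly", {
  b <- random_binary_volume(c(6, 6, 6), seed = 1)
  expect_equal(sharpness_ratio(b), 1)
  v <- stack_volume(array(c(0, 255, 127.5, 255), c(1, 2, 2)), role = "real")
  expect_equal(sharpness_ratio(v), 2 / 3)
  for (seed in 1:10) {
    set.seed(seed)
    avg <- stack_volume(array(sample(c(0, 63.75, 127.5, 191.25, 255),
                                     5^3, replace = TRUE), c(5, 5, 5)),
                        role = "real")
    oracle <- sum(avg$data == 255) / sum(avg$data > 0)
    expect_equal(sharpness_ratio(avg), oracle)
  }
  expect_error(sharpness_ratio(stack_volume(array(0, c(2, 2, 2)))),
               "degenerate")
})

test_that("dice follows its set formula and conventions", {
  a <- random_binary_volume(c(6, 6, 6), seed = 2)
  expect_equal(dice(a, a), 1)
  d1 <- stack_volume(array(c(255, 0, 0, 0), c(1, 2, 2)))
  d2 <- stack_volume(array(c(0, 0, 0, 255), c(1, 2, 2)))
  expect_equal(dice(d1, d2), 0)
  # |A| = |B| = 4 with overlap 2 -> 0.5
  x <- stack_volume(array(c(rep(255, 4), rep(0, 4)), c(2, 2, 2)))
  y <- stack_volume(array(c(0, 0, rep(255, 4), 0, 0), c(2, 2, 2)))
  expect_equal(dice(x, y), 0.5)
  # both empty -> 1 by convention
  z <- stack_volume(array(0, c(2, 2, 2)))
  expect_equal(dice(z, z), 1)
  expect_error(dice(a, stack_volume(a$data, spacing = c(2, 1, 1))),
               "different grids")
})

test_that("rmse matches its closed form and links to dice", {
  a <- random_binary_volume(c(8, 8, 8), seed = 3)
  expect_equal(rmse(a, a), 0)
  for (seed in 1:10) {
    b <- random_binary_volume(c(8, 8, 8), seed = seed + 50)
    # closed form: binary volumes differing at k of N voxels
    k <- sum(a$data != b$data)
    N <- length(a$data)
    expect_equal(rmse(a, b), 255 * sqrt(k / N))
    expect_equal(rmse(a, b), rmse(b, a))
    # exact identity: rmse^2 N / 255^2 = |A| + |B| - 2|A int B|
    A <- sum(a$data == 255); B <- sum(b$data == 255)
    AB <- sum(a$data == 255 & b$data == 255)
    expect_equal(rmse(a, b)^2 * N / 255^2, A + B - 2 * AB)
    # and dice can be rewritten through the same overlap count
    expect_equal(dice(a, b), 2 * AB / (A + B))
  }
  # triangle inequality on binary volumes
  b <- random_binary_volume(c(8, 8, 8), seed = 60)
  c_ <- random_binary_volume(c(8, 8, 8), seed = 61)
  expect_lte(rmse(a, c_), rmse(a, b) + rmse(b, c_) + 1e-12)
})

test_that("real-valued rmse equals a brute-force loop", {
  set.seed(9)
  a <- stack_volume(array(runif(5^3, 0, 255), c(5, 5, 5)), role = "real")
  b <- stack_volume(array(runif(5^3, 0, 255), c(5, 5, 5)), role = "real")
  acc <- 0
  for (i in seq_along(a$data)) acc <- acc + (a$data[i] - b$data[i])^2
  expect_equal(rmse(a, b), sqrt(acc / length(a$data)))
})

test_that("binarized volumes are perfectly sharp", {
  set.seed(5)
  avg <- stack_volume(array(runif(6^3, 0, 255), c(6, 6, 6)), role = "real")
  for (t in c(20, 127.5, 250)) {
    expect_equal(sharpness_ratio(binarize(avg, t)), 1)
  }
})

test_that("comparison reports are symmetric with unit diagonal", {
  a <- small_blob(c(16, 16, 16), 4)
  b <- apply_cuts(a, sphere_cut(c(4, 4, 4), 2))
  rep <- comparison_report(list(A = a, B = b, C = a), averaged = a)
  expect_equal(diag(rep$dice), c(A = 1, B = 1, C = 1))
  expect_equal(diag(rep$rmse), c(A = 0, B = 0, C = 0))
  expect_equal(rep$dice, t(rep$dice))
  expect_equal(rep$rmse, t(rep$rmse))
  expect_equal(rep$dice["A", "C"], 1)
  # identical models give CV 0
  rep2 <- comparison_report(list(a, a))
  expect_equal(rep2$summary$mean_dice, 1)
  expect_equal(rep2$summary$cv_dice, 0)
  # CV equals SD/mean computed by an independent one-pass oracle
  off <- rep$dice[upper.tri(rep$dice)]
  n <- length(off)
  m1 <- sum(off) / n
  sd1 <- sqrt((sum(off^2) - n * m1^2) / (n - 1))
  expect_equal(rep$summary$cv_dice, sd1 / m1, tolerance = 1e-12)
  # serialization writes JSON + CSV
  jp <- file.path(tempdir(), "rep.json")
  write_comparison_report(rep, json_path = jp,
                          csv_prefix = file.path(tempdir(), "rep"))
  expect_true(file.exists(jp))
  expect_true(file.exists(file.path(tempdir(), "rep_dice.csv")))
})

test_that("neutral alignment improves a known rigid offset", {
  blob <- small_blob(c(24, 24, 24), 6)
  C <- center_of_mass(blob)
  gt <- rigid_transform(rotation_vector_to_versor(c(0, 0, 0.12)),
                        c(2, -1, 1), C)
  offset <- binarize(resample(blob, gt, grid_of(blob)), 127.5)
  pre <- dice(offset, blob)
  aligned <- align_for_comparison(list(offset), blob)
  expect_length(aligned, 1L)
  expect_gt(dice(aligned[[1]], blob), pre)
  # aligning an already-aligned model barely changes Dice
  again <- align_for_comparison(aligned, blob)
  expect_lt(abs(dice(again[[1]], blob) - dice(aligned[[1]], blob)), 0.005)
})
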