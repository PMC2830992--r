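# Shared fixtures, built in code. Heavy protocol runs used by several
# acceptance checks are computed once and memoized here.

random_byte_volume <- function(shape = c(8, 8, 8), seed = 1,
                               spacing = c(1, 1, 1)) {
  set.seed(seed)
  stack_volume(array(sample(0:255, prod(shape), replace = TRUE), dim = shape),
               spacing = spacing)
}

random_binary_volume <- function(shape = c(8, 8, 8), seed = 1, p = 0.4) {
  set.seed(seed)
  stack_volume(array(ifelse(stats::runif(prod(shape)) < p, 255, 0),
                     dim = shape))
}

small_blob <- function(shape = c(24, 24, 24), r = 6) {
  g <- voxel_grid(shape)
  ctr <- (shape[3:1] - 1) / 2
  pts <- voxel_centers(g)
  d <- sqrt(rowSums(sweep(pts, 2, ctr, "-")^2))
  stack_volume(array(ifelse(d <= r, 255, 0), dim = shape))
}

# asymmetric rigid-body phantom: three unequal overlapping balls (no
# rotational symmetry, unlike small_blob)
asym_blob <- function(shape = c(24, 24, 24)) {
  g <- voxel_grid(shape)
  pts <- voxel_centers(g)
  balls <- list(list(c(9, 11, 12), 6), list(c(15, 11, 11), 4),
                list(c(12, 16, 13), 3))
  inside <- rep(FALSE, nrow(pts))
  for (b in balls) {
    inside <- inside |
      (rowSums(sweep(pts, 2, b[[1]], "-")^2) <= b[[2]]^2)
  }
  stack_volume(array(ifelse(inside, 255, 0), dim = shape))
}

# independent point-in-polygon oracle: winding-angle summation
winding_inside <- function(px, py, poly) {
  vapply(seq_along(px), function(r) {
    dx <- poly[, 1] - px[r]; dy <- poly[, 2] - py[r]
    a <- atan2(dy, dx)
    d <- diff(c(a, a[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# memoized heavy acceptance computations (population protocol runs)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_population <- function(which = c("a", "neutral")) {
  which <- match.arg(which)
  key <- paste0("pop_", which)
  if (is.null(.acceptance_cache[[key]])) {
    seed <- if (which == "a") 101L else 202L
    .acceptance_cache[[key]] <- generate_population(population_spec(seed = seed))
  }
  .acceptance_cache[[key]]
}

acceptance_protocol_run <- function(which = c("ref1", "ref2", "neutral")) {
  which <- match.arg(which)
  key <- paste0("run_", which)
  if (is.null(.acceptance_cache[[key]])) {
    pop <- acceptance_population(if (which == "neutral") "neutral" else "a")
    ref <- if (which == "ref2") 2L else 1L
    .acceptance_cache[[key]] <- suppressWarnings(
      iterative_average(pop$subjects, averaging_protocol(reference_index = ref)))
  }
  .acceptance_cache[[key]]
}
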