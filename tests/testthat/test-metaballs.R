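test_that("the kernel has compact support and unit peak", {
  expect_equal(kernel_value(0, 3), 1)
  expect_equal(kernel_value(3, 3), 0)
  expect_equal(kernel_value(10, 3), 0)
  d <- seq(0, 3, length.out = 50)
  expect_true(all(diff(kernel_value(d, 3)) < 0))
  expect_error(kernel_value(-1, 3), "non-negative")
})

test_that("the rendered surface radius follows the closed form", {
  # numeric root of the kernel at the iso-level, independent of the constant
  R <- 7
  root <- uniroot(function(d) kernel_value(d, R) - 0.5, c(0, R))$root
  expect_equal(root / R, kernel_surface_factor(0.5), tolerance = 1e-6)
  expect_equal(kernel_surface_factor(0.5), 0.4542, tolerance = 1e-3)
})

test_that("field summation is additive and the spatial index is exact", {
  empty <- meta_object(matrix(numeric(0), 0, 3), numeric(0), 1)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(field_value(empty, pts), rep(0, 10))
  one <- meta_object(matrix(0, 1, 3), 2, 1)
  two <- meta_object(matrix(0, 2, 3), c(2, 2), 1)
  expect_equal(field_value(two, pts), 2 * field_value(one, pts))
  withr::with_seed(99, {
    centers <- matrix(runif(3000, -20, 20), ncol = 3)
    radii <- runif(1000, 0.3, 3)
    q <- matrix(runif(600, -22, 22), ncol = 3)
  })
  mo <- meta_object(centers, radii, 1)
  expect_equal(field_value(mo, q, method = "indexed"),
               field_value(mo, q, method = "brute"), tolerance = 1e-9)
})

test_that("segment skinning matches the counting oracle", {
  a <- list(position = c(0, 0, 0), radius = 1)
  b <- list(position = c(10, 0, 0), radius = 1)
  mo <- skin_segment(a, b, 1)
  expect_equal(nrow(mo$centers), 11)
  expect_equal(diff(mo$centers[, 1]), rep(1, 10))
  expect_equal(mo$influence,
               rep(1 / kernel_surface_factor(), 11))
  # zero-length segment
  z <- skin_segment(a, list(position = c(0, 0, 0), radius = 1))
  expect_equal(nrow(z$centers), 1)
  # linear radius interpolation: midpoint of (1, 3) has surface radius 2
  mo2 <- skin_segment(a, list(position = c(10, 0, 0), radius = 3), 1)
  mid <- which.min(abs(mo2$centers[, 1] - 5))
  expect_equal(mo2$influence[mid] * kernel_surface_factor(), 2)
  # ceil(L / step) + 1 oracle over random lengths
  withr::with_seed(5, lens <- runif(20, 0.1, 30))
  for (L in lens) {
    got <- nrow(skin_segment(a, list(position = c(L, 0, 0), radius = 1))$centers)
    expect_equal(got, ceiling(L) + 1)
  }
})

test_that("arbor skinning is the per-segment union without deduplication", {
  m <- small_astro(seed = 21)
  m <- resample_morphology(m)
  secs <- morphology_sections(m)
  a1 <- secs[vapply(secs, `[[`, 1L, "arbor") == 1]
  # oracle: total = sum over every segment of its own skin count
  oracle <- 0L
  rmin <- Inf
  for (sec in a1) {
    ss <- section_samples(m, sec)
    rmin <- min(rmin, min(ss$radius))
    for (i in seq_len(nrow(ss) - 1))
      oracle <- oracle + nrow(skin_segment(ss[i, ], ss[i + 1, ])$centers)
  }
  mo <- skin_arbor(m, 1)
  expect_equal(nrow(mo$centers), oracle)
  expect_equal(mo$resolution, rmin)
  expect_true(all(is.finite(field_value(mo, mo$centers))))
})

test_that("blending concatenates balls and takes the minimum resolution", {
  x <- meta_object(matrix(rnorm(9), 3), c(1, 2, 3), 0.5)
  y <- meta_object(matrix(rnorm(6), 2), c(1, 1), 0.2)
  expect_identical(blend(list(x)), x)
  b <- blend(list(x, y))
  expect_equal(nrow(b$centers), 5)
  expect_equal(b$resolution, 0.2)
  pts <- matrix(rnorm(300), ncol = 3)
  expect_equal(field_value(b, pts),
               field_value(x, pts) + field_value(y, pts), tolerance = 1e-12)
  expect_error(blend(list()), "at least one")
})

test_that("polygonization of one metaball is a sphere of the effective radius", {
  mo <- meta_object(matrix(0, 1, 3), 10, resolution = 0.5)
  m <- polygonize(mo)
  expect_equal(euler_characteristic(m), 2)
  nm <- count_non_manifold(m)
  expect_equal(nm$edges, 0)
  expect_equal(nm$boundary_edges, 0)
  r_eff <- 10 * kernel_surface_factor()
  v_exact <- 4 / 3 * pi * r_eff^3
  expect_lt(abs(mesh_volume(m) - v_exact) / v_exact, 0.05)
  # grid-refinement convergence: halved spacing moves the volume < 2%
  m2 <- polygonize(mo, spacing = 0.25)
  expect_lt(abs(mesh_volume(m2) - mesh_volume(m)) / mesh_volume(m), 0.02)
})

test_that("support-disjoint balls polygonize into separate components", {
  r_s <- 2 * kernel_surface_factor()  # rendered radius of an R = 2 ball
  # surfaces touching (surface gap 0): one component
  near <- meta_object(rbind(c(0, 0, 0), c(2 * r_s, 0, 0)), c(2, 2), 0.1)
  expect_length(split_partitions(polygonize(near)), 1)
  # influence regions disjoint: two components
  far <- meta_object(rbind(c(0, 0, 0), c(4.5, 0, 0)), c(2, 2), 0.1)
  expect_length(split_partitions(polygonize(far)), 2)
})

test_that("polygonize fails helpfully on coarse grids and empty objects", {
  tiny <- meta_object(matrix(0, 1, 3), 0.5, resolution = 5)
  expect_error(polygonize(tiny), "too coarse")
  empty <- meta_object(matrix(numeric(0), 0, 3), numeric(0), 1)
  expect_error(polygonize(empty), "empty")
})
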