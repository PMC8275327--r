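test_that("simple subdivision follows the midpoint rule", {
  p <- endfoot_patch(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                     c(1, 2, 3), rbind(c(1, 2, 3)))
  s1 <- subdivide_patch(p, subdivision_spec(1, "simple"))
  expect_equal(nrow(s1$triangles), 4)
  expect_equal(nrow(s1$vertices), 6)
  # original vertices untouched, new ones are edge midpoints
  expect_equal(s1$vertices[1:3, ], p$vertices)
  mids <- s1$vertices[4:6, ]
  expected_mids <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(mids[order(mids[, 1], mids[, 2]), ],
               expected_mids[order(expected_mids[, 1], expected_mids[, 2]), ])
  # thickness at midpoints = mean of edge endpoints
  expect_setequal(s1$thickness[4:6], c(1.5, 2.5, 2))
  # identity at level 0; 4^3 growth at level 3
  expect_identical(subdivide_patch(p, subdivision_spec(0)), p)
  s3 <- subdivide_patch(p, subdivision_spec(3))
  expect_equal(nrow(s3$triangles), 64)
  # thickness bounds conserved
  expect_gte(min(s3$thickness), min(p$thickness))
  expect_lte(max(s3$thickness), max(p$thickness))
})

test_that("smooth subdivision smooths the interior but keeps the outline", {
  p <- square_patch(n = 4, size = 9, thickness = 2)
  s <- subdivide_patch(p, subdivision_spec(2, "smooth"))
  expect_equal(nrow(s$triangles), 16 * nrow(p$triangles))
  # the flat patch stays in its plane and inside the original square
  expect_true(all(abs(s$vertices[, 3]) < 1e-12))
  expect_gte(min(s$vertices[, 1:2]), -1e-9)
  expect_lte(max(s$vertices[, 1:2]), 9 + 1e-9)
  expect_gte(min(s$thickness), min(p$thickness))
  expect_lte(max(s$thickness), max(p$thickness))
  # still an open connected manifold
  expect_length(astroskin:::endfoot_violations(s), 0)
})

test_that("required_levels halves the longest edge down to the thickness", {
  # max edge 8, min thickness 1: 8 -> 4 -> 2 -> 1 needs 3 levels
  p <- endfoot_patch(rbind(c(0, 0, 0), c(8, 0, 0), c(4, 3, 0)),
                     c(1, 1.5, 4), rbind(c(1, 2, 3)))
  expect_equal(required_levels(p), 3)
  sub <- subdivide_patch(p, subdivision_spec(required_levels(p)))
  expect_lte(astroskin:::max_edge_length(sub), min(p$thickness))
  # already fine: 0 levels
  fine <- endfoot_patch(rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0)),
                        c(1, 1, 1), rbind(c(1, 2, 3)))
  expect_equal(required_levels(fine), 0)
  # cap at 6 with a warning
  huge <- endfoot_patch(rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 800, 0)),
                        c(0.1, 0.1, 0.1), rbind(c(1, 2, 3)))
  expect_warning(L <- required_levels(huge), "capped")
  expect_equal(L, 6)
})

test_that("skinning a subdivided endfoot yields one closed component", {
  p <- square_patch(n = 3, size = 10, thickness = 2)
  # unsubdivided: vertex spacing 5 exceeds thickness 2
  expect_error(skin_endfoot(p), "fragmentation")
  sub <- subdivide_patch(p, subdivision_spec(required_levels(p)))
  mo <- skin_endfoot(sub)
  expect_equal(nrow(mo$centers), nrow(sub$vertices))
  expect_equal(mo$influence,
               sub$thickness / 2 / kernel_surface_factor())
  mesh <- polygonize(mo)
  expect_length(split_partitions(mesh), 1)
  expect_equal(euler_characteristic(mesh), 2)
  expect_equal(count_non_manifold(mesh)$edges, 0)
  # thickness-as-radius flag doubles the surface radius
  mo2 <- skin_endfoot(sub, thickness_is_radius = TRUE)
  expect_equal(mo2$influence, 2 * mo$influence)
})
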