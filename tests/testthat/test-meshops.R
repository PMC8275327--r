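test_that("partition splitting matches a union-find oracle", {
  one <- icosphere(1, c(0, 0, 0), 2)
  expect_length(split_partitions(one), 1)
  two <- generate_defect_mesh("two_shells", seed = 3)
  parts <- split_partitions(two)
  expect_length(parts, 2)
  # larger (outer) shell first
  expect_gt(mesh_volume(parts[[1]]), mesh_volume(parts[[2]]))
  # oracle: graph components over shared vertices (igraph)
  g <- igraph::graph_from_edgelist(
    rbind(two$faces[, 1:2], two$faces[, 2:3]), directed = FALSE)
  comp <- igraph::components(g)$membership
  expect_equal(length(unique(comp[two$faces[, 1]])), length(parts))
  expect_equal(sum(vapply(parts, n_faces, integer(1))), n_faces(two))
})

test_that("interior partition removal keeps the enclosing shell", {
  two <- generate_defect_mesh("two_shells", seed = 4)
  outer <- remove_interior_partition(two)
  expect_equal(mesh_volume(outer), mesh_volume(split_partitions(two)[[1]]))
  expect_error(remove_interior_partition(icosphere(1)), "2 partitions")
  # non-nested spheres are refused
  a <- icosphere(1, c(0, 0, 0), 1)
  b <- icosphere(1, c(5, 0, 0), 2)
  apart <- tri_mesh(rbind(a$vertices, b$vertices),
                    rbind(a$faces, b$faces + nrow(a$vertices)))
  expect_error(remove_interior_partition(apart), "nested")
})

test_that("non-manifold counting flags constructed defects only", {
  clean <- icosphere(1, c(0, 0, 0), 2)
  expect_equal(count_non_manifold(clean),
               list(edges = 0L, vertices = 0L, boundary_edges = 0L))
  fin <- generate_defect_mesh("fin", seed = 5)
  nm <- count_non_manifold(fin)
  expect_equal(nm$edges, 1)
  # three triangles sharing one edge, built directly
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  F3 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_equal(count_non_manifold(tri_mesh(V, F3))$edges, 1)
  hole <- generate_defect_mesh("hole", seed = 5)
  expect_equal(count_non_manifold(hole)$boundary_edges, 3)
})

test_that("self-intersection counts agree with the all-pairs oracle", {
  expect_equal(as.integer(detect_self_intersections(icosphere(1))), 0)
  # random triangle soup: indexed path must equal brute force
  withr::with_seed(31, {
    V <- matrix(runif(150 * 3, 0, 4), ncol = 3)
  })
  F2 <- matrix(seq_len(150), ncol = 3, byrow = TRUE)  # 50 disjoint-index tris
  soup <- tri_mesh(V, F2)
  n_idx <- as.integer(detect_self_intersections(soup, "indexed"))
  n_brute <- as.integer(detect_self_intersections(soup, "brute"))
  expect_equal(n_idx, n_brute)
  expect_gt(n_brute, 0)  # a dense soup certainly intersects somewhere
})

test_that("decimation reaches the target while preserving shape", {
  sph <- icosphere(2, c(1, 0, -1), 4)  # 5120 faces
  dec <- decimate(sph, 0.1)
  expect_lte(n_faces(dec), floor(0.1 * n_faces(sph)) + 1)
  expect_lt(abs(mesh_volume(dec) - mesh_volume(sph)) / mesh_volume(sph),
            0.05)
  # bounding extents within 1%
  bb_in <- apply(sph$vertices, 2, range)
  bb_out <- apply(dec$vertices, 2, range)
  expect_lt(max(abs(bb_in - bb_out)) / max(bb_in[2, ] - bb_in[1, ]), 0.01)
  # Euler characteristic of the closed genus-0 mesh is preserved
  expect_equal(euler_characteristic(dec), 2)
  expect_equal(count_non_manifold(dec)$edges, 0)
  # near-identity ratio
  dec2 <- decimate(sph, 0.999)
  expect_gte(n_faces(dec2), 0.99 * n_faces(sph))
  expect_error(decimate(sph, 1.5), "ratio")
})

test_that("watertight repair fixes the injected defect classes", {
  # hole: one missing triangle
  hole <- generate_defect_mesh("hole", seed = 6)
  full_vol <- mesh_volume(icosphere(1, c(0, 0, 0), 2))
  fixed <- repair_watertight(hole)
  expect_true(attr(fixed, "qc")$watertight)
  expect_lt(abs(mesh_volume(fixed) - full_vol) / full_vol, 0.01)
  # fin: non-manifold edge removed
  fin <- generate_defect_mesh("fin", seed = 6)
  expect_true(attr(repair_watertight(fin), "qc")$watertight)
  # inverted: orientation restored outward
  inv <- generate_defect_mesh("inverted", seed = 6)
  expect_lt(mesh_volume(inv, signed = TRUE), 0)
  fixed_inv <- repair_watertight(inv)
  expect_gt(mesh_volume(fixed_inv, signed = TRUE), 0)
  # two shells: largest kept
  shells <- generate_defect_mesh("two_shells", seed = 6)
  kept <- repair_watertight(shells)
  expect_equal(mesh_metrics(kept)$partition_count, 1L)
  # idempotence on repaired meshes and no-op on clean input
  again <- repair_watertight(fixed)
  expect_identical(again$faces, fixed$faces)
  clean <- icosphere(1, c(0, 0, 0), 2)
  expect_equal(n_faces(repair_watertight(clean)), n_faces(clean))
})

test_that("mesh metrics reproduce closed-form area and volume", {
  cube <- unit_cube_mesh()
  met <- mesh_metrics(cube)
  expect_equal(met$surface_area, 6)
  expect_equal(met$volume, 1)
  expect_true(met$watertight)
  sph <- icosphere(1, c(0, 0, 0), 4)
  expect_lt(abs(mesh_volume(sph) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  # area invariant under rigid transforms
  rot <- withr::with_seed(8, qr.Q(qr(matrix(rnorm(9), 3))))
  moved <- tri_mesh(sweep(sph$vertices %*% rot, 2, c(3, -2, 7), "+"),
                    sph$faces)
  expect_equal(mesh_area(moved), mesh_area(sph), tolerance = 1e-9)
})

test_that("Hausdorff RMS behaves like a calibrated distance", {
  sph <- icosphere(1, c(0, 0, 0), 3)
  expect_equal(hausdorff_rms(sph, sph, samples = 2000, seed = 3), 0)
  big <- icosphere(1.01, c(0, 0, 0), 3)
  h <- hausdorff_rms(sph, big, samples = 5000, seed = 3)
  expected <- 0.01 / astroskin:::bbox_diagonal(sph$vertices)
  expect_lt(abs(h - expected) / expected, 0.25)
  # deterministic given the seed
  expect_identical(h, hausdorff_rms(sph, big, samples = 5000, seed = 3))
})
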