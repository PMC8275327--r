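test_that("origin-to-arbor marching matches the per-segment oracle", {
  soma <- list(position = c(0, 0, 0), radius = 5)
  expect_equal(nrow(skin_soma_marching(soma)$centers), 1)
  root <- list(position = c(10, 0, 0), radius = 1)
  mo <- skin_soma_marching(soma, list(root))
  oracle <- nrow(skin_segment(soma, root)$centers)
  expect_equal(nrow(mo$centers), oracle + 1)
  # radii taper linearly from soma to root along the somatic segment
  seg <- skin_segment(soma, root)
  r_surf <- seg$influence * kernel_surface_factor()
  expect_equal(r_surf[1], 5)
  expect_equal(r_surf[length(r_surf)], 1)
  expect_true(all(diff(r_surf) < 0))
  # arbor order does not matter
  roots <- list(root, list(position = c(0, 8, 0), radius = 2),
                list(position = c(0, 0, 9), radius = 1.5))
  a <- skin_soma_marching(soma, roots)
  b <- skin_soma_marching(soma, rev(roots))
  key <- function(mo) {
    o <- do.call(order, as.data.frame(cbind(mo$centers, mo$influence)))
    cbind(mo$centers, mo$influence)[o, ]
  }
  expect_equal(key(a), key(b))
})

test_that("the soft-body soma keeps its topology and relaxes its energy", {
  soma <- list(position = c(1, 2, 3), radius = 6)
  # no arbors: no external forces, the icosphere is already at rest
  s0 <- simulate_soma_surface(soma)
  expect_equal(euler_characteristic(s0), 2)
  expect_lt(abs(mesh_volume(s0) - 4 / 3 * pi * 6^3) / (4 / 3 * pi * 6^3),
            0.02)
  roots <- list(list(position = c(13, 2, 3), radius = 1.5),
                list(position = c(1, 16, 3), radius = 1))
  s <- simulate_soma_surface(soma, roots)
  expect_equal(euler_characteristic(s), 2)
  expect_equal(nrow(s$faces), nrow(s0$faces))  # connectivity never edited
  # spring energy is non-increasing once the pulls are frozen
  en <- attr(s, "energy")
  ps <- attr(s, "pull_steps")
  expect_true(all(diff(en[(ps + 1):length(en)]) <= 1e-9))
  # deterministic given the seed
  s2 <- simulate_soma_surface(soma, roots)
  expect_identical(s$vertices, s2$vertices)
})

test_that("uniform remeshing yields an evenly spaced on-surface cloud", {
  sph <- icosphere(1, c(0, 0, 0), 3)
  cloud <- uniform_remesh(sph, 0.2, seed = 2)
  budget <- mesh_area(sph) / (0.2^2 * sqrt(3) / 2)
  expect_gt(nrow(cloud$vertices), 0.7 * budget)
  expect_lt(nrow(cloud$vertices), 1.3 * budget)
  nn <- astroskin:::cpp_nn_distance(cloud$vertices)
  expect_lt(sd(nn) / mean(nn), 0.35)
  # all points within one spacing of the input surface
  d <- point_mesh_distance(cloud$vertices, sph)$distance
  expect_lt(max(d), 0.2)
  # normals point outward on a sphere
  expect_true(all(rowSums(cloud$normals * cloud$vertices) > 0))
  expect_error(uniform_remesh(sph, 10), "diameter")
})

test_that("hybrid soma skinning reproduces the input surface", {
  surf <- icosphere(5, c(0, 0, 0), 3)
  cloud <- uniform_remesh(surf, 0.4, seed = 1)
  expect_error(skin_soma_hybrid(cloud, 0.3), "fragment")
  mo <- skin_soma_hybrid(cloud, 0.5)
  expect_equal(nrow(mo$centers), nrow(cloud$vertices))
  mesh <- polygonize(mo)
  parts <- split_partitions(mesh)
  expect_length(parts, 2)
  v_sphere <- 4 / 3 * pi * 5^3
  expect_lt(abs(mesh_volume(parts[[1]]) - v_sphere) / v_sphere, 0.10)
  expect_gt(mesh_volume(parts[[1]]), mesh_volume(parts[[2]]))
  # the exterior partition encloses every input vertex
  inside <- vapply(seq_len(nrow(cloud$vertices)), function(i)
    astroskin:::point_in_mesh(parts[[1]], cloud$vertices[i, ]), logical(1))
  expect_true(all(inside))
  # pruning the interior leaves a closed genus-0 surface
  pruned <- remove_interior_partition(mesh)
  expect_equal(euler_characteristic(pruned), 2)
  expect_equal(count_non_manifold(pruned)$edges, 0)
})
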