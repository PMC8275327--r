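test_that("the generator is deterministic and leaves no RNG footprint", {
  a <- generate_astrocyte(synth_astro_params(seed = 42))
  b <- generate_astrocyte(synth_astro_params(seed = 42))
  expect_identical(a$samples, b$samples)
  for (i in seq_along(a$endfeet)) {
    expect_identical(a$endfeet[[i]]$vertices, b$endfeet[[i]]$vertices)
    expect_identical(a$endfeet[[i]]$thickness, b$endfeet[[i]]$thickness)
  }
  # no global random state touched
  withr::with_seed(123, x1 <- runif(1))
  withr::with_seed(123, {
    invisible(generate_astrocyte(synth_astro_params(seed = 7, n_arbors = 1,
                                                    max_branch_order = 1,
                                                    oversample_spacing = 0.2,
                                                    n_endfeet = 0)))
    x2 <- runif(1)
  })
  expect_identical(x1, x2)
})

test_that("generated morphologies honour the construction invariants", {
  p <- synth_astro_params(seed = 42)
  m <- generate_astrocyte(p)
  expect_equal(nrow(arbor_roots(m)), p$n_arbors)
  # radii strictly decrease away from the soma
  s <- m$samples
  pr <- s$radius[match(s$parent_id, s$id)]
  nonroot <- !is.na(s$parent_id)
  expect_true(all(s$radius[nonroot] < pr[nonroot]))
  # closed-form minimum skeleton radius
  expect_equal(min(s$radius), p$soma_radius * p$taper^p$max_branch_order,
               tolerance = 1e-9)
  # always passes validation
  expect_true(validate_morphology(m)$valid)
  # endfeet exercise the subdivision path
  expect_length(m$endfeet, p$n_endfeet)
  expect_true(all(vapply(m$endfeet, required_levels, integer(1)) >= 1))
  expect_true(all(vapply(m$endfeet, function(e)
    min(e$thickness) >= 0.5 && max(e$thickness) <= 1.5, logical(1))))
})

test_that("defect meshes carry exactly the named defect", {
  hole <- generate_defect_mesh("hole", seed = 2)
  es <- astroskin:::cpp_edge_stats(hole$faces)
  expect_equal(es$n_boundary, 3)  # one triangular boundary loop
  expect_equal(es$n_nonmanifold, 0)
  fin <- generate_defect_mesh("fin", seed = 2)
  expect_gte(count_non_manifold(fin)$edges, 1)
  inv <- generate_defect_mesh("inverted", seed = 2)
  expect_lt(mesh_volume(inv, signed = TRUE), 0)
  shells <- generate_defect_mesh("two_shells", seed = 2)
  expect_length(split_partitions(shells), 2)
})
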