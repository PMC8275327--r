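test_that("greedy resampling matches an independent scan oracle", {
  s <- straight_section(n = 101, span = 10, radius = 1)
  out <- adaptive_resample_section(s, resampling_policy(1))
  # independent oracle: walk and keep at >= factor * radius spacing
  oracle_keep <- function(x, r, f) {
    kept <- 1
    for (i in 2:(length(x) - 1))
      if (abs(x[i] - x[kept[length(kept)]]) >= f * r) kept <- c(kept, i)
    unique(c(kept, length(x)))
  }
  expect_equal(out$id, s$id[oracle_keep(s$x, 1, 1)])
  expect_equal(nrow(out), 11)
  expect_equal(out$x, 0:10)
})

test_that("short and already-sparse sections pass through unchanged", {
  s2 <- straight_section(n = 2, span = 5)
  expect_equal(adaptive_resample_section(s2), s2)
  sparse <- straight_section(n = 6, span = 50, radius = 1)  # spacing 10 x r
  expect_equal(adaptive_resample_section(sparse), sparse)
})

test_that("morphology resampling is idempotent and preserves topology", {
  m <- small_astro(seed = 11)
  r1 <- resample_morphology(m)
  expect_lt(nrow(r1$samples), nrow(m$samples))
  expect_equal(length(morphology_sections(r1)),
               length(morphology_sections(m)))
  r2 <- resample_morphology(r1)
  expect_identical(r2$samples, r1$samples)
  # endpoints of every section survive verbatim
  for (sec in morphology_sections(m)) {
    ids <- sec$sample_ids
    expect_true(all(c(ids[1], ids[length(ids)]) %in% r1$samples$id))
  }
})

test_that("larger spacing factors never keep more samples", {
  m <- small_astro(seed = 12)
  counts <- vapply(c(0.5, 1, 2, 4), function(f)
    nrow(resample_morphology(m, resampling_policy(f))$samples), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("resampling preserves shape and cable length", {
  m <- small_astro(seed = 13)
  r <- resample_morphology(m)
  rep <- morphometry_report(m, r)
  expect_equal(rep$n_sections, morphometry_report(m, m)$n_sections)
  expect_lt(abs(attr(rep, "total_cable_change")), 0.02)
  expect_true(all(abs(rep$cable_rel_change) < 0.02))
  # identical inputs give zero deltas
  rep0 <- morphometry_report(m, m)
  expect_true(all(rep0$cable_rel_change == 0))
  expect_equal(rep0$samples_before, rep0$samples_after)
  # polyline Hausdorff bound: every dropped sample stays within
  # spacing_factor * max radius of the resampled polyline
  secs_m <- morphology_sections(m)
  secs_r <- morphology_sections(r)
  for (k in seq_along(secs_m)) {
    P <- as.matrix(section_samples(m, secs_m[[k]])[, c("x", "y", "z")])
    L <- as.matrix(section_samples(r, secs_r[[k]])[, c("x", "y", "z")])
    bound <- 1 * max(section_samples(m, secs_m[[k]])$radius)
    expect_lt(max(points_to_polyline(P, L)), bound)
  }
})

test_that("morphometry comparison refuses mismatched topologies", {
  m <- small_astro(seed = 14)
  m2 <- generate_astrocyte(synth_astro_params(seed = 14, n_arbors = 2,
                                              max_branch_order = 2,
                                              oversample_spacing = 0.1,
                                              n_endfeet = 0))
  expect_error(morphometry_report(m, m2), "mismatch")
})
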