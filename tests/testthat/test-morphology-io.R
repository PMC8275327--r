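test_that("a minimal SWC chain parses into one arbor", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 5 -1",
               "2 3 6 0 0 1 1",
               "3 3 8 0 0 1 2"), path)
  m <- read_swc(path)
  expect_equal(nrow(m$samples), 3)
  expect_equal(soma_sample(m)$radius, 5)
  expect_equal(nrow(arbor_roots(m)), 1)
  secs <- morphology_sections(m)
  expect_length(secs, 1)
  # two segments in total: soma->root plus one within the section
  expect_equal(nrow(m$samples) - 1, 2)
  expect_equal(m$samples$structure,
               c("soma", "perivascular_process", "perivascular_process"))
})

test_that("degenerate SWC inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 2"), path)  # self-parent
  expect_error(read_swc(path), "cycle")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 9 0 0 5 -1"), path)  # two roots
  expect_error(read_swc(path), "root")
  writeLines(c("1 1 0 0 0 5"), path)  # six columns
  expect_error(read_swc(path), "line 1")
  writeLines(c("1 1 0 0 zero 5 -1"), path)
  expect_error(read_swc(path), "line 1")
})

test_that("SWC round trip preserves the sample table exactly", {
  m <- small_astro(seed = 3)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(m2$samples, m$samples)
})

test_that("endfeet sidecar validates schema and round trips bit-identically", {
  p1 <- endfoot_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      c(1, 1, 1), rbind(c(1, 2, 3)))
  expect_equal(nrow(p1$vertices), 3)
  # 4 triangles sharing one edge is non-manifold
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1),
             c(-1, -1, 0))
  F4 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5), c(1, 2, 6))
  expect_error(endfoot_patch(V, rep(1, 6), F4), "non-manifold")
  # thickness length mismatch
  expect_error(endfoot_patch(p1$vertices, c(1, 1), p1$triangles), "thickness")
  # round trip a generated endfoot
  m <- generate_astrocyte(synth_astro_params(seed = 5, n_arbors = 2,
                                             max_branch_order = 2,
                                             oversample_spacing = 0.1,
                                             n_endfeet = 2))
  path <- withr::local_tempfile(fileext = ".endfeet.json")
  write_endfeet_sidecar(m$endfeet, path)
  back <- read_endfeet_sidecar(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$vertices, m$endfeet[[i]]$vertices)
    expect_identical(back[[i]]$thickness, m$endfeet[[i]]$thickness)
    expect_identical(back[[i]]$triangles, m$endfeet[[i]]$triangles)
  }
  # wrong format field
  jsonlite::write_json(list(format = "something_else"), path,
                       auto_unbox = TRUE)
  expect_error(read_endfeet_sidecar(path), "schema")
})

test_that("validate_morphology reports violations without raising", {
  m <- small_astro(seed = 2)
  v <- validate_morphology(m)
  expect_true(v$valid)
  expect_equal(nrow(v$violations), 0)
  expect_equal(v$min_radius, min(m$samples$radius))  # linear-scan oracle
  bad <- m
  bad$samples$radius[10] <- 0
  v2 <- validate_morphology(bad)
  expect_false(v2$valid)
  expect_true(any(v2$violations$code == "nonpositive_radius" &
                  v2$violations$sample_id == bad$samples$id[10]))
})

test_that("section decomposition is consistent with the parent table", {
  m <- small_astro(seed = 4)
  secs <- morphology_sections(m)
  lens <- vapply(secs, function(s) length(s$sample_ids), integer(1))
  # segments counted over sections = (summed section samples) - n_sections
  expect_equal(sum(lens) - length(secs), sum(lens - 1))
  # and equal the number of non-soma, non-root-link segments in the table:
  # every sample except soma contributes exactly one segment to its parent;
  # root samples' segments are somatic connections, not section segments
  expect_equal(sum(lens - 1), nrow(m$samples) - 1 - nrow(arbor_roots(m)))
  # consecutive section samples reproduce the parent links
  for (sec in secs) {
    ss <- section_samples(m, sec)
    expect_equal(ss$parent_id[-1], ss$id[-nrow(ss)])
  }
  # child sections start at their parent's last sample
  for (sec in secs) {
    if (!is.na(sec$parent)) {
      parent_ids <- secs[[sec$parent]]$sample_ids
      expect_equal(sec$sample_ids[1], parent_ids[length(parent_ids)])
    }
  }
})
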