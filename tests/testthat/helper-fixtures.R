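# shared in-code fixtures; nothing is read from disk

# flat square endfoot patch in the z = 0 plane
square_patch <- function(n = 3, size = 10, thickness = 2) {
  g <- expand.grid(x = seq(0, size, length.out = n),
                   y = seq(0, size, length.out = n))
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1) * n + i
  tris <- list()
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      tris[[length(tris) + 1]] <-
        rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
              c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  endfoot_patch(V, rep(thickness, n * n), do.call(rbind, tris))
}

# small fast astrocyte for unit tests (full-size defaults are exercised in
# the acceptance suite)
small_astro <- function(seed = 1, n_endfeet = 0L, ...) {
  generate_astrocyte(synth_astro_params(
    seed = seed, n_arbors = 3L, max_branch_order = 2L,
    oversample_spacing = 0.1, n_endfeet = n_endfeet, ...))
}

# straight densely sampled section as a sample table
straight_section <- function(n = 101, span = 10, radius = 1) {
  tibble::tibble(id = seq_len(n), structure = "generic_neurite",
                 x = seq(0, span, length.out = n), y = 0, z = 0,
                 radius = radius,
                 parent_id = c(NA, seq_len(n - 1)))
}

# closed unit cube surface (12 triangles, coherent outward winding)
unit_cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(V) <- NULL
  F2 <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  m <- tri_mesh(V, astroskin:::cpp_orient_coherent(F2)$faces)
  if (mesh_volume(m, signed = TRUE) < 0)
    m <- tri_mesh(V, m$faces[, c(1, 3, 2)])
  m
}

# distance from each point to a polyline (for resampling shape bounds)
points_to_polyline <- function(P, L) {
  apply(P, 1, function(p) {
    d <- Inf
    for (i in seq_len(nrow(L) - 1)) {
      a <- L[i, ]; b <- L[i + 1, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-300)
      t <- min(max(t, 0), 1)
      d <- min(d, sqrt(sum((p - (a + t * ab))^2)))
    }
    d
  })
}
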