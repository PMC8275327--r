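#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; closed, 2-manifold,
#' outward-oriented, genus 0.
#'
#' @param radius Sphere radius (um).
#' @param center Length-3 centre.
#' @param subdivisions Midpoint subdivision levels (0 = icosahedron; faces =
#'   `20 * 4^subdivisions`).
#' @return A [tri_mesh()].
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F2 <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce coherent outward winding before subdividing
  F2 <- cpp_orient_coherent(F2)$faces
  base <- tri_mesh(V, F2)
  if (mesh_volume(base, signed = TRUE) < 0) F2 <- F2[, c(1, 3, 2)]
  for (s in seq_len(subdivisions)) {
    res <- .midpoint_subdivide(V, F2)
    V <- res$V / rows_norm(res$V)  # project back to the unit sphere
    F2 <- res$F
  }
  tri_mesh(sweep(V * radius, 2, center, "+"), F2)
}

# one level of midpoint (1-to-4) subdivision with shared-edge vertex reuse;
# returns un-projected vertices
.midpoint_subdivide <- function(V, F2) {
  nf <- nrow(F2)
  e <- rbind(F2[, c(1, 2)], F2[, c(2, 3)], F2[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(ekey)
  mid_idx <- nrow(V) + match(ekey, uk)
  ue <- e[!duplicated(ekey), , drop = FALSE]
  mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
  Vn <- rbind(V, mids)
  m12 <- mid_idx[1:nf]
  m23 <- mid_idx[nf + 1:nf]
  m31 <- mid_idx[2 * nf + 1:nf]
  Fn <- rbind(cbind(F2[, 1], m12, m31),
              cbind(m12, F2[, 2], m23),
              cbind(m31, m23, F2[, 3]),
              cbind(m12, m23, m31))
  list(V = Vn, F = Fn)
}
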