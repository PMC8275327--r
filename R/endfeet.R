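#' Endfoot subdivision specification
#'
#' Endfoot patches are tessellated far more coarsely than their thickness, so
#' skinning them directly would produce fragmented shells; patches are
#' subdivided until the edge length drops below the smallest per-vertex
#' thickness. Levels are capped at 6 (face count grows as `4^levels`).
#'
#' @param levels Subdivision levels, 0-6 (default 3).
#' @param mode `"simple"` (midpoint, geometry-preserving) or `"smooth"`
#'   (Loop-style weights with crease boundary rules).
#' @return An object of class `subdivision_spec`.
#' @export
subdivision_spec <- function(levels = 3L, mode = c("simple", "smooth")) {
  mode <- match.arg(mode)
  levels <- as.integer(levels)
  if (levels < 0 || levels > 6)
    stop("levels must be between 0 and 6 (face count grows as 4^levels)")
  structure(list(levels = levels, mode = mode), class = "subdivision_spec")
}

# one subdivision level of an endfoot patch; thickness is always midpoint-
# interpolated (no overshoot); geometry is smoothed only in smooth mode
.subdivide_once <- function(p, smooth) {
  V <- p$vertices
  F2 <- p$triangles
  th <- p$thickness
  nf <- nrow(F2)
  e <- rbind(F2[, c(1, 2)], F2[, c(2, 3)], F2[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  first <- !duplicated(ekey)
  ue <- e[first, , drop = FALSE]
  uk <- ekey[first]
  mid_idx <- nrow(V) + match(ekey, uk)
  ecount <- table(ekey)[uk]
  boundary_edge <- as.integer(ecount) == 1L
  # midpoint positions (refined below in smooth mode)
  mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
  newV <- V
  if (smooth) {
    # interior edge points: 3/8 (a+b) + 1/8 (c+d) over the two flanking tris
    opp <- matrix(NA_integer_, nrow(ue), 2)
    occ <- split(seq_along(ekey), ekey)[uk]
    opp_of <- function(row) F2[((row - 1) %% nf) + 1,
                               c(3, 1, 2)[(row - 1) %/% nf + 1]]
    for (i in seq_len(nrow(ue))) {
      rows <- occ[[i]]
      opp[i, seq_along(rows)] <- vapply(rows, opp_of, integer(1))
    }
    int_e <- !boundary_edge
    mids[int_e, ] <- 0.375 * (V[ue[int_e, 1], , drop = FALSE] +
                              V[ue[int_e, 2], , drop = FALSE]) +
                     0.125 * (V[opp[int_e, 1], , drop = FALSE] +
                              V[opp[int_e, 2], , drop = FALSE])
    # old vertices: Loop weights; boundary vertices averaged only along the
    # boundary (crease rule), so the outline is not eroded
    bverts <- sort(unique(as.vector(ue[boundary_edge, , drop = FALSE])))
    nbrs <- split(c(ue[, 2], ue[, 1]), c(ue[, 1], ue[, 2]))
    bnbrs <- split(c(ue[boundary_edge, 2], ue[boundary_edge, 1]),
                   c(ue[boundary_edge, 1], ue[boundary_edge, 2]))
    for (v in seq_len(nrow(V))) {
      if (v %in% bverts) {
        bn <- bnbrs[[as.character(v)]]
        if (length(bn) == 2)
          newV[v, ] <- 0.75 * V[v, ] + 0.125 * colSums(V[bn, , drop = FALSE])
      } else {
        nb <- nbrs[[as.character(v)]]
        n <- length(nb)
        beta <- (1 / n) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / n))^2)
        newV[v, ] <- (1 - n * beta) * V[v, ] +
          beta * colSums(V[nb, , drop = FALSE])
      }
    }
  }
  Vn <- rbind(newV, mids)
  thn <- c(th, (th[ue[, 1]] + th[ue[, 2]]) / 2)
  m12 <- mid_idx[1:nf]
  m23 <- mid_idx[nf + 1:nf]
  m31 <- mid_idx[2 * nf + 1:nf]
  Fn <- rbind(cbind(F2[, 1], m12, m31),
              cbind(m12, F2[, 2], m23),
              cbind(m31, m23, F2[, 3]),
              cbind(m12, m23, m31))
  endfoot_patch(Vn, thn, Fn)
}

#' Subdivide an endfoot patch
#'
#' Triangle count grows by a factor of 4 per level. Simple mode inserts edge
#' midpoints and never moves original vertices; smooth mode applies
#' Loop-style smoothing weights, with boundary vertices interpolated along
#' the boundary only. Thickness is midpoint-interpolated to new vertices in
#' both modes (bounds are conserved).
#'
#' @param p An [endfoot_patch()].
#' @param s A [subdivision_spec()].
#' @return The subdivided [endfoot_patch()].
#' @export
subdivide_patch <- function(p, s = subdivision_spec()) {
  for (l in seq_len(s$levels)) p <- .subdivide_once(p, s$mode == "smooth")
  p
}

max_edge_length <- function(p) {
  e <- rbind(p$triangles[, c(1, 2)], p$triangles[, c(2, 3)],
             p$triangles[, c(3, 1)])
  max(sqrt(rowSums((p$vertices[e[, 1], , drop = FALSE] -
                    p$vertices[e[, 2], , drop = FALSE])^2)))
}

#' Subdivision levels required before skinning an endfoot
#'
#' The smallest number of midpoint subdivisions after which the longest patch
#' edge is no longer than the smallest per-vertex thickness, capped at 6
#' (with a warning when the cap truncates).
#'
#' @param p An [endfoot_patch()].
#' @return Integer level, 0-6.
#' @export
required_levels <- function(p) {
  ratio <- max_edge_length(p) / min(p$thickness)
  L <- max(0, ceiling(log2(ratio)))
  if (L > 6) {
    warning(sprintf(
      "endfoot needs %d subdivision levels; capped at 6 (edges remain %.3g x thickness)",
      L, ratio / 2^6))
    L <- 6
  }
  as.integer(L)
}

#' Skin an endfoot patch into a meta-object
#'
#' One metaball per patch vertex, with surface-effective radius equal to half
#' the local thickness (thickness is diameter-like; set `thickness_is_radius`
#' to flip that reading). The patch must already be subdivided so its longest
#' edge does not exceed the smallest thickness; otherwise the balls cannot
#' overlap and polygonization would create fragmented shells.
#'
#' @param p A subdivided [endfoot_patch()].
#' @param thickness_is_radius Treat thickness as a radius instead of a
#'   diameter.
#' @param iso_level Iso-contour level.
#' @return A [meta_object()] (resolution = smallest ball surface radius).
#' @export
skin_endfoot <- function(p, thickness_is_radius = FALSE, iso_level = 0.5) {
  maxe <- max_edge_length(p)
  tmin <- min(p$thickness)
  if (maxe > tmin)
    stop(sprintf(paste0(
      "fragmentation risk: longest patch edge (%.3g um) exceeds the ",
      "smallest thickness (%.3g um); run subdivide_patch() with ",
      "required_levels() first"), maxe, tmin))
  r_s <- if (thickness_is_radius) p$thickness else p$thickness / 2
  meta_object(p$vertices, influence_from_surface(r_s, iso_level),
              resolution = min(r_s))
}
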