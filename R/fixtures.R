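# --------------------------------------------------------------------------
# Deterministic synthetic astrocytes. The generator emulates the geometric
# and topological shape class of cortical astroglia -- a spherical soma,
# several tapering binary-branching arbors that wander smoothly outward, and
# open endfeet patches wrapped part-way around a virtual vessel cylinder at
# arbor tips -- densely oversampled along sections so the resampling stage
# has real work to do. It makes no claim of morphometric fidelity.
# --------------------------------------------------------------------------

#' Parameters for the synthetic astrocyte generator
#'
#' @param seed RNG seed (mandatory; the generator never touches global
#'   random state).
#' @param n_arbors Number of arbors (default 6).
#' @param max_branch_order Maximum branch order (default 4).
#' @param soma_radius Soma radius, um (default 6).
#' @param taper Radius ratio per branch order, in (0, 1) (default 0.8); the
#'   smallest skeleton radius is `soma_radius * taper^max_branch_order`.
#' @param oversample_spacing Inter-sample arc spacing, um (default 0.05).
#' @param n_endfeet Number of endfeet patches (default 2).
#' @param vessel_radius Radius of the virtual vessel cylinder the endfeet
#'   wrap, um (default 4).
#' @return An object of class `synth_astro_params`.
#' @export
synth_astro_params <- function(seed = 1L, n_arbors = 6L, max_branch_order = 4L,
                               soma_radius = 6, taper = 0.8,
                               oversample_spacing = 0.05, n_endfeet = 2L,
                               vessel_radius = 4) {
  stopifnot(n_arbors >= 1, max_branch_order >= 1, soma_radius > 0,
            taper > 0, taper < 1, oversample_spacing > 0, n_endfeet >= 0,
            vessel_radius > 0)
  structure(list(seed = as.integer(seed), n_arbors = as.integer(n_arbors),
                 max_branch_order = as.integer(max_branch_order),
                 soma_radius = soma_radius, taper = taper,
                 oversample_spacing = oversample_spacing,
                 n_endfeet = as.integer(n_endfeet),
                 vessel_radius = vessel_radius),
            class = "synth_astro_params")
}

# roughly even directions on the sphere (Fibonacci spiral)
.fib_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5)) * 2
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotate v by angle about unit axis (Rodrigues)
.rotate_about <- function(v, axis, angle) {
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Generate a synthetic astrocyte morphology
#'
#' Soma at the origin; `n_arbors` smoothly wandering binary trees with radii
#' tapering continuously by `taper` per branch order (smallest skeleton
#' radius = `soma_radius * taper^max_branch_order`), densely oversampled at
#' `oversample_spacing`; `n_endfeet` open patches wrapped part-way around a
#' virtual vessel cylinder just beyond arbor tips, with per-vertex thickness
#' drawn uniformly from 0.5-1.5 um. Byte-identical output for equal seeds.
#'
#' @param p A [synth_astro_params()].
#' @return An [astro_morphology()].
#' @export
generate_astrocyte <- function(p = synth_astro_params()) {
  withr::with_seed(p$seed, .generate_astrocyte_impl(p))
}

.generate_astrocyte_impl <- function(p) {
  rows <- list(tibble(id = 1L, structure = "soma", x = 0, y = 0, z = 0,
                      radius = p$soma_radius, parent_id = NA_integer_))
  next_id <- 2L
  tips <- list()  # per arbor: list(position, direction, radius)
  dirs <- .fib_directions(p$n_arbors)
  base_len <- 8
  len_taper <- 0.85
  for (a in seq_len(p$n_arbors)) {
    structure_type <- if (a <= p$n_endfeet) "perivascular_process"
                      else "perisynaptic_process"
    u0 <- normalize(dirs[a, ] + rnorm(3, sd = 0.05))
    # stack of branches: start position/direction, depth, parent sample id
    stack <- list(list(pos = u0 * p$soma_radius, dir = u0, depth = 1L,
                       parent = 1L))
    deepest <- NULL
    while (length(stack)) {
      br <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      len <- base_len * len_taper^(br$depth - 1) * runif(1, 0.85, 1.15)
      nst <- max(2L, ceiling(len / p$oversample_spacing))
      pos <- br$pos
      dir <- br$dir
      ids <- next_id - 1L + seq_len(nst)
      X <- matrix(0, nst, 3)
      for (i in seq_len(nst)) {
        # smooth wander: tiny perpendicular jitter per step
        perp <- rnorm(3, sd = 1)
        perp <- perp - sum(perp * dir) * dir
        dir <- normalize(dir + 0.006 * perp)
        pos <- pos + dir * p$oversample_spacing
        X[i, ] <- pos
      }
      f <- seq_len(nst) / nst
      radius <- p$soma_radius * p$taper^(br$depth - 1 + f)
      rows[[length(rows) + 1L]] <- tibble(
        id = ids, structure = structure_type,
        x = X[, 1], y = X[, 2], z = X[, 3], radius = radius,
        parent_id = c(br$parent, ids[-nst]))
      next_id <- next_id + nst
      last_id <- ids[nst]
      if (br$depth < p$max_branch_order) {
        axis <- orthogonal_unit(dir)
        axis <- .rotate_about(axis, dir, runif(1, 0, 2 * pi))
        ang <- (25 + runif(1, -5, 10)) * pi / 180
        for (sgn in c(-1, 1)) {
          child_dir <- normalize(.rotate_about(dir, axis, sgn * ang))
          stack[[length(stack) + 1L]] <-
            list(pos = pos, dir = child_dir, depth = br$depth + 1L,
                 parent = last_id)
        }
      } else if (is.null(deepest)) {
        deepest <- list(position = pos, direction = dir,
                        radius = radius[nst])
      }
    }
    tips[[a]] <- deepest
  }
  endfeet <- list()
  for (k in seq_len(p$n_endfeet)) {
    a <- ((k - 1) %% p$n_arbors) + 1
    endfeet[[k]] <- .make_endfoot(tips[[a]], p$vessel_radius)
  }
  astro_morphology(dplyr::bind_rows(rows), endfeet)
}

# open patch wrapped part-way around a virtual vessel cylinder placed just
# beyond the arbor tip, so the skinned endfoot overlaps the tip metaball
.make_endfoot <- function(tip, vessel_radius, half_angle = 50 * pi / 180,
                          axial_halfspan = 3, nu = 5, nv = 4) {
  u <- tip$direction
  centre <- tip$position + u * (vessel_radius + 0.5)
  axis <- orthogonal_unit(u)
  b <- cross3(axis, -u)
  ang <- seq(-half_angle, half_angle, length.out = nu)
  t <- seq(-axial_halfspan, axial_halfspan, length.out = nv)
  g <- expand.grid(ang = ang, t = t)
  V <- t(vapply(seq_len(nrow(g)), function(i) {
    centre + axis * g$t[i] +
      vessel_radius * (cos(g$ang[i]) * (-u) + sin(g$ang[i]) * b)
  }, numeric(3)))
  idx <- function(i, j) (j - 1L) * nu + i  # i over angles, j over axis
  tris <- list()
  for (j in seq_len(nv - 1)) {
    for (i in seq_len(nu - 1)) {
      tris[[length(tris) + 1L]] <-
        rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
              c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  thickness <- runif(nrow(V), 0.5, 1.5)
  endfoot_patch(V, thickness, do.call(rbind, tris))
}

#' Generate an icosphere with a named defect
#'
#' Test surfaces for the repair and QC operators: `"hole"` (one face
#' removed, a single boundary loop), `"fin"` (an extra triangle glued onto
#' an edge, making it non-manifold), `"inverted"` (all windings flipped),
#' `"two_shells"` (two concentric spheres).
#'
#' @param kind One of `"hole"`, `"fin"`, `"inverted"`, `"two_shells"`.
#' @param seed Seed for the random orientation of the sphere.
#' @param radius Sphere radius (um).
#' @return A [tri_mesh()].
#' @export
generate_defect_mesh <- function(kind = c("hole", "fin", "inverted",
                                          "two_shells"),
                                 seed = 1L, radius = 1) {
  kind <- match.arg(kind)
  rot <- withr::with_seed(as.integer(seed),
                          qr.Q(qr(matrix(rnorm(9), 3))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  base <- icosphere(radius = radius, subdivisions = 2)
  base$vertices <- base$vertices %*% rot
  if (mesh_volume(base, signed = TRUE) < 0)
    base <- tri_mesh(base$vertices, base$faces[, c(1, 3, 2)])
  switch(kind,
    hole = tri_mesh(base$vertices, base$faces[-1, , drop = FALSE]),
    fin = {
      f1 <- base$faces[1, ]
      mid <- colMeans(base$vertices[f1[1:2], , drop = FALSE])
      apexdir <- normalize(mid)
      V <- rbind(base$vertices, mid + apexdir * 0.5 * radius)
      tri_mesh(V, rbind(base$faces, c(f1[1], f1[2], nrow(V))))
    },
    inverted = tri_mesh(base$vertices, base$faces[, c(1, 3, 2)]),
    two_shells = {
      inner <- icosphere(radius = radius / 2, subdivisions = 1)
      inner$vertices <- inner$vertices %*% rot
      if (mesh_volume(inner, signed = TRUE) < 0)
        inner <- tri_mesh(inner$vertices, inner$faces[, c(1, 3, 2)])
      tri_mesh(rbind(base$vertices, inner$vertices),
               rbind(base$faces, inner$faces + nrow(base$vertices)))
    })
}
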