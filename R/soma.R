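# --------------------------------------------------------------------------
# Somatic surface reconstruction. Synthetic astrocyte somata carry only an
# origin and a mean radius, so a 3D profile must be approximated. Two routes:
#   (i)  origin-to-arbor metaball marching: fast, simplified profile;
#   (ii) hybrid: a mass-spring relaxed surface, uniformly re-sampled into a
#        point cloud, skinned with displaced per-vertex meta-patches so the
#        exterior isosurface partition reproduces the input surface.
# --------------------------------------------------------------------------

#' Soft-body parameters for the somatic surface simulation
#'
#' @param stiffness Spring constant (unitless, default 0.1).
#' @param steps Number of relaxation steps (default 100).
#' @param damping Damping in (0, 1); larger means smaller steps (default 0.5).
#' @param pull_fraction How far toward each arbor root the surface is drawn,
#'   in (0, 1] (default 0.4).
#' @return An object of class `soft_body_params`.
#' @export
soft_body_params <- function(stiffness = 0.1, steps = 100L, damping = 0.5,
                             pull_fraction = 0.4) {
  stopifnot(stiffness > 0, steps >= 1, damping > 0, damping < 1,
            pull_fraction > 0, pull_fraction <= 1)
  structure(list(stiffness = stiffness, steps = as.integer(steps),
                 damping = damping, pull_fraction = pull_fraction),
            class = "soft_body_params")
}

#' Skin a soma by origin-to-arbor metaball marching
#'
#' One metaball matches the somatic sample; for each arbor the somatic
#' segment (soma origin to arbor root) is filled with marching metaballs
#' whose radii taper linearly from the soma radius to the root radius.
#'
#' @param soma Somatic sample (list with `position`, `radius`, or a 1-row
#'   sample table).
#' @param arbor_roots List of arbor-root samples (or a sample table, one row
#'   per root; may be empty).
#' @param step_factor Marching step as a multiple of the local radius.
#' @return A [meta_object()].
#' @export
skin_soma_marching <- function(soma, arbor_roots = list(), step_factor = 1) {
  soma <- as_skin_sample(soma)
  if (is.data.frame(arbor_roots))
    arbor_roots <- lapply(seq_len(nrow(arbor_roots)),
                          function(i) arbor_roots[i, ])
  parts <- list(meta_object(matrix(soma$position, 1),
                            influence_from_surface(soma$radius),
                            resolution = soma$radius))
  for (root in arbor_roots)
    parts[[length(parts) + 1L]] <- skin_segment(soma, root, step_factor)
  blend(parts)
}

#' Simulate a somatic surface with a mass-spring model
#'
#' Starts from a subdivided icosphere at the somatic radius; vertices facing
#' each arbor root are pulled toward a fraction of the root distance while
#' Hookean edge springs resist, integrated as damped gradient descent for a
#' fixed number of steps (70% with pulls active, the remainder spring-only
#' relaxation). Connectivity is never edited, so the result stays closed and
#' genus 0.
#'
#' @param soma,arbor_roots As in [skin_soma_marching()].
#' @param p A [soft_body_params()].
#' @param seed Kept for interface stability; the simulation is deterministic.
#' @param subdivisions Icosphere subdivision level.
#' @return A [tri_mesh()] with attributes `"energy"` (spring energy per
#'   step), `"pull_steps"` and `"converged"`.
#' @export
simulate_soma_surface <- function(soma, arbor_roots = list(),
                                  p = soft_body_params(), seed = 1L,
                                  subdivisions = 3) {
  soma <- as_skin_sample(soma)
  if (is.data.frame(arbor_roots))
    arbor_roots <- lapply(seq_len(nrow(arbor_roots)),
                          function(i) arbor_roots[i, ])
  arbor_roots <- lapply(arbor_roots, as_skin_sample)
  mesh <- icosphere(soma$radius, soma$position, subdivisions)
  X <- mesh$vertices
  F2 <- mesh$faces
  e <- unique(t(apply(rbind(F2[, 1:2], F2[, 2:3], F2[, c(3, 1)]), 1, sort)))
  rest <- sqrt(rowSums((X[e[, 1], ] - X[e[, 2], ])^2))
  deg <- tabulate(as.vector(e), nbins = nrow(X))
  # pulled vertex sets and their targets
  pulls <- list()
  for (root in arbor_roots) {
    d <- vnorm(root$position - soma$position)
    if (d < 1e-12) next
    u <- (root$position - soma$position) / d
    vdir <- sweep(X, 2, soma$position)
    vdir <- vdir / rows_norm(vdir)
    ang <- acos(pmin(1, pmax(-1, vdir %*% u)))
    theta <- asin(min(1, 1.2 * root$radius / soma$radius))
    sel <- which(ang < theta)
    if (!length(sel)) sel <- which.min(ang)
    target <- soma$position +
      u * (soma$radius + p$pull_fraction * max(0, d - soma$radius))
    pulls[[length(pulls) + 1L]] <- list(sel = sel, target = target)
  }
  k <- p$stiffness
  k_pull <- p$stiffness
  L <- k * 2 * max(deg) + k_pull           # gradient Lipschitz bound
  lr <- (1 - p$damping) / L
  pull_steps <- round(0.7 * p$steps)
  energy <- numeric(p$steps)
  maxdisp <- numeric(p$steps)
  for (step in seq_len(p$steps)) {
    d1 <- X[e[, 1], ] - X[e[, 2], ]
    len <- pmax(rows_norm(d1), 1e-12)
    coef <- k * (len - rest) / len
    fe <- d1 * coef
    Fv <- matrix(0, nrow(X), 3)
    acc1 <- rowsum(-fe, e[, 1], reorder = FALSE)
    acc2 <- rowsum(fe, e[, 2], reorder = FALSE)
    Fv[as.integer(rownames(acc1)), ] <- Fv[as.integer(rownames(acc1)), ] + acc1
    Fv[as.integer(rownames(acc2)), ] <- Fv[as.integer(rownames(acc2)), ] + acc2
    if (step <= pull_steps) {
      for (pl in pulls) {
        Fv[pl$sel, ] <- Fv[pl$sel, ] +
          k_pull * sweep(-X[pl$sel, , drop = FALSE], 2, pl$target, "+")
      }
    }
    Xn <- X + lr * Fv
    maxdisp[step] <- max(rows_norm(Xn - X))
    X <- Xn
    d1 <- X[e[, 1], ] - X[e[, 2], ]
    energy[step] <- 0.5 * k * sum((rows_norm(d1) - rest)^2)
  }
  tailn <- max(2L, round(0.1 * p$steps))
  tail_disp <- maxdisp[(p$steps - tailn + 1):p$steps]
  converged <- all(diff(tail_disp) <= 1e-9) ||
    tail_disp[tailn] < 1e-6 * soma$radius
  if (!converged)
    warning("soma soft-body relaxation has not converged; consider more steps")
  out <- tri_mesh(X, F2)
  attr(out, "energy") <- energy
  attr(out, "pull_steps") <- pull_steps
  attr(out, "converged") <- converged
  out
}

#' Uniformly sampled point cloud on a surface
#'
#' @param vertices n x 3 point matrix.
#' @param normals n x 3 outward unit normals.
#' @param target_spacing Intended inter-point spacing (um).
#' @return An object of class `surface_cloud`.
#' @export
surface_cloud <- function(vertices, normals, target_spacing) {
  vertices <- as_matrix3(vertices, "vertices")
  normals <- as_matrix3(normals, "normals")
  stopifnot(nrow(vertices) == nrow(normals), target_spacing > 0)
  structure(list(vertices = vertices, normals = normals,
                 target_spacing = target_spacing), class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("<surface_cloud> %d points, target spacing %.3g um\n",
              nrow(x$vertices), x$target_spacing))
  invisible(x)
}

#' Particle-based uniform remeshing of a closed surface
#'
#' Area-weighted random surface samples are relaxed by short-range repulsion
#' and re-projected onto the surface each iteration, yielding an
#' approximately blue-noise point cloud (nearest-neighbour spacing
#' coefficient of variation well below 0.35 on smooth surfaces) with outward
#' normals taken from the closest face.
#'
#' @param m A closed 2-manifold [tri_mesh()].
#' @param target_spacing Desired point spacing (um); must not exceed the
#'   surface diameter.
#' @param iterations Relaxation iterations (default 50).
#' @param seed RNG seed for the initial sampling.
#' @return A [surface_cloud()].
#' @export
uniform_remesh <- function(m, target_spacing, iterations = 50L, seed = 1L) {
  diam <- bbox_diagonal(m$vertices)
  if (target_spacing > diam)
    stop(sprintf("target_spacing (%.3g) exceeds the surface diameter (%.3g)",
                 target_spacing, diam))
  ori <- cpp_orient_coherent(m$faces)
  m <- tri_mesh(m$vertices, ori$faces)
  if (mesh_volume(m, signed = TRUE) < 0)
    m <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  area <- mesh_area(m)
  n <- max(20L, round(area / (target_spacing^2 * sqrt(3) / 2)))
  pts <- withr::with_seed(as.integer(seed), sample_on_mesh(m, n))
  h <- 2 * target_spacing
  for (it in seq_len(iterations)) {
    disp <- cpp_repulse(pts, h, 0.25 * target_spacing)
    proj <- cpp_point_mesh(pts + disp, m$vertices, m$faces)
    pts <- proj$closest
  }
  proj <- cpp_point_mesh(pts, m$vertices, m$faces)
  fn <- rows_cross(
    m$vertices[m$faces[, 2], , drop = FALSE] - m$vertices[m$faces[, 1], , drop = FALSE],
    m$vertices[m$faces[, 3], , drop = FALSE] - m$vertices[m$faces[, 1], , drop = FALSE])
  fn <- fn / pmax(rows_norm(fn), 1e-300)
  normals <- fn[proj$face, , drop = FALSE]
  surface_cloud(pts, normals, target_spacing)
}

# blended-field height of an infinite hexagonal lattice of metaballs: used to
# calibrate the inward displacement so the exterior isosurface passes just
# outside the input surface
.lattice_surface_height <- function(spacing, influence, iso_level = 0.5) {
  reach <- influence * 1.5
  i <- seq(-ceiling(reach / spacing), ceiling(reach / spacing))
  g <- expand.grid(i = i, j = i)
  lx <- (g$i + 0.5 * (g$j %% 2)) * spacing
  ly <- g$j * spacing * sqrt(3) / 2
  d2 <- lx^2 + ly^2
  d2 <- d2[d2 <= reach^2]
  fh <- function(h) {
    dd2 <- d2 + h^2
    u <- pmax(0, 1 - dd2 / influence^2)
    sum(u^3) - iso_level
  }
  if (fh(0) <= 0) return(kernel_surface_factor(iso_level) * influence)
  stats::uniroot(fh, c(0, influence), tol = 1e-10)$root
}

#' Skin a somatic surface cloud with displaced meta-patches
#'
#' Creates one metaball per cloud vertex, displaced inward along the normal
#' so that the exterior partition of the polygonized blend reproduces the
#' input surface. Ball influence radii follow the polygonization resolution
#' (surface-effective radius = `base_resolution`); the displacement step is
#' calibrated from the blended field of a hexagonal ball lattice at the cloud
#' spacing, shrunk by a small outward margin (0.05 surface radii) so the exterior
#' partition encloses every input vertex. Polygonizing the result without pruning
#' yields exactly two nested partitions (exterior and interior shells).
#'
#' @param cloud A [surface_cloud()].
#' @param base_resolution Polygonization resolution of the meta-object the
#'   patches must blend with (um); the cloud spacing must be smaller, else
#'   the patches would not blend smoothly (fragmentation risk).
#' @param iso_level Iso-contour level.
#' @return A [meta_object()] with the displacement in attribute
#'   `"displacement"`.
#' @export
skin_soma_hybrid <- function(cloud, base_resolution, iso_level = 0.5) {
  if (cloud$target_spacing >= base_resolution)
    stop(sprintf(paste0(
      "cloud spacing %.3g um is not below the polygonization resolution ",
      "%.3g um; the meta-patches would fragment"),
      cloud$target_spacing, base_resolution))
  r_s <- base_resolution
  R <- influence_from_surface(r_s, iso_level)
  h_star <- .lattice_surface_height(cloud$target_spacing, R, iso_level)
  delta <- max(h_star - 0.05 * r_s, 0.2 * r_s)
  centers <- cloud$vertices - delta * cloud$normals
  out <- meta_object(centers, rep(R, nrow(centers)),
                     resolution = base_resolution)
  attr(out, "displacement") <- delta
  out
}
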