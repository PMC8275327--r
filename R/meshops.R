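#' Split a mesh into connected partitions
#'
#' Partitions are connected components through shared vertices. Closed
#' partitions are ordered by descending enclosed volume, open partitions (any
#' boundary edge) come after, ordered by descending area.
#'
#' @param m A `tri_mesh`.
#' @return A list of `tri_mesh` objects.
#' @export
split_partitions <- function(m) {
  if (!n_faces(m)) return(list())
  comp <- cpp_face_components(m$faces, n_vertices(m))
  parts <- lapply(sort(unique(comp)), function(k) {
    F2 <- m$faces[comp == k, , drop = FALSE]
    used <- sort(unique(as.vector(F2)))
    remap <- integer(n_vertices(m))
    remap[used] <- seq_along(used)
    tri_mesh(m$vertices[used, , drop = FALSE],
             matrix(remap[F2], ncol = 3))
  })
  closed <- vapply(parts, function(p) cpp_edge_stats(p$faces)$n_boundary == 0,
                   logical(1))
  key <- vapply(parts, function(p) mesh_volume(p), numeric(1))
  key[!closed] <- vapply(parts[!closed], mesh_area, numeric(1))
  parts[order(!closed, -key)]
}

#' Count non-manifold edges and vertices
#'
#' Edges incident to more than two triangles are non-manifold; edges incident
#' to exactly one are boundary edges and reported separately. A vertex is
#' non-manifold when its incident triangles do not form a single
#' edge-connected fan.
#'
#' @param m A `tri_mesh`.
#' @return A list with `edges`, `vertices` and `boundary_edges` counts.
#' @export
count_non_manifold <- function(m) {
  es <- cpp_edge_stats(m$faces)
  nmv <- cpp_nonmanifold_vertices(m$faces, n_vertices(m))
  list(edges = es$n_nonmanifold, vertices = length(nmv),
       boundary_edges = es$n_boundary)
}

#' Count geometrically intersecting non-adjacent triangle pairs
#'
#' Pairs that share a vertex are excluded (they touch by construction). The
#' default path prunes candidates with a uniform spatial grid; `method =
#' "brute"` tests all pairs and must give the same count.
#'
#' @param m A `tri_mesh`.
#' @param method `"indexed"` (default) or `"brute"`.
#' @return Integer count, with the offending pairs in attribute `"pairs"`.
#' @export
detect_self_intersections <- function(m, method = c("indexed", "brute")) {
  method <- match.arg(method)
  res <- cpp_self_intersections(m$vertices, m$faces, method == "brute")
  structure(as.integer(res$count), pairs = res$pairs)
}

#' Quality-control metrics for a surface mesh
#'
#' @param m A `tri_mesh`.
#' @param check_self_intersections Run the (more expensive) triangle-triangle
#'   intersection scan; when `FALSE` the count is `NA` and watertightness is
#'   judged without it.
#' @return A one-row tibble: `partition_count`, `non_manifold_edges`,
#'   `non_manifold_vertices`, `boundary_edges`, `self_intersections`,
#'   `surface_area` (um^2), `volume` (um^3; `NA` when the mesh is not
#'   closed), `watertight`.
#' @export
mesh_metrics <- function(m, check_self_intersections = TRUE) {
  es <- cpp_edge_stats(m$faces)
  nm <- count_non_manifold(m)
  nparts <- if (n_faces(m))
    max(cpp_face_components(m$faces, n_vertices(m))) else 0L
  si <- if (check_self_intersections)
    as.integer(detect_self_intersections(m)) else NA_integer_
  closed <- es$n_boundary == 0 && es$n_nonmanifold == 0
  tibble(
    partition_count = as.integer(nparts),
    non_manifold_edges = as.integer(nm$edges),
    non_manifold_vertices = as.integer(nm$vertices),
    boundary_edges = as.integer(es$n_boundary),
    self_intersections = si,
    surface_area = mesh_area(m),
    volume = if (closed) mesh_volume(m) else NA_real_,
    watertight = closed && nparts == 1L && nm$vertices == 0L &&
      (!check_self_intersections || si == 0L))
}

# ray-parity point containment (+x ray, Moller-Trumbore, vectorized)
point_in_mesh <- function(m, p) {
  V <- m$vertices; F2 <- m$faces
  a <- V[F2[, 1], , drop = FALSE]
  e1 <- V[F2[, 2], , drop = FALSE] - a
  e2 <- V[F2[, 3], , drop = FALSE] - a
  # ray direction slightly tilted to dodge edge-on hits
  d <- normalize(c(1, 1e-4, 2e-4))
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- matrix(rep(p, each = nrow(a)), ncol = 3) - a
  u <- rowSums(tv * pv) / det
  qv <- rows_cross(tv, e1)
  v <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
  t0 <- rowSums(e2 * qv) / det
  hits <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t0 > 1e-9
  sum(hits) %% 2 == 1
}

#' Remove the interior partition of a two-partition mesh
#'
#' The metaball-skinned hybrid soma produces two nested closed shells; the
#' inner one (fewer triangles, ties broken by smaller volume) is discarded.
#' Nesting is verified by a ray-parity containment test.
#'
#' @param m A `tri_mesh` with exactly two closed, nested partitions.
#' @return The exterior partition as a `tri_mesh`.
#' @export
remove_interior_partition <- function(m) {
  parts <- split_partitions(m)
  if (length(parts) != 2)
    stop(sprintf("expected exactly 2 partitions, found %d (face counts: %s)",
                 length(parts),
                 paste(vapply(parts, n_faces, integer(1)), collapse = ", ")))
  nf <- vapply(parts, n_faces, integer(1))
  if (nf[1] != nf[2]) {
    keep <- which.max(nf)
  } else {
    keep <- which.max(vapply(parts, mesh_volume, numeric(1)))
  }
  drop <- setdiff(1:2, keep)
  if (!point_in_mesh(parts[[keep]], parts[[drop]]$vertices[1, ]))
    stop("partitions are not nested; refusing to remove either")
  parts[[keep]]
}

#' Decimate a mesh by quadric edge collapse
#'
#' Collapses edges in order of quadric error until the face count drops to
#' `ratio` times the input. Collapses that would flip a face normal or create
#' a non-manifold configuration are rejected; if the target is unreachable
#' the achieved ratio is reported in attribute `"achieved_ratio"` with a
#' warning.
#'
#' @param m A manifold `tri_mesh`.
#' @param ratio Target face-count ratio in (0, 1).
#' @return A decimated `tri_mesh`.
#' @export
decimate <- function(m, ratio) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie in (0, 1)")
  target <- max(4L, as.integer(floor(ratio * n_faces(m))))
  res <- cpp_decimate_qem(m$vertices, m$faces, target)
  out <- tri_mesh(res$vertices, res$faces)
  achieved <- res$achieved_faces / n_faces(m)
  if (res$achieved_faces > target + 1L)
    warning(sprintf(
      "decimation stopped early at ratio %.3f (target %.3f): %s",
      achieved, ratio, "further collapses would break manifoldness"))
  attr(out, "achieved_ratio") <- achieved
  out
}

# merge vertices closer than tol (grid hashing on rounded coordinates)
merge_duplicate_vertices <- function(m, tol = 1e-6) {
  key <- paste(round(m$vertices[, 1] / tol),
               round(m$vertices[, 2] / tol),
               round(m$vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])  # kept subset preserves original order
  V <- m$vertices[first, , drop = FALSE]
  F2 <- matrix(remap[m$faces], ncol = 3)
  tri_mesh(V, F2)
}

drop_degenerate_faces <- function(m, tol = 1e-20) {
  F2 <- m$faces
  dup <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
  n <- rows_cross(face_corner(m, 2) - face_corner(m, 1),
                  face_corner(m, 3) - face_corner(m, 1))
  area2 <- rowSums(n * n)
  keep <- !dup & area2 > tol
  tri_mesh(m$vertices, F2[keep, , drop = FALSE])
}

# remove fin faces until no edge has more than two incident triangles; the
# face shedding the most boundary/non-manifold edges is dropped first
remove_fins <- function(m, max_iter = 50) {
  for (it in seq_len(max_iter)) {
    es <- cpp_edge_stats(m$faces)
    if (es$n_nonmanifold == 0) break
    nme <- es$nonmanifold_edges
    bad_keys <- paste(pmin(nme[, 1], nme[, 2]), pmax(nme[, 1], nme[, 2]))
    bnd_keys <- if (nrow(es$boundary_edges))
      paste(pmin(es$boundary_edges[, 1], es$boundary_edges[, 2]),
            pmax(es$boundary_edges[, 1], es$boundary_edges[, 2]))
    else character(0)
    F2 <- m$faces
    ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
    fkeys <- cbind(ek(F2[, 1], F2[, 2]), ek(F2[, 2], F2[, 3]),
                   ek(F2[, 3], F2[, 1]))
    on_nm <- matrix(fkeys %in% bad_keys, ncol = 3)
    on_bnd <- matrix(fkeys %in% bnd_keys, ncol = 3)
    cand <- which(rowSums(on_nm) > 0)
    # score: boundary edges make a face a dangling fin
    score <- rowSums(on_bnd)[cand] * 10 + rowSums(on_nm)[cand]
    drop <- cand[which.max(score)]
    m <- tri_mesh(m$vertices, F2[-drop, , drop = FALSE])
  }
  m
}

# chain boundary edges into loops and fill each by a centroid fan (or a single
# triangle for 3-edge loops); new triangles traverse existing boundary edges
# in the opposite direction so orientation stays coherent
fill_holes <- function(m, max_loop = 1e4) {
  if (cpp_edge_stats(m$faces)$n_boundary == 0) return(m)
  F2 <- m$faces
  # directed boundary edges as they appear in faces
  e_all <- rbind(F2[, 1:2, drop = FALSE], F2[, 2:3, drop = FALSE],
                 F2[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  cnt <- table(key)
  bnd <- e_all[cnt[key] == 1, , drop = FALSE]
  if (!nrow(bnd)) return(m)
  nxt <- stats::setNames(bnd[, 2], bnd[, 1])  # a -> b along the face winding
  if (anyDuplicated(bnd[, 1]))
    stop("boundary is not a set of simple loops; cannot fill")
  V <- m$vertices
  newF <- list()
  visited <- stats::setNames(rep(FALSE, nrow(bnd)), bnd[, 1])
  for (start in bnd[, 1]) {
    skey <- as.character(start)
    if (visited[[skey]]) next
    loop <- start
    cur <- start
    repeat {
      visited[[as.character(cur)]] <- TRUE
      cur <- nxt[[as.character(cur)]]
      if (cur == start) break
      loop <- c(loop, cur)
      if (length(loop) > max_loop)
        stop(sprintf("unfillable hole: boundary loop exceeds %d edges",
                     as.integer(max_loop)))
    }
    if (length(loop) == 3) {
      # reversed relative to the face windings along the loop
      newF[[length(newF) + 1L]] <- matrix(rev(loop), ncol = 3)
    } else {
      centre <- colMeans(V[loop, , drop = FALSE])
      V <- rbind(V, centre)
      cid <- nrow(V)
      to <- c(loop[-1], loop[1])
      newF[[length(newF) + 1L]] <- cbind(to, loop, cid)
    }
  }
  tri_mesh(V, rbind(F2, do.call(rbind, newF)))
}

#' Repair a mesh into a watertight surface
#'
#' Pipeline: merge duplicate vertices, drop degenerate triangles, remove
#' non-manifold fins, fill holes by boundary-loop triangulation, enforce a
#' coherent outward orientation, keep the largest partition. If defects
#' remain they are reported in the attribute `"residual"` with a warning; the
#' operation is idempotent on meshes it has successfully repaired.
#'
#' @param m A `tri_mesh`.
#' @param merge_tol Duplicate-vertex merge tolerance (um).
#' @param check_self_intersections Include the self-intersection count in the
#'   final QC check.
#' @return A repaired `tri_mesh` with a [mesh_metrics()] row in attribute
#'   `"qc"`.
#' @export
repair_watertight <- function(m, merge_tol = 1e-6,
                              check_self_intersections = TRUE) {
  m <- merge_duplicate_vertices(m, merge_tol)
  m <- drop_degenerate_faces(m)
  m <- remove_fins(m)
  m <- tryCatch(fill_holes(m), error = function(e) {
    warning("partial repair: ", conditionMessage(e))
    m
  })
  ori <- cpp_orient_coherent(m$faces)
  m <- tri_mesh(m$vertices, ori$faces)
  parts <- split_partitions(m)
  if (length(parts) > 1) m <- parts[[1]]
  # drop unreferenced vertices, then point outward
  used <- sort(unique(as.vector(m$faces)))
  remap <- integer(n_vertices(m))
  remap[used] <- seq_along(used)
  m <- tri_mesh(m$vertices[used, , drop = FALSE],
                matrix(remap[m$faces], ncol = 3))
  if (mesh_volume(m, signed = TRUE) < 0)
    m <- tri_mesh(m$vertices, m$faces[, c(1, 3, 2), drop = FALSE])
  qc <- mesh_metrics(m, check_self_intersections = check_self_intersections)
  if (!qc$watertight)
    warning("repair left residual defects; see attr(, 'qc')")
  attr(m, "qc") <- qc
  m
}

#' Area-weighted random points on a mesh surface
#'
#' @param m A `tri_mesh`.
#' @param n Number of points.
#' @return An n x 3 matrix. Uses the current RNG state.
#' @export
sample_on_mesh <- function(m, n) {
  a <- face_corner(m, 1); b <- face_corner(m, 2); c3 <- face_corner(m, 3)
  areas <- rows_norm(rows_cross(b - a, c3 - a)) / 2
  idx <- sample.int(n_faces(m), n, replace = TRUE, prob = areas)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  u <- 1 - r1; v <- r1 * (1 - r2); w <- r1 * r2
  u * a[idx, , drop = FALSE] + v * b[idx, , drop = FALSE] +
    w * c3[idx, , drop = FALSE]
}

#' Distances from points to a mesh surface
#'
#' @param points An n x 3 matrix.
#' @param m A `tri_mesh`.
#' @return A list with `distance`, `closest` (n x 3) and `face` (index).
#' @export
point_mesh_distance <- function(points, m) {
  cpp_point_mesh(as_matrix3(points, "points"), m$vertices, m$faces)
}

#' Symmetric RMS Hausdorff distance between two meshes
#'
#' Samples `samples` area-weighted random points on each mesh, measures
#' point-to-surface distances to the other mesh, and returns the RMS over all
#' sampled distances, normalized by the bounding-box diagonal of `a` (Metro
#' convention; swapping the arguments only changes the normalization).
#'
#' @param a,b `tri_mesh` objects.
#' @param samples Points sampled per side.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return A non-negative scalar (unitless).
#' @export
hausdorff_rms <- function(a, b, samples = 10000L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    pa <- sample_on_mesh(a, samples)
    pb <- sample_on_mesh(b, samples)
  })
  da <- cpp_point_mesh(pa, b$vertices, b$faces)$distance
  db <- cpp_point_mesh(pb, a$vertices, a$faces)$distance
  sqrt(mean(c(da, db)^2)) / bbox_diagonal(a$vertices)
}
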