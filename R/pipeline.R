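#' Pipeline configuration
#'
#' @param soma_method `"marching"` (fast, simplified profile; the default)
#'   or `"hybrid"` (mass-spring surface + uniform cloud + displaced
#'   meta-patches).
#' @param resample_factor Spacing factor for [resampling_policy()].
#' @param step_factor Metaball marching step factor.
#' @param iso_level Iso-contour level of the blended field.
#' @param resolution_cap Upper bound on the polygonization grid spacing (um).
#' @param resolution_floor Lower bound on the grid spacing (um); guards
#'   against pathological grids from vanishing radii.
#' @param endfoot_subdiv `"auto"` ([required_levels()] per patch) or a fixed
#'   integer level.
#' @param endfoot_subdiv_mode `"simple"` or `"smooth"`.
#' @param outputs Subset of `c("visual", "simulation")`; at least one.
#' @param decimate_ratio Face-count ratio for the visual branch.
#' @param n_workers Parallel workers for batch runs (fork-based; outputs are
#'   independent of the worker count).
#' @param seed Base seed; each morphology derives its own seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(soma_method = c("marching", "hybrid"),
                            resample_factor = 1, step_factor = 1,
                            iso_level = 0.5, resolution_cap = 1,
                            resolution_floor = 0.05,
                            endfoot_subdiv = "auto",
                            endfoot_subdiv_mode = c("simple", "smooth"),
                            outputs = c("visual", "simulation"),
                            decimate_ratio = 0.1, n_workers = 1L,
                            seed = 1L) {
  soma_method <- match.arg(soma_method)
  endfoot_subdiv_mode <- match.arg(endfoot_subdiv_mode)
  outputs <- match.arg(outputs, several.ok = TRUE)
  if (!length(outputs)) stop("select at least one output branch")
  stopifnot(resample_factor > 0, step_factor > 0, iso_level > 0,
            iso_level < 1, resolution_cap > 0, resolution_floor > 0,
            decimate_ratio > 0, decimate_ratio < 1, n_workers >= 1)
  structure(list(soma_method = soma_method,
                 resample_factor = resample_factor,
                 step_factor = step_factor, iso_level = iso_level,
                 resolution_cap = resolution_cap,
                 resolution_floor = resolution_floor,
                 endfoot_subdiv = endfoot_subdiv,
                 endfoot_subdiv_mode = endfoot_subdiv_mode,
                 outputs = outputs, decimate_ratio = decimate_ratio,
                 n_workers = as.integer(n_workers), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Polygonization resolution of a morphology
#'
#' The grid spacing is the smallest radius anywhere in the morphology
#' (endfeet half-thickness included), clamped to
#' `[resolution_floor, resolution_cap]`.
#'
#' @param m An [astro_morphology()].
#' @param cap,floor Clamp bounds (um).
#' @return Grid spacing in um.
#' @export
morphology_resolution <- function(m, cap = 1, floor = 0.05) {
  max(min(morphology_min_radius(m), cap), floor)
}

#' Skin a whole morphology into one blended meta-object
#'
#' Resamples the arbors, skins soma, arbors and (subdivided) endfeet into
#' separate meta-objects and blends them. The blended object's resolution is
#' the morphology resolution rule, not the per-part minimum.
#'
#' @param m An [astro_morphology()].
#' @param cfg A [pipeline_config()].
#' @param seed Seed for the stochastic soma-cloud steps (hybrid only).
#' @return A [meta_object()]; attribute `"hybrid"` is `TRUE` when the soma
#'   needs interior-partition pruning after polygonization.
#' @export
skin_morphology <- function(m, cfg = pipeline_config(), seed = 1L) {
  res <- morphology_resolution(m, cfg$resolution_cap, cfg$resolution_floor)
  m2 <- resample_morphology(m, resampling_policy(cfg$resample_factor))
  soma <- soma_sample(m2)
  roots <- arbor_roots(m2)
  parts <- list()
  hybrid <- identical(cfg$soma_method, "hybrid")
  if (hybrid) {
    surf <- simulate_soma_surface(soma, roots, soft_body_params(), seed)
    cloud <- uniform_remesh(surf, target_spacing = 0.8 * res, seed = seed)
    parts[[1]] <- skin_soma_hybrid(cloud, base_resolution = res,
                                   iso_level = cfg$iso_level)
  } else {
    parts[[1]] <- skin_soma_marching(soma, roots, cfg$step_factor)
  }
  for (a in seq_len(nrow(roots)))
    parts[[length(parts) + 1L]] <- skin_arbor(m2, a, cfg$step_factor)
  for (ef in m2$endfeet) {
    lv <- if (identical(cfg$endfoot_subdiv, "auto")) required_levels(ef)
          else as.integer(cfg$endfoot_subdiv)
    ef2 <- subdivide_patch(ef, subdivision_spec(lv, cfg$endfoot_subdiv_mode))
    parts[[length(parts) + 1L]] <-
      skin_endfoot(ef2, iso_level = cfg$iso_level)
  }
  mo <- blend(parts)
  mo$resolution <- res
  attr(mo, "hybrid") <- hybrid
  mo
}

# one morphology through the full pipeline; returns a one-row report tibble
.pipeline_one <- function(swc_path, endfeet_path, cfg, out_dir, seed) {
  stem <- tools::file_path_sans_ext(basename(swc_path))
  t0 <- proc.time()[["elapsed"]]
  m <- read_swc(swc_path)
  if (!is.null(endfeet_path) && !is.na(endfeet_path) &&
      nzchar(endfeet_path))
    m$endfeet <- read_endfeet_sidecar(endfeet_path)
  mo <- skin_morphology(m, cfg, seed)
  mesh <- polygonize(mo, cfg$iso_level)
  message(sprintf("[%s] skinned %d balls, polygonized %d faces (res %.3g um)",
                  stem, n_balls(mo), n_faces(mesh), mo$resolution))
  if (isTRUE(attr(mo, "hybrid"))) {
    nparts <- max(cpp_face_components(mesh$faces, n_vertices(mesh)))
    if (nparts == 2) mesh <- remove_interior_partition(mesh)
  }
  files <- character(0)
  watertight <- NA
  qc_sim <- NULL
  if ("visual" %in% cfg$outputs) {
    vis <- decimate(mesh, cfg$decimate_ratio)
    f <- file.path(out_dir, paste0(stem, "_visual.obj"))
    write_mesh(vis, f)
    files <- c(files, f)
  }
  if ("simulation" %in% cfg$outputs) {
    sim <- repair_watertight(mesh)
    qc_sim <- attr(sim, "qc")
    watertight <- qc_sim$watertight
    f <- file.path(out_dir, paste0(stem, "_simulation.obj"))
    write_mesh(sim, f)
    files <- c(files, f)
  }
  qc <- if (!is.null(qc_sim)) qc_sim else
    mesh_metrics(mesh, check_self_intersections = FALSE)
  jsonlite::write_json(as.list(qc),
                       file.path(out_dir, paste0(stem, "_qc.json")),
                       auto_unbox = TRUE, digits = NA)
  tibble(morphology = stem, status = "ok", error = NA_character_,
         n_balls = n_balls(mo), resolution = mo$resolution,
         faces_raw = n_faces(mesh), watertight = watertight,
         non_manifold_edges = qc$non_manifold_edges,
         partition_count = qc$partition_count,
         files = list(files),
         seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the end-to-end meshing pipeline over a batch of morphologies
#'
#' For each SWC file (with optional endfeet sidecar): read, resample, skin,
#' blend, polygonize, prune the interior partition (hybrid soma), then write
#' a decimated mesh (visual branch) and/or a repaired watertight mesh
#' (simulation branch) plus a QC report JSON. Failures are isolated per
#' morphology and the batch continues. The resolved configuration is written
#' next to the outputs. Results are independent of `n_workers`.
#'
#' @param cfg A [pipeline_config()].
#' @param morphology_paths Character vector of SWC paths.
#' @param endfeet_paths Optional character vector of sidecar paths (same
#'   length; `NA` entries mean no endfeet). Defaults to
#'   `<stem>.endfeet.json` next to each SWC when that file exists.
#' @param out_dir Output directory (created if missing).
#' @return A run-report tibble, one row per morphology, with attribute
#'   `"all_ok"`.
#' @export
run_pipeline <- function(cfg, morphology_paths, endfeet_paths = NULL,
                         out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(endfeet_paths)) {
    endfeet_paths <- vapply(morphology_paths, function(p) {
      cand <- paste0(tools::file_path_sans_ext(p), ".endfeet.json")
      if (file.exists(cand)) cand else NA_character_
    }, character(1))
  }
  stopifnot(length(endfeet_paths) == length(morphology_paths))
  jsonlite::write_json(unclass(cfg),
                       file.path(out_dir, "pipeline_config.json"),
                       auto_unbox = TRUE, digits = NA)
  worker <- function(i) {
    seed_i <- cfg$seed + i  # per-morphology seed: worker-count invariant
    tryCatch(
      .pipeline_one(morphology_paths[i], endfeet_paths[i], cfg, out_dir,
                    seed_i),
      error = function(e) tibble(
        morphology = tools::file_path_sans_ext(basename(morphology_paths[i])),
        status = "error", error = conditionMessage(e),
        n_balls = NA_integer_, resolution = NA_real_,
        faces_raw = NA_integer_, watertight = NA,
        non_manifold_edges = NA_integer_, partition_count = NA_integer_,
        files = list(character(0)), seconds = NA_real_))
  }
  idx <- seq_along(morphology_paths)
  rows <- if (cfg$n_workers > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(idx, worker, mc.cores = cfg$n_workers)
  else lapply(idx, worker)
  report <- dplyr::bind_rows(rows)
  attr(report, "all_ok") <- all(report$status == "ok") &&
    all(is.na(report$watertight) | report$watertight)
  report
}
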