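#' Astrocyte morphology container
#'
#' An astrocyte morphology is a single somatic sample plus a set of acyclic
#' arbors (trees of point samples with radii, SWC-style) and an optional list
#' of endfeet patches. The sample table uses micrometres throughout.
#'
#' @param samples A data frame with columns `id` (integer), `structure`
#'   (one of `"soma"`, `"perivascular_process"`, `"perisynaptic_process"`,
#'   `"generic_neurite"`), `x`, `y`, `z` (positions, um), `radius` (um) and
#'   `parent_id` (integer, `NA` for the root/soma sample).
#' @param endfeet A list of [endfoot_patch()] objects.
#' @return An object of class `astro_morphology`.
#' @seealso [read_swc()], [validate_morphology()], [generate_astrocyte()]
#' @export
astro_morphology <- function(samples, endfeet = list()) {
  samples <- as_tibble(samples)
  needed <- c("id", "structure", "x", "y", "z", "radius", "parent_id")
  missing <- setdiff(needed, names(samples))
  if (length(missing))
    stop("sample table lacks columns: ", paste(missing, collapse = ", "))
  samples$id <- as.integer(samples$id)
  samples$parent_id <- as.integer(samples$parent_id)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  if (!all(vapply(endfeet, inherits, logical(1), "endfoot_patch")))
    stop("endfeet must be a list of endfoot_patch objects")
  structure(list(samples = samples[, needed], endfeet = endfeet),
            class = "astro_morphology")
}

#' @export
print.astro_morphology <- function(x, ...) {
  secs <- morphology_sections(x)
  cat(sprintf(
    "<astro_morphology> %d samples, %d arbors, %d sections, %d endfeet\n",
    nrow(x$samples), length(unique(vapply(secs, `[[`, 1L, "arbor"))),
    length(secs), length(x$endfeet)))
  cat(sprintf("  min radius %.4g um (skeleton), soma radius %.4g um\n",
              min(x$samples$radius), soma_sample(x)$radius))
  invisible(x)
}

#' The somatic (root) sample of a morphology
#'
#' @param m An `astro_morphology`.
#' @return A one-row tibble.
#' @export
soma_sample <- function(m) {
  root <- m$samples[is.na(m$samples$parent_id), ]
  if (nrow(root) != 1) stop("morphology must have exactly one root sample")
  root
}

#' First samples of each arbor (the children of the soma)
#'
#' @param m An `astro_morphology`.
#' @return A tibble, one row per arbor root.
#' @export
arbor_roots <- function(m) {
  soma <- soma_sample(m)
  m$samples[!is.na(m$samples$parent_id) & m$samples$parent_id == soma$id, ]
}

#' Decompose a morphology into sections
#'
#' A section is a maximal chain of segments between two branch points (or
#' between a branch point and a terminal). Child sections start at the branch
#' sample they emanate from, so that sample is shared between a parent section
#' and each of its children, and consecutive samples within a section always
#' span one segment.
#'
#' @param m An `astro_morphology`.
#' @return A list of sections; each is a list with `sample_ids` (ordered
#'   integer vector, length >= 2), `parent` (index of the parent section or
#'   `NA`), `arbor` (arbor number) and `depth` (branch order, root section =
#'   1).
#' @export
morphology_sections <- function(m) {
  s <- m$samples
  kids <- split(s$id, factor(s$parent_id, levels = s$id))
  roots <- arbor_roots(m)$id
  .walk_sections(s, kids, roots)
}

# depth-first section walk; child sections start at their branch sample
.walk_sections <- function(s, kids, roots) {
  sections <- list()
  for (a in seq_along(roots)) {
    stack <- list(list(first = roots[a], prefix = integer(0),
                       parent = NA_integer_, depth = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ids <- c(fr$prefix, fr$first)
      cur <- fr$first
      repeat {
        ch <- kids[[as.character(cur)]]
        if (is.null(ch) || length(ch) != 1) break
        cur <- ch
        ids <- c(ids, cur)
      }
      sections[[length(sections) + 1L]] <-
        list(sample_ids = ids, parent = fr$parent, arbor = a, depth = fr$depth)
      this_idx <- length(sections)
      ch <- kids[[as.character(cur)]]
      if (!is.null(ch) && length(ch) > 1) {
        for (c2 in rev(ch))
          stack[[length(stack) + 1L]] <-
            list(first = c2, prefix = cur, parent = this_idx,
                 depth = fr$depth + 1L)
      }
    }
  }
  sections
}

#' Extract the sample table of one section
#'
#' @param m An `astro_morphology`.
#' @param section One element of [morphology_sections()].
#' @return A tibble of samples in section order.
#' @export
section_samples <- function(m, section) {
  idx <- match(section$sample_ids, m$samples$id)
  m$samples[idx, ]
}

#' Smallest radius in a morphology
#'
#' The polygonization resolution rule keys off the smallest radius anywhere in
#' the morphology. Endfeet store a per-vertex thickness (a diameter-like
#' quantity); half of the smallest thickness participates so that skinned
#' endfeet cannot fall below the grid resolution and fragment.
#'
#' @param m An `astro_morphology`.
#' @param include_endfeet Include endfeet half-thickness in the minimum.
#' @return Smallest radius in micrometres.
#' @export
morphology_min_radius <- function(m, include_endfeet = TRUE) {
  r <- min(m$samples$radius)
  if (include_endfeet && length(m$endfeet)) {
    tmin <- min(vapply(m$endfeet, function(p) min(p$thickness), numeric(1)))
    r <- min(r, tmin / 2)
  }
  r
}

#' Validate a morphology against its structural invariants
#'
#' Report-only: violations are listed, never raised. Checked: positive radii,
#' a single root sample, valid parent references, acyclic parent links, and
#' endfeet patch invariants (index validity, thickness length, open manifold).
#'
#' @param m An `astro_morphology`.
#' @return A list of class `astro_validation` with elements `violations`
#'   (tibble: `code`, `sample_id`, `message`), `min_radius`, `n_samples`,
#'   `n_sections`, `n_endfeet` and `valid`.
#' @export
validate_morphology <- function(m) {
  s <- m$samples
  v <- list()
  add <- function(code, sample_id, message)
    v[[length(v) + 1L]] <<- tibble(code = code,
                                   sample_id = as.integer(sample_id),
                                   message = message)
  bad_r <- s$id[s$radius <= 0]
  for (id in bad_r) add("nonpositive_radius", id,
                        sprintf("sample %d has radius <= 0", id))
  roots <- s$id[is.na(s$parent_id)]
  if (length(roots) != 1)
    add("root_count", NA, sprintf("expected 1 root sample, found %d",
                                  length(roots)))
  known <- !is.na(s$parent_id) & !(s$parent_id %in% s$id)
  for (id in s$id[known])
    add("missing_parent", id, sprintf("sample %d references unknown parent", id))
  # cycle check: every sample with a known parent must be reachable from a
  # root (or from a sample whose parent is unknown) by child links
  seeds <- s$id[is.na(s$parent_id) | !(s$parent_id %in% s$id)]
  kids <- split(s$id, factor(s$parent_id, levels = s$id))
  reached <- stats::setNames(rep(FALSE, nrow(s)), s$id)
  frontier <- seeds
  while (length(frontier)) {
    keys <- as.character(frontier)
    fresh <- !reached[keys]
    reached[keys[fresh]] <- TRUE
    frontier <- unlist(kids[keys[fresh]], use.names = FALSE)
  }
  if (!all(reached)) {
    first_bad <- as.integer(names(reached)[!reached][1])
    add("cycle", first_bad,
        sprintf("sample %d lies on a parent-link cycle", first_bad))
  }
  for (i in seq_along(m$endfeet)) {
    probs <- endfoot_violations(m$endfeet[[i]])
    for (p in probs) add("endfoot", i, sprintf("endfoot %d: %s", i, p))
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble(code = character(0), sample_id = integer(0), message = character(0))
  n_sections <- if (length(roots) == 1 && nrow(violations) == 0)
    length(morphology_sections(m)) else NA_integer_
  structure(list(violations = violations,
                 min_radius = min(s$radius),
                 n_samples = nrow(s),
                 n_sections = n_sections,
                 n_endfeet = length(m$endfeet),
                 valid = nrow(violations) == 0),
            class = "astro_validation")
}

#' @export
print.astro_validation <- function(x, ...) {
  cat(sprintf("<astro_validation> %s: %d samples, min radius %.4g um\n",
              if (x$valid) "valid" else "INVALID", x$n_samples, x$min_radius))
  if (!x$valid) print(x$violations)
  invisible(x)
}
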