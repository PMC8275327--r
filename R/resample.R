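#' Resampling policy for oversampled sections
#'
#' Synthesized astrocytic processes are densely oversampled; before skinning,
#' each section is thinned so consecutive kept samples are at least
#' `spacing_factor` times the local radius apart. Section endpoints are
#' always preserved and kept samples are a subset of the originals, so the
#' resampled polyline lies on the original one.
#'
#' @param spacing_factor Minimum inter-sample spacing as a multiple of the
#'   radius of the last kept sample (default 1).
#' @return An object of class `resampling_policy`.
#' @export
resampling_policy <- function(spacing_factor = 1) {
  if (spacing_factor <= 0) stop("spacing_factor must be positive")
  structure(list(spacing_factor = spacing_factor, preserve_endpoints = TRUE),
            class = "resampling_policy")
}

# greedy scan over one ordered sample table; returns a logical keep mask
.resample_keep <- function(xyz, radius, spacing_factor) {
  n <- nrow(xyz)
  keep <- rep(FALSE, n)
  keep[1] <- TRUE
  last <- 1L
  if (n > 2) {
    for (i in 2:(n - 1)) {
      d <- sqrt(sum((xyz[i, ] - xyz[last, ])^2))
      if (d >= spacing_factor * radius[last]) {
        keep[i] <- TRUE
        last <- i
      }
    }
  }
  keep[n] <- TRUE
  keep
}

#' Adaptively resample one section
#'
#' Greedy arc walk: the first and last samples are retained verbatim; an
#' interior sample is kept iff its distance from the last kept sample is at
#' least `spacing_factor` times that sample's radius. Radii and order of kept
#' samples are unchanged.
#'
#' @param s A section sample table (data frame with `x`, `y`, `z`, `radius`;
#'   at least 2 rows).
#' @param p A [resampling_policy()].
#' @return The resampled section (same columns, subset of rows).
#' @export
adaptive_resample_section <- function(s, p = resampling_policy()) {
  if (nrow(s) < 2) stop("a section needs at least 2 samples")
  keep <- .resample_keep(as.matrix(s[, c("x", "y", "z")]), s$radius,
                         p$spacing_factor)
  s[keep, , drop = FALSE]
}

#' Adaptively resample a whole morphology
#'
#' Applies [adaptive_resample_section()] to every section. Branch samples are
#' section endpoints, so they are always retained and the section graph
#' (topology) is unchanged; endfeet are untouched. The operation is
#' idempotent.
#'
#' @param m An [astro_morphology()].
#' @param p A [resampling_policy()].
#' @return The resampled morphology.
#' @export
resample_morphology <- function(m, p = resampling_policy()) {
  secs <- morphology_sections(m)
  s <- m$samples
  pos <- as.matrix(s[, c("x", "y", "z")])
  keep_ids <- soma_sample(m)$id
  for (sec in secs) {
    idx <- match(sec$sample_ids, s$id)
    keep <- .resample_keep(pos[idx, , drop = FALSE], s$radius[idx],
                           p$spacing_factor)
    keep_ids <- c(keep_ids, sec$sample_ids[keep])
  }
  keep_mask <- s$id %in% unique(keep_ids)
  # reconnect: parent = nearest kept ancestor (integer-index ancestor walk)
  pidx <- match(s$parent_id, s$id)
  new_parent <- vapply(which(keep_mask), function(row) {
    cur <- pidx[row]
    while (!is.na(cur) && !keep_mask[cur]) cur <- pidx[cur]
    if (is.na(cur)) NA_integer_ else s$id[cur]
  }, integer(1))
  kept <- s[keep_mask, , drop = FALSE]
  kept$parent_id <- new_parent
  astro_morphology(kept, m$endfeet)
}

#' Compare morphometrics before and after resampling
#'
#' @param before,after Two [astro_morphology()] objects with identical
#'   section topology.
#' @return A tibble with one row per arbor: sample count, section count, max
#'   branch order and total cable length before/after, plus the relative
#'   cable-length change. Overall relative cable change in attribute
#'   `"total_cable_change"`.
#' @export
morphometry_report <- function(before, after) {
  sb <- morphology_sections(before)
  sa <- morphology_sections(after)
  if (length(sb) != length(sa))
    stop(sprintf("section topology mismatch: %d vs %d sections",
                 length(sb), length(sa)))
  arb_b <- vapply(sb, `[[`, 1L, "arbor")
  arb_a <- vapply(sa, `[[`, 1L, "arbor")
  if (!identical(arb_b, arb_a))
    stop("section topology mismatch: arbor assignment differs")
  cable <- function(m, secs) {
    vapply(secs, function(sec) {
      P <- as.matrix(section_samples(m, sec)[, c("x", "y", "z")])
      if (nrow(P) < 2) return(0)
      sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                        P[-nrow(P), , drop = FALSE])^2)))
    }, numeric(1))
  }
  cb <- cable(before, sb)
  ca <- cable(after, sa)
  nb <- vapply(sb, function(x) length(x$sample_ids), integer(1))
  na_ <- vapply(sa, function(x) length(x$sample_ids), integer(1))
  dep <- vapply(sb, `[[`, 1L, "depth")
  per_arbor <- dplyr::summarise(
    dplyr::group_by(tibble(arbor = arb_b, cb = cb, ca = ca, nb = nb,
                           na = na_, depth = dep), .data$arbor),
    n_sections = dplyr::n(),
    samples_before = sum(.data$nb), samples_after = sum(.data$na),
    max_branch_order = max(.data$depth),
    cable_before = sum(.data$cb), cable_after = sum(.data$ca),
    cable_rel_change = (sum(.data$ca) - sum(.data$cb)) /
      max(sum(.data$cb), .Machine$double.eps),
    .groups = "drop")
  attr(per_arbor, "total_cable_change") <-
    (sum(ca) - sum(cb)) / max(sum(cb), .Machine$double.eps)
  per_arbor
}
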