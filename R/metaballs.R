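# --------------------------------------------------------------------------
# Implicit-surface machinery. A metaball contributes a Wyvill soft-object
# kernel field f(d) = (1 - d^2/R^2)^3 inside its influence radius R; fields
# sum, and the surface is the iso_level isocontour (default 0.5). A single
# ball's rendered surface therefore sits at
#     r_s = R * sqrt(1 - iso^(1/3))   (~0.4542 R at iso = 0.5),
# so skeleton radii are divided by that factor when converted to influence
# radii, keeping the rendered tube calibre equal to the morphological radius.
# --------------------------------------------------------------------------

#' Ratio between a metaball's rendered surface radius and influence radius
#'
#' @param iso_level Iso-contour level of the blended field.
#' @return `sqrt(1 - iso_level^(1/3))`, about 0.4542 at the default 0.5.
#' @export
kernel_surface_factor <- function(iso_level = 0.5) {
  if (iso_level <= 0 || iso_level >= 1) stop("iso_level must lie in (0, 1)")
  sqrt(1 - iso_level^(1 / 3))
}

influence_from_surface <- function(r, iso_level = 0.5) {
  r / kernel_surface_factor(iso_level)
}

#' Metaball kernel value
#'
#' Wyvill soft-object kernel: 1 at the centre, continuously decreasing, and
#' exactly 0 at and beyond the influence radius (compact support).
#'
#' @param distance Non-negative distance(s) from the metaball centre (um).
#' @param influence_radius Positive influence radius (um).
#' @return Kernel value(s) in `[0, 1]`.
#' @export
kernel_value <- function(distance, influence_radius) {
  if (any(distance < 0)) stop("distance must be non-negative")
  if (influence_radius <= 0) stop("influence_radius must be positive")
  as.numeric(cpp_kernel_value(as.numeric(distance), influence_radius))
}

#' Construct a meta-object (a set of metaballs plus a polygonization resolution)
#'
#' @param centers n x 3 matrix of ball centres (um).
#' @param influence Length-n vector of influence radii (um).
#' @param resolution Polygonization grid spacing (um); by convention the
#'   smallest sample radius that contributed to the object.
#' @return An object of class `meta_object`.
#' @export
meta_object <- function(centers, influence, resolution) {
  centers <- if (length(centers)) as_matrix3(centers, "centers")
             else matrix(numeric(0), 0, 3)
  influence <- as.numeric(influence)
  if (nrow(centers) != length(influence))
    stop("centers and influence lengths differ")
  if (any(influence <= 0)) stop("influence radii must be positive")
  if (!is.na(resolution) && resolution <= 0) stop("resolution must be positive")
  structure(list(centers = centers, influence = influence,
                 resolution = resolution), class = "meta_object")
}

#' @export
print.meta_object <- function(x, ...) {
  cat(sprintf("<meta_object> %d metaballs, resolution %.4g um\n",
              nrow(x$centers), x$resolution))
  invisible(x)
}

n_balls <- function(mo) nrow(mo$centers)

#' Blended field value of a meta-object at query points
#'
#' The field is the plain sum of all ball kernels (commutative, associative
#' blending). The spatially indexed path must agree with brute-force
#' summation to floating tolerance.
#'
#' @param mo A `meta_object`.
#' @param points An n x 3 matrix (or a single length-3 vector) of query
#'   points (um).
#' @param method `"indexed"` (uniform hash grid over ball centres) or
#'   `"brute"`.
#' @return Numeric vector of field values.
#' @export
field_value <- function(mo, points, method = c("indexed", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as_matrix3(points, "points")
  if (!n_balls(mo)) return(rep(0, nrow(points)))
  cpp_field_at_points(mo$centers, mo$influence, points, method == "indexed")
}

# accept either list(position=, radius=) or a 1-row sample table
as_skin_sample <- function(x) {
  if (is.data.frame(x))
    return(list(position = c(x$x[1], x$y[1], x$z[1]), radius = x$radius[1]))
  if (is.list(x) && !is.null(x[["position"]]))
    return(list(position = as.numeric(x[["position"]]),
                radius = as.numeric(x[["radius"]])))
  stop("expected a sample (list with position/radius or a 1-row sample table)")
}

#' Skin one segment by metaball marching
#'
#' Places a series of metaballs along the segment axis between two samples,
#' evenly spaced no further apart than `step_factor` times the smaller
#' endpoint radius; ball surface radii interpolate linearly between the
#' endpoint radii and both endpoints receive a ball. A zero-length segment
#' yields a single ball.
#'
#' @param a,b Samples: lists with `position` (length 3, um) and `radius`
#'   (um), or 1-row sample tables.
#' @param step_factor Spacing as a multiple of the local radius (default 1).
#' @return A `meta_object` (resolution = smaller endpoint radius).
#' @export
skin_segment <- function(a, b, step_factor = 1) {
  a <- as_skin_sample(a); b <- as_skin_sample(b)
  if (step_factor <= 0) stop("step_factor must be positive")
  L <- vnorm(b$position - a$position)
  if (L == 0)
    return(meta_object(matrix(a$position, 1), influence_from_surface(a$radius),
                       resolution = a$radius))
  rmin <- min(a$radius, b$radius)
  nseg <- max(1L, ceiling(L / (step_factor * rmin)))
  t <- seq(0, 1, length.out = nseg + 1L)
  centers <- cbind(a$position[1] + t * (b$position[1] - a$position[1]),
                   a$position[2] + t * (b$position[2] - a$position[2]),
                   a$position[3] + t * (b$position[3] - a$position[3]))
  radii <- (1 - t) * a$radius + t * b$radius
  meta_object(centers, influence_from_surface(radii), resolution = rmin)
}

#' Skin an arbor into a meta-object
#'
#' Traverses the arbor's sections depth-first and skins every segment with
#' [skin_segment()]; balls are concatenated without deduplication (the field
#' stays finite at shared junction samples). The object's resolution is the
#' smallest sample radius in the arbor.
#'
#' @param m An [astro_morphology()].
#' @param arbor Arbor number (position in [arbor_roots()]).
#' @param step_factor Passed to [skin_segment()].
#' @return A `meta_object`.
#' @export
skin_arbor <- function(m, arbor, step_factor = 1) {
  secs <- morphology_sections(m)
  secs <- secs[vapply(secs, `[[`, 1L, "arbor") == arbor]
  if (!length(secs)) stop("no such arbor: ", arbor)
  parts <- list()
  rmin <- Inf
  for (sec in secs) {
    ss <- section_samples(m, sec)
    rmin <- min(rmin, min(ss$radius))
    if (nrow(ss) < 2) next
    for (i in seq_len(nrow(ss) - 1)) {
      parts[[length(parts) + 1L]] <-
        skin_segment(ss[i, ], ss[i + 1, ], step_factor)
    }
  }
  out <- blend(parts)
  out$resolution <- rmin
  out
}

#' Blend meta-objects into one
#'
#' Balls are concatenated (field summation is commutative and associative)
#' and the resolution is the minimum over the parts.
#'
#' @param parts A non-empty list of `meta_object`s.
#' @return A `meta_object`.
#' @export
blend <- function(parts) {
  if (!length(parts)) stop("blend() needs at least one meta_object")
  if (inherits(parts, "meta_object")) parts <- list(parts)
  meta_object(do.call(rbind, lapply(parts, `[[`, "centers")),
              unlist(lapply(parts, `[[`, "influence")),
              min(vapply(parts, `[[`, numeric(1), "resolution")))
}
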