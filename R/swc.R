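# SWC structure-type codes <-> astrocyte process types.
# 1 = soma; 3 (dendrite-like) = perivascular process; 2 (axon-like) =
# perisynaptic process; anything else = generic neurite.
.swc_code_to_structure <- function(code) {
  out <- rep("generic_neurite", length(code))
  out[code == 1] <- "soma"
  out[code == 3] <- "perivascular_process"
  out[code == 2] <- "perisynaptic_process"
  out
}

.structure_to_swc_code <- function(structure) {
  unname(c(soma = 1L, perivascular_process = 3L, perisynaptic_process = 2L,
           generic_neurite = 5L)[structure])
}

#' Read an astrocyte skeleton from an SWC file
#'
#' Standard whitespace-delimited 7-column SWC (`id type x y z radius parent`,
#' `#` comments). The arbors are reconstructed from the parent links; the
#' endfeet list of the returned morphology is empty (see
#' [read_endfeet_sidecar()]).
#'
#' @param path Path to an SWC file.
#' @return An [astro_morphology()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("SWC file has no data lines: ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("malformed SWC line %d (expected 7 columns, got %d): %s",
                 rows[bad[1]], length(fields[[bad[1]]]), lines[rows[bad[1]]]))
  M <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  nn <- which(apply(is.na(M), 1, any))
  if (length(nn))
    stop(sprintf("malformed SWC line %d (non-numeric field): %s",
                 rows[nn[1]], lines[rows[nn[1]]]))
  samples <- tibble(
    id = as.integer(M[, 1]),
    structure = .swc_code_to_structure(as.integer(M[, 2])),
    x = M[, 3], y = M[, 4], z = M[, 5],
    radius = M[, 6],
    parent_id = ifelse(M[, 7] < 0, NA_integer_, as.integer(M[, 7])))
  m <- astro_morphology(samples)
  roots <- sum(is.na(samples$parent_id))
  if (roots != 1)
    stop(sprintf("SWC validation: expected 1 root sample, found %d", roots))
  val <- validate_morphology(m)
  cyc <- val$violations[val$violations$code %in% c("cycle", "missing_parent"), ]
  if (nrow(cyc)) stop("SWC validation: ", cyc$message[1])
  m
}

#' Write an astrocyte skeleton to an SWC file
#'
#' Positions and radii are written at full double precision so that a
#' read-write-read round trip reproduces the sample table exactly. Endfeet
#' are not part of SWC; see [write_endfeet_sidecar()].
#'
#' @param m An [astro_morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  s <- m$samples
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   s$id, .structure_to_swc_code(s$structure),
                   s$x, s$y, s$z, s$radius,
                   ifelse(is.na(s$parent_id), -1L, s$parent_id))
  writeLines(c("# SWC written by astroskin (positions and radii in um)",
               lines), path)
  invisible(path)
}
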