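#' Indexed triangle surface mesh
#'
#' @param vertices Numeric matrix, n x 3 (um).
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as_matrix3(vertices, "vertices")
  faces <- as_matrix3(faces, "faces")
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Vertex and face counts of a mesh
#'
#' @param m A `tri_mesh`.
#' @return Integer count.
#' @export
n_vertices <- function(m) nrow(m$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(m) nrow(m$faces)

face_corner <- function(m, k) m$vertices[m$faces[, k], , drop = FALSE]

#' Total surface area of a mesh
#'
#' @param m A `tri_mesh`.
#' @return Area in um^2.
#' @export
mesh_area <- function(m) {
  if (!n_faces(m)) return(0)
  n <- rows_cross(face_corner(m, 2) - face_corner(m, 1),
                  face_corner(m, 3) - face_corner(m, 1))
  sum(rows_norm(n)) / 2
}

#' Enclosed volume of a mesh (signed tetrahedra to the origin)
#'
#' @param m A `tri_mesh`.
#' @param signed Return the signed value (positive for coherent outward
#'   orientation) instead of its absolute value.
#' @return Volume in um^3. Only meaningful for closed meshes.
#' @export
mesh_volume <- function(m, signed = FALSE) {
  if (!n_faces(m)) return(0)
  a <- face_corner(m, 1); b <- face_corner(m, 2); c3 <- face_corner(m, 3)
  v <- sum(rowSums(a * rows_cross(b, c3))) / 6
  if (signed) v else abs(v)
}

#' Euler characteristic V - E + F
#'
#' @param m A `tri_mesh`.
#' @return Integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(m) {
  es <- cpp_edge_stats(m$faces)
  nrow(m$vertices) - es$n_edges + nrow(m$faces)
}

# ---------------------------------------------------------------------------
# mesh file IO: ASCII OBJ (primary), OFF, PLY, STL
# ---------------------------------------------------------------------------

#' Write a mesh to OBJ, OFF, PLY or STL
#'
#' The format is chosen from the file extension. All writers are ASCII.
#'
#' @param m A `tri_mesh`.
#' @param path Output path ending in `.obj`, `.off`, `.ply` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  V <- m$vertices; F2 <- m$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "obj") {
    writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("f %d %d %d", F2[, 1], F2[, 2], F2[, 3])), con)
  } else if (ext == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(F2)),
                 sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("3 %d %d %d", F2[, 1] - 1L, F2[, 2] - 1L,
                         F2[, 3] - 1L)), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F2)),
                 "property list uchar int vertex_indices", "end_header",
                 sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("3 %d %d %d", F2[, 1] - 1L, F2[, 2] - 1L,
                         F2[, 3] - 1L)), con)
  } else if (ext == "stl") {
    n <- rows_cross(V[F2[, 2], , drop = FALSE] - V[F2[, 1], , drop = FALSE],
                    V[F2[, 3], , drop = FALSE] - V[F2[, 1], , drop = FALSE])
    len <- pmax(rows_norm(n), 1e-300)
    n <- n / len
    body <- character(7 * nrow(F2))
    for (k in 1:3) {
      P <- V[F2[, k], , drop = FALSE]
      body[seq(2 + k, by = 7, length.out = nrow(F2))] <-
        sprintf("      vertex %.9g %.9g %.9g", P[, 1], P[, 2], P[, 3])
    }
    body[seq(1, by = 7, length.out = nrow(F2))] <-
      sprintf("  facet normal %.9g %.9g %.9g", n[, 1], n[, 2], n[, 3])
    body[seq(2, by = 7, length.out = nrow(F2))] <- "    outer loop"
    body[seq(6, by = 7, length.out = nrow(F2))] <- "    endloop"
    body[seq(7, by = 7, length.out = nrow(F2))] <- "  endfacet"
    writeLines(c("solid astroskin", body, "endsolid astroskin"), con)
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

#' Read a mesh from OBJ, OFF or ASCII PLY
#'
#' @param path Path to a mesh file; format chosen by extension.
#' @return A `tri_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    V <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v", "", vl)),
                                           "\\s+"))), ncol = 3, byrow = TRUE)
    fparts <- strsplit(trimws(sub("^f", "", fl)), "\\s+")
    F2 <- t(vapply(fparts, function(p)
      as.integer(sub("/.*", "", p))[1:3], integer(3)))
    tri_mesh(V, F2)
  } else if (ext == "off") {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
    hdr <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- hdr[1]; nf <- hdr[2]
    V <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]),
                                           "\\s+"))), ncol = 3, byrow = TRUE)
    fl <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
    F2 <- t(vapply(fl, function(p) as.integer(p[2:4]) + 1L, integer(3)))
    tri_mesh(V, F2)
  } else if (ext == "ply") {
    end <- which(trimws(lines) == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)[1]))
    V <- matrix(as.numeric(unlist(strsplit(trimws(lines[(end + 1):(end + nv)]),
                                           "\\s+"))), ncol = 3, byrow = TRUE)
    fl <- strsplit(trimws(lines[(end + nv + 1):(end + nv + nf)]), "\\s+")
    F2 <- t(vapply(fl, function(p) as.integer(p[2:4]) + 1L, integer(3)))
    tri_mesh(V, F2)
  } else stop("unsupported mesh format: .", ext)
}
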