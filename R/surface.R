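#' Triangulated lumen surface
#'
#' A triangle mesh of the vessel/aneurysm wall.  Vertices are in metres;
#' faces index vertices 1-based.  Per-vertex unit normals follow the inward
#' convention (pointing into the lumen) once computed by
#' [compute_vertex_normals()]; a freshly constructed or freshly read surface
#' has `normals = NULL`.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (m).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @param orientation `"inward"` or `"none"`; records whether `normals`
#'   follow the inward convention.
#' @return an object of class `"tri_surface"`.
#' @export
tri_surface <- function(vertices, faces, normals = NULL,
                        orientation = if (is.null(normals)) "none" else "inward") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!identical(dim(normals), dim(vertices)))
      stop("`normals` must match `vertices` in shape")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("vertex normals must have unit length (tolerance 1e-6)")
  }
  structure(
    list(vertices = vertices, faces = faces, normals = normals,
         orientation = orientation),
    class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("tri_surface:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      if (is.null(x$normals)) "no normals" else
        paste0(x$orientation, " normals"), "\n")
  invisible(x)
}

# Per-face (unnormalised) normal vectors: cross((v2-v1), (v3-v1)).
# Their norm is twice the triangle area.
face_normals_raw <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Merge exactly coincident vertices
#'
#' Collapses vertices with bit-identical coordinates (no tolerance merging,
#' so topology is deterministic) and remaps faces.
#'
#' @param surface a [tri_surface].
#' @return a [tri_surface] with duplicate vertices removed.
#' @export
dedup_vertices <- function(surface) {
  v <- surface$vertices
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "\r")
  first <- !duplicated(key)
  newid <- match(key, key[first])  # position of each vertex in the kept set
  tri_surface(v[first, , drop = FALSE],
              matrix(newid[surface$faces], ncol = 3))
}

#' Build a triangulated open cylinder wall
#'
#' A structured triangulation of the lateral wall of a cylinder of radius
#' `radius` about the z axis, spanning `z` in `[0, length]`.  Used as the
#' lumen surface of the Poiseuille phantom; the ends stay open (no caps),
#' matching a clipped vessel segment.
#'
#' @param radius cylinder radius, m.
#' @param length axial extent, m.
#' @param n_theta number of circumferential subdivisions (>= 3).
#' @param n_z number of axial vertex rings (>= 2).
#' @return a [tri_surface] without normals.
#' @export
cylinder_surface <- function(radius, length, n_theta = 48, n_z = 24) {
  stopifnot(radius > 0, length > 0, n_theta >= 3, n_z >= 2)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  z <- seq(0, length, length.out = n_z)
  verts <- cbind(
    radius * rep(cos(th), times = n_z),
    radius * rep(sin(th), times = n_z),
    rep(z, each = n_theta)
  )
  vid <- function(it, iz) (iz - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  it <- rep(seq_len(n_theta), times = n_z - 1)
  iz <- rep(seq_len(n_z - 1), each = n_theta)
  # two triangles per quad, wound counter-clockwise seen from outside
  f1 <- cbind(vid(it, iz), vid(it + 1L, iz), vid(it + 1L, iz + 1L))
  f2 <- cbind(vid(it, iz), vid(it + 1L, iz + 1L), vid(it, iz + 1L))
  tri_surface(verts, rbind(f1, f2))
}
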