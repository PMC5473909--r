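#' Triangular surface mesh
#'
#' Constructs a `trimesh` object, the basic unit every computation in the
#' package starts from: a set of 3D vertices and a set of triangular faces
#' indexing them.  Coordinates are dimensionless; they carry whatever length
#' unit the source data uses (microns for confocal reconstructions).
#'
#' Faces with more than three vertices are rejected here; the file readers
#' triangulate polygons fan-wise before calling this constructor.  Degenerate
#' (zero-area) triangles are dropped with a warning, so a freshly constructed
#' mesh never contains them.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), one row per vertex.
#' @param faces integer matrix with 3 columns of 1-based vertex indices,
#'   one row per triangle, consistent winding assumed.
#' @param vertex_data optional data frame of per-vertex scalar attachments
#'   (e.g. curvature fields), one row per vertex.
#' @param drop_degenerate drop zero-area faces (default `TRUE`).
#' @return an object of class `trimesh` with elements `vertices`, `faces`
#'   and `vertex_data`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'              rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
#' mesh_volume(m)
#' @export
trimesh <- function(vertices, faces, vertex_data = NULL,
                    drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop("'faces' must have 3 columns (triangles only)")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(vertex_data)) {
    vertex_data <- as.data.frame(vertex_data)
    if (nrow(vertex_data) != nrow(vertices))
      stop("'vertex_data' must have one row per vertex")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      vertex_data = vertex_data),
                 class = "trimesh")
  if (drop_degenerate && nrow(faces) > 0L) {
    a <- triangle_areas(m)
    bad <- a <= .Machine$double.eps * max(a, 1)
    if (any(bad)) {
      warning(sprintf("dropped %d degenerate (zero-area) face(s)", sum(bad)))
      m$faces <- m$faces[!bad, , drop = FALSE]
    }
  }
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$vertex_data))
    cat("  vertex data:", paste(names(x$vertex_data), collapse = ", "), "\n")
  invisible(x)
}

# per-face corner coordinate matrices (list of three n_face x 3 matrices)
face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(v[f[, 1L], , drop = FALSE],
       v[f[, 2L], , drop = FALSE],
       v[f[, 3L], , drop = FALSE])
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

triangle_areas <- function(mesh) {
  p <- face_corners(mesh)
  cr <- cross3(p[[2L]] - p[[1L]], p[[3L]] - p[[1L]])
  0.5 * sqrt(rowSums(cr * cr))
}

# unit face normals following the winding order
face_normals <- function(mesh) {
  p <- face_corners(mesh)
  cr <- cross3(p[[2L]] - p[[1L]], p[[3L]] - p[[1L]])
  n <- sqrt(rowSums(cr * cr))
  cr / pmax(n, .Machine$double.xmin)
}

# directed edge table: one row per face half-edge (3 per face)
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1L], f[, 2L], f[, 3L]),
        to   = c(f[, 2L], f[, 3L], f[, 1L]))
}

# undirected edge keys as character "lo-hi"
edge_keys <- function(he) {
  lo <- pmin(he[, 1L], he[, 2L])
  hi <- pmax(he[, 1L], he[, 2L])
  paste(lo, hi, sep = "-")
}

#' Validate a mesh's topology
#'
#' Checks closedness (every edge shared by exactly two faces), manifoldness,
#' orientation consistency, and outward orientation (positive signed volume),
#' and reports vertex/face/boundary-edge counts plus the Euler characteristic
#' `V - E + F` (2 for a closed genus-0 surface, 0 for a torus).  The mesh is
#' never modified and validation never throws.
#'
#' @param mesh a [trimesh()].
#' @return a list of class `mesh_validation` with fields `is_closed`,
#'   `is_manifold`, `is_oriented`, `is_outward_oriented`, `n_vertices`,
#'   `n_faces`, `n_edges`, `n_boundary_edges`, `euler_characteristic`.
#' @export
validate_mesh <- function(mesh) {
  he <- half_edges(mesh)
  keys <- edge_keys(he)
  cnt <- table(keys)
  n_edges <- length(cnt)
  n_boundary <- sum(cnt == 1L)
  manifold <- all(cnt <= 2L)
  closed <- manifold && n_boundary == 0L && nrow(mesh$faces) > 0L
  # orientation: a shared undirected edge must occur once in each direction
  dir_keys <- paste(he[, 1L], he[, 2L], sep = ">")
  oriented <- manifold && !anyDuplicated(dir_keys)
  outward <- NA
  if (closed && oriented)
    outward <- signed_volume(mesh) > 0
  res <- list(
    is_closed = closed,
    is_manifold = manifold,
    is_oriented = oriented,
    is_outward_oriented = outward,
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    n_edges = n_edges,
    n_boundary_edges = n_boundary,
    euler_characteristic =
      nrow(mesh$vertices) - n_edges + nrow(mesh$faces))
  class(res) <- "mesh_validation"
  res
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("mesh validation report\n")
  cat(sprintf("  vertices %d, faces %d, edges %d (boundary %d)\n",
              x$n_vertices, x$n_faces, x$n_edges, x$n_boundary_edges))
  cat(sprintf("  closed: %s  manifold: %s  oriented: %s  outward: %s\n",
              x$is_closed, x$is_manifold, x$is_oriented,
              x$is_outward_oriented))
  cat(sprintf("  Euler characteristic: %d\n", x$euler_characteristic))
  invisible(x)
}

# logical vector: TRUE for vertices not touching any boundary edge
interior_vertices <- function(mesh) {
  he <- half_edges(mesh)
  keys <- edge_keys(he)
  cnt <- table(keys)
  boundary_keys <- names(cnt)[cnt == 1L]
  on_boundary <- rep(FALSE, nrow(mesh$vertices))
  if (length(boundary_keys)) {
    idx <- he[keys %in% boundary_keys, , drop = FALSE]
    on_boundary[unique(as.vector(idx))] <- TRUE
  }
  !on_boundary
}

#' Surface area of a mesh
#'
#' Sum of the areas of all triangles.
#'
#' @param mesh a [trimesh()].
#' @return total surface area (squared length units).
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  sum(triangle_areas(mesh))
}

# signed volume via the divergence theorem (sum of origin tetrahedra)
signed_volume <- function(mesh) {
  p <- face_corners(mesh)
  sum(rowSums(p[[1L]] * cross3(p[[2L]], p[[3L]]))) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Absolute value of the signed sum of origin tetrahedra (divergence
#' theorem); translation-invariant for closed surfaces.
#'
#' @param mesh a closed, consistently oriented [trimesh()].
#' @return enclosed volume (cubed length units).
#' @export
mesh_volume <- function(mesh) {
  val <- validate_mesh(mesh)
  if (!val$is_closed)
    stop("mesh is not closed; run validate_mesh() to inspect it")
  abs(signed_volume(mesh))
}

#' Sphericity of a closed shape
#'
#' The dimensionless ratio \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / \Sigma}.
#' It equals 1 for a perfect sphere and decreases with eccentricity or
#' asymmetry of the surface; it is invariant under rigid motions and
#' uniform scaling.
#'
#' @param V enclosed volume (or a [trimesh()], in which case `Sigma` is
#'   ignored and both measures are taken from the mesh).
#' @param Sigma surface area.
#' @return sphericity in (0, 1] for real closed surfaces.
#' @export
sphericity <- function(V, Sigma = NULL) {
  if (inherits(V, "trimesh")) {
    Sigma <- mesh_area(V)
    V <- mesh_volume(V)
  }
  if (!is.numeric(V) || !is.numeric(Sigma) || V <= 0 || Sigma <= 0)
    stop("volume and surface area must be positive numbers")
  pi^(1 / 3) * (6 * V)^(2 / 3) / Sigma
}
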