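#' Triangle surface meshes with labeled open boundaries
#'
#' A `surface_mesh` holds a triangulated surface as a `k x 3` matrix of
#' vertex coordinates (millimetres), a `t x 3` integer matrix of vertex
#' indices (one triangle per row), and an optional named list of boundary
#' loops.  Each loop is an ordered cyclic vector of vertex indices tracing
#' one open boundary of the surface; labels (e.g. `"root"`, `"descending"`,
#' `"SA1"`) identify anatomically corresponding openings across meshes and
#' are used as landmark constraints during registration.
#'
#' @param vertices numeric matrix, `k x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `t x 3`, 1-based vertex indices.
#' @param boundary_loops optional named list of integer vectors, each an
#'   ordered closed cycle of vertex indices along one open boundary.
#' @param validate check the mesh invariants (finite coordinates, indices in
#'   range, no degenerate faces, every edge on at most two faces)?
#'
#' @return An object of class `surface_mesh`.
#' @export
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     matrix(c(1L, 2L, 3L), 1))
#' n_vertices(tri)
surface_mesh <- function(vertices, faces, boundary_loops = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         boundary_loops = boundary_loops),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @rdname surface_mesh
#' @param mesh a `surface_mesh`.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  k <- nrow(v)
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > k) stop("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      stop("mesh contains degenerate faces (repeated vertex index)")
    ec <- edge_face_count(f)
    if (any(ec$count > 2L)) {
      bad <- ec$edges[which(ec$count > 2L)[1L], ]
      stop(sprintf("non-manifold edge (%d, %d) shared by more than 2 faces",
                   bad[1L], bad[2L]))
    }
  }
  if (!is.null(mesh$boundary_loops)) {
    labs <- names(mesh$boundary_loops)
    if (is.null(labs) || anyDuplicated(labs))
      stop("boundary loops must carry unique labels")
    for (lp in mesh$boundary_loops)
      if (min(lp) < 1L || max(lp) > k) stop("boundary loop index out of range")
  }
  invisible(mesh)
}

#' @rdname surface_mesh
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname surface_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", n_vertices(x), n_faces(x)))
  if (!is.null(x$boundary_loops))
    cat(sprintf(", %d labeled boundary loops (%s)",
                length(x$boundary_loops),
                paste(names(x$boundary_loops), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# unique undirected edges of a face matrix, as a 2-column matrix with
# edge[,1] < edge[,2]; `count` gives the number of incident faces per edge.
edge_face_count <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  first <- !duplicated(key)
  uk <- key[first]
  list(edges = e[first, , drop = FALSE],
       count = as.integer(tab[uk]),
       key = uk)
}

#' Edge set of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return Integer matrix, one unique undirected edge per row.
#' @export
mesh_edges <- function(mesh) {
  if (n_faces(mesh) == 0L) return(matrix(integer(0), 0L, 2L))
  edge_face_count(mesh$faces)$edges
}

#' Surface area and average edge length
#'
#' `surface_area()` sums the areas of all triangles (mm^2);
#' `mean_edge_length()` averages the lengths of the unique mesh edges (mm).
#' Matched average edge length across a dataset is the practical meaning of
#' remeshing every surface to a vertex count proportional to its area.
#'
#' @param mesh a `surface_mesh`.
#' @return A scalar, mm^2 or mm.
#' @export
surface_area <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  v <- mesh$vertices
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname surface_area
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  if (nrow(e) == 0L) return(NA_real_)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Area-proportional vertex count
#'
#' Vertex budget for remeshing a surface of area `area` so that its average
#' edge length matches a template of area `template_area` remeshed at `base`
#' vertices: `round(base * area / template_area)`.
#'
#' @param area,template_area surface areas, mm^2 (positive).
#' @param base vertex count assigned to the template surface.
#' @return Integer vertex count.
#' @export
scaled_vertex_count <- function(area, template_area, base) {
  stopifnot(area > 0, template_area > 0, base > 0)
  as.integer(round(base * area / template_area))
}
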