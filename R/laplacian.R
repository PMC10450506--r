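#' Combinatorial Laplacian of a mesh
#'
#' Builds the graph Laplacian of the mesh edge graph with unit edge weights:
#' `L[i,j] = -1` for every edge `(i,j)`, `L[i,i] = deg(i)`, zero elsewhere.
#' The operator is symmetric, has zero row sums and is positive
#' semidefinite; `<f, L f>` is the discrete Dirichlet energy of a vertex
#' signal `f`, the smoothness measure the registration optimizer uses to
#' diffuse gradients over the surface.
#'
#' Boundary vertices are treated like interior ones (same combinatorial
#' rule).  Isolated vertices are retained with an all-zero row, with a
#' warning, so that the operator always matches the mesh dimension.
#'
#' @param mesh a [surface_mesh()], or a 2-column integer matrix of edges
#'   (in which case `n` gives the number of vertices).
#' @param n vertex count when `mesh` is an edge matrix.
#' @return A `laplacian_operator`: list with `matrix` (a
#'   [Matrix::sparseMatrix()], `dsCMatrix`) and `mesh_hash` binding it to
#'   the topology it was built from.
#' @export
#' @examples
#' tri <- surface_mesh(diag(3), matrix(c(1L, 2L, 3L), 1))
#' as.matrix(build_combinatorial_laplacian(tri)$matrix)
build_combinatorial_laplacian <- function(mesh, n = NULL) {
  if (inherits(mesh, "surface_mesh")) {
    edges <- mesh_edges(mesh)
    n <- n_vertices(mesh)
    hash <- topology_hash(mesh$faces, n)
  } else {
    edges <- as.matrix(mesh)
    storage.mode(edges) <- "integer"
    if (is.null(n)) n <- max(edges)
    hash <- topology_hash(edges, n)
  }
  if (n < 2L || nrow(edges) < 1L)
    stop("Laplacian needs at least 2 vertices and 1 edge")
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (any(deg == 0L))
    warning("mesh has isolated vertices; their Laplacian rows are zero")
  # upper-triangle entries only (edges are stored with i < j)
  L <- Matrix::sparseMatrix(
    i = c(edges[, 1], seq_len(n)),
    j = c(edges[, 2], seq_len(n)),
    x = c(rep(-1, nrow(edges)), deg),
    dims = c(n, n), symmetric = TRUE
  )
  structure(list(matrix = L, mesh_hash = hash),
            class = "laplacian_operator")
}

topology_hash <- function(faces, n) {
  # cheap order-sensitive hash of the connectivity
  x <- as.double(t(faces))
  sprintf("k%d-t%d-%.0f", n, length(x) %/% 3L,
          sum(x * seq_along(x)) %% 2^31)
}

#' Dirichlet energy of a vertex signal
#'
#' `<f, L f>` for a signal `f` defined on the mesh vertices.  Zero for
#' constant signals on any mesh; grows with the variability of `f` across
#' edges (it equals the sum of squared differences of `f` over all edges).
#'
#' @param L a `laplacian_operator` (or a sparse/dense matrix).
#' @param f numeric vector (or `k x d` matrix; columns are summed).
#' @return Non-negative scalar.
#' @export
dirichlet_energy <- function(L, f) {
  M <- if (inherits(L, "laplacian_operator")) L$matrix else L
  f <- as.matrix(f)
  if (nrow(f) != nrow(M))
    stop(sprintf("signal length %d does not match operator dimension %d",
                 nrow(f), nrow(M)))
  sum(colSums(f * as.matrix(M %*% f)))
}
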