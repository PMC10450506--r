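#' Uniform-density cluster decimation
#'
#' Remeshes a triangle mesh to approximately `n_target` vertices by Lloyd
#' clustering of the vertex set: vertices are grouped into `n_target`
#' spatially compact clusters, each cluster is collapsed to its centroid,
#' and faces are re-indexed (degenerate and duplicate faces dropped).  This
#' is the resolution-control step used both for dataset homogenisation
#' (vertex counts scaled by surface area, see [scaled_vertex_count()]) and
#' to build the coarse levels of the multi-scale registration.
#'
#' The cluster seeds are placed by systematic sampling of the vertex list
#' and refined by a fixed number of Lloyd iterations, so the result is
#' deterministic.  The method name is recorded in the `remeshing` attribute
#' of the output.
#'
#' @param mesh a [surface_mesh()].
#' @param n_target requested vertex count, `10 <= n_target`; if
#'   `n_target >= n_vertices(mesh)` the input is returned unchanged with a
#'   warning.
#' @param iters Lloyd refinement iterations.
#' @return A [surface_mesh()] with close to `n_target` vertices (within a
#'   few percent).  Boundary-loop labels are not carried over; use
#'   [label_loops_nearest()] to recover them.
#' @export
decimate_to_count <- function(mesh, n_target, iters = 10L) {
  k <- n_vertices(mesh)
  n_target <- as.integer(n_target)
  if (n_target >= k) {
    warning("n_target >= vertex count; returning mesh unchanged")
    return(mesh)
  }
  stopifnot(n_target >= 10L)
  v <- mesh$vertices

  centers <- v[round(seq(1L, k, length.out = n_target)), , drop = FALSE]
  assign <- NULL
  for (it in seq_len(iters)) {
    assign <- nn_index(v, centers)
    sums <- rowsum(v, assign, reorder = FALSE)
    cnt <- as.integer(table(factor(assign, levels = seq_len(n_target))))
    grp <- as.integer(rownames(sums))
    centers[grp, ] <- sums / cnt[grp]
    empty <- which(cnt == 0L)
    if (length(empty) > 0L) {
      # reseed empty clusters at the vertices farthest from their center
      d <- rowSums((v - centers[assign, , drop = FALSE])^2)
      far <- order(d, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- v[far, , drop = FALSE]
    }
  }
  assign <- nn_index(v, centers)

  f <- matrix(assign[mesh$faces], ncol = 3L)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  # drop duplicate faces (same vertex triple in any order)
  tri_key <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
  f <- f[!duplicated(tri_key), , drop = FALSE]
  # enforce edge-manifoldness: drop later faces on over-shared edges
  repeat {
    ec <- edge_face_count(f)
    over <- ec$key[ec$count > 2L]
    if (length(over) == 0L) break
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    fk <- matrix(ek %in% over, ncol = 3L)
    bad_faces <- which(rowSums(fk) > 0L)
    # keep the first two faces per offending edge, drop the rest
    drop <- logical(nrow(f))
    for (oe in over) {
      fidx <- which(matrix(ek == oe, ncol = 3L) %*% rep(1L, 3L) > 0L)
      drop[fidx[-(1:2)]] <- TRUE
    }
    if (!any(drop)) break
    f <- f[!drop, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(n_target)
  remap[used] <- seq_along(used)
  out <- surface_mesh(centers[used, , drop = FALSE],
                      matrix(remap[f], ncol = 3L), validate = FALSE)
  attr(out, "remeshing") <- "systematic-seed Lloyd vertex clustering"
  out
}
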