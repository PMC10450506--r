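#' Extract the open-boundary loops of a mesh
#'
#' Boundary edges are the mesh edges incident to exactly one face.  They are
#' grouped into closed cycles, each returned as an ordered vector of vertex
#' indices.  Loops are oriented following the winding of their adjacent
#' faces, i.e. counter-clockwise with respect to the outward normal for a
#' consistently wound mesh.  A closed surface returns an empty list; an open
#' tube returns two loops; a branched vessel clipped at its root, distal end
#' and three branches returns five.
#'
#' Labeling is a separate step: loops come back unlabeled, in discovery
#' order.  Use [label_loops_nearest()] to transfer labels from a labeled
#' reference mesh.
#'
#' @param mesh a [surface_mesh()].
#' @return List of integer vectors (possibly empty), one per loop.
#' @export
extract_boundary_loops <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(list())
  # directed edges as they appear in faces
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[which(cnt > 2L)[1L]]
    stop(sprintf("non-manifold boundary edge (%s) shared by more than 2 faces",
                 gsub(" ", ", ", bad)))
  }
  isb <- cnt[key] == 1L
  bd <- de[isb, , drop = FALSE]       # directed boundary edges, face winding
  if (nrow(bd) == 0L) return(list())
  # walk cycles: tail -> head following the face orientation; if the face
  # winding is inconsistent (possible after decimation repairs), fall back
  # to an undirected walk, which loses the orientation convention only
  loops <- tryCatch(walk_loops(bd, directed = TRUE),
                    error = function(e) walk_loops(bd, directed = FALSE))
  loops
}

walk_loops <- function(bd, directed = TRUE) {
  if (!directed)
    bd <- rbind(bd, bd[, 2:1, drop = FALSE])   # both directions available
  ekey <- paste(bd[, 1], bd[, 2])
  nxt <- split(seq_len(nrow(bd)), bd[, 1])
  used <- rep(FALSE, nrow(bd))
  mark_used <- function(e) {
    used[e] <<- TRUE
    if (!directed) {
      rev <- which(bd[, 1] == bd[e, 2] & bd[, 2] == bd[e, 1])
      used[rev] <<- TRUE
    }
  }
  loops <- list()
  for (e0 in seq_len(nrow(bd))) {
    if (used[e0]) next
    start <- bd[e0, 1]
    v <- start
    loop <- integer(0)
    repeat {
      loop <- c(loop, v)
      cand <- nxt[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L)
        stop("open boundary walk failed: boundary edges do not close a loop")
      e <- cand[1L]
      mark_used(e)
      v <- bd[e, 2]
      if (v == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

loop_centroid <- function(mesh, loop) {
  colMeans(mesh$vertices[loop, , drop = FALSE])
}

#' Transfer boundary-loop labels from a reference mesh
#'
#' Each labeled loop of `ref_mesh` is matched, greedily and one-to-one in
#' order of increasing centroid distance, to one unlabeled loop of `mesh`.
#' Used to recover labels on decimated meshes at coarse registration
#' scales, where vertex indices change but loop positions persist.
#'
#' @param mesh a [surface_mesh()] whose loops are to be labeled.
#' @param loops optional list of loops of `mesh` (default: extracted).
#' @param ref_mesh a [surface_mesh()] with labeled `boundary_loops`.
#' @return `mesh` with `boundary_loops` set to a named list, or `NULL` when
#'   the loop counts differ (label recovery failed).
#' @export
label_loops_nearest <- function(mesh, ref_mesh, loops = NULL) {
  if (is.null(loops)) loops <- extract_boundary_loops(mesh)
  ref <- ref_mesh$boundary_loops
  if (is.null(ref) || length(loops) != length(ref)) return(NULL)
  rc <- t(vapply(ref, loop_centroid, numeric(3), mesh = ref_mesh))
  lc <- t(vapply(loops, loop_centroid, numeric(3), mesh = mesh))
  nr <- nrow(rc)
  D <- outer(seq_len(nr), seq_len(nr),
             Vectorize(function(i, j) sum((rc[i, ] - lc[j, ])^2)))
  assign <- rep(NA_integer_, nr)
  for (step in seq_len(nr)) {
    ij <- arrayInd(which.min(D), dim(D))
    assign[ij[1L]] <- ij[2L]
    D[ij[1L], ] <- Inf
    D[, ij[2L]] <- Inf
  }
  mesh$boundary_loops <- setNames(loops[assign], names(ref))
  mesh
}
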