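#' Chamfer, root-Chamfer and Hausdorff distances between point sets
#'
#' `chamfer_distance()` is the symmetric mean of squared nearest-neighbour
#' distances between two point sets (mm^2): the average squared distance
#' from every point of `A` to its nearest point of `B`, plus the same with
#' the roles swapped.  It is the registration objective.
#' `root_chamfer()` is its square root (mm), reported so that it is
#' comparable with the Hausdorff distance.  `hausdorff_distance()` is the
#' worst-case symmetric nearest-neighbour distance (mm): the larger of the
#' two directed max–min distances.
#'
#' All three operate on mesh vertices (point clouds), not on the continuous
#' surfaces; pass `mesh$vertices` or any `n x 3` matrix.
#'
#' @param A,B numeric matrices, `n x 3` / `m x 3`, or [surface_mesh()]
#'   objects (their vertices are used).  Both must be non-empty.
#' @return A non-negative scalar.
#' @export
#' @examples
#' A <- rbind(c(0, 0, 0), c(1, 0, 0))
#' B <- rbind(c(0, 0, 0))
#' chamfer_distance(A, B)   # (0 + 1)/2 + 0 = 0.5
#' hausdorff_distance(A, B) # 1
chamfer_distance <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  ab <- nn_sqdist(A, B)
  ba <- nn_sqdist(B, A)
  mean(ab) + mean(ba)
}

#' @rdname chamfer_distance
#' @export
root_chamfer <- function(A, B) sqrt(chamfer_distance(A, B))

#' @rdname chamfer_distance
#' @export
hausdorff_distance <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  sqrt(max(max(nn_sqdist(A, B)), max(nn_sqdist(B, A))))
}

as_points <- function(x) {
  if (inherits(x, "surface_mesh")) x <- x$vertices
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("point set is empty")
  if (ncol(x) != 3L) stop("point sets must be n x 3 matrices")
  if (!all(is.finite(x))) stop("point set has non-finite coordinates")
  x
}

# squared distance from each row of A to its nearest neighbour in B
nn_sqdist <- function(A, B) {
  idx <- nn_index(A, B)
  rowSums((A - B[idx, , drop = FALSE])^2)
}
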