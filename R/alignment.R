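#' Rigid transforms
#'
#' A rotation (proper orthogonal, `det = +1`) plus a translation, in mm.
#' No scaling is ever included: overall size is treated as part of the
#' anatomical variability and must survive alignment.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3L, 3L)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-8,
            det(rotation) > 0)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param points `n x 3` matrix or [surface_mesh()].
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "surface_mesh")) {
    points$vertices <- apply_transform(transform, points$vertices)
    return(points)
  }
  sweep(points %*% t(transform$rotation), 2L, -transform$translation)
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform`s; `compose_transforms(a, b)` applies `b`
#'   first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

# closed-form correspondence-based rigid Procrustes fit (Kabsch):
# the rigid transform minimising || R x_i + t - y_i ||^2, det(R) = +1
kabsch <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, mx), sweep(Y, 2L, my))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, my - as.vector(R %*% mx))
}

#' Iterative closest point rigid alignment
#'
#' Aligns `moving` onto `fixed` by alternating nearest-neighbour
#' correspondence with the closed-form rigid Procrustes fit, until the mean
#' nearest-neighbour distance stops improving by more than `tol`.  Used to
#' remove gross pose differences before non-rigid registration; on the
#' synthetic data it is applied to the analytic centerline polylines, and
#' it can also be applied to surface vertices directly.
#'
#' @param moving,fixed `n x 3` point matrices (>= 3 non-collinear points).
#' @param max_iters iteration cap.
#' @param tol convergence tolerance on the mean NN distance, mm.
#' @return A [rigid_transform()] mapping `moving` onto `fixed`.
#' @export
icp_rigid <- function(moving, fixed, max_iters = 100L, tol = 1e-8) {
  moving <- as_points(moving); fixed <- as_points(fixed)
  check_non_collinear <- function(P) {
    s <- svd(sweep(P, 2L, colMeans(P)))$d
    if (length(s) < 2L || s[2L] < 1e-9 * max(s[1L], 1))
      stop("degenerate (collinear) point set in icp_rigid")
  }
  check_non_collinear(moving); check_non_collinear(fixed)
  tr <- rigid_transform()
  prev <- Inf
  for (it in seq_len(max_iters)) {
    cur <- apply_transform(tr, moving)
    idx <- nn_index(cur, fixed)
    tr <- kabsch(moving, fixed[idx, , drop = FALSE])
    d <- mean(sqrt(rowSums((apply_transform(tr, moving) -
                              fixed[idx, , drop = FALSE])^2)))
    if (prev - d < tol) break
    prev <- d
  }
  tr
}

#' Pack and unpack shape vectors
#'
#' A shape vector concatenates the vertex coordinates interleaved per
#' vertex: `(x1, y1, z1, ..., xk, yk, zk)`.  All shapes of a dataset must
#' share one topology (face matrix) so that entries correspond across
#' shapes.
#'
#' @param mesh a [surface_mesh()].
#' @return `pack_shape()`: numeric vector of length `3k`.
#' @export
pack_shape <- function(mesh) as.vector(t(mesh$vertices))

#' @rdname pack_shape
#' @param shape numeric vector of length `3k`.
#' @param topology face matrix shared by the dataset.
#' @param boundary_loops optional named loop list to attach.
#' @export
unpack_shape <- function(shape, topology, boundary_loops = NULL) {
  if (length(shape) %% 3L != 0L)
    stop("shape vector length is not divisible by 3")
  surface_mesh(matrix(shape, ncol = 3L, byrow = TRUE), topology,
               boundary_loops = boundary_loops, validate = FALSE)
}

#' Shape datasets
#'
#' An `M x 3k` matrix of shape vectors (rows, see [pack_shape()]) over one
#' shared topology.
#'
#' @param shapes `M x 3k` numeric matrix, or list of [surface_mesh()].
#' @param topology face matrix (taken from the first mesh when `shapes` is
#'   a mesh list).
#' @return An object of class `shape_dataset`.
#' @export
shape_dataset <- function(shapes, topology = NULL) {
  if (is.list(shapes)) {
    topology <- topology %||% shapes[[1L]]$faces
    shapes <- do.call(rbind, lapply(shapes, pack_shape))
  }
  stopifnot(is.matrix(shapes), ncol(shapes) %% 3L == 0L)
  structure(list(shapes = shapes, topology = topology),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat(sprintf("<shape_dataset> %d shapes x %d vertices\n",
              nrow(x$shapes), ncol(x$shapes) %/% 3L))
  invisible(x)
}

#' Generalized Procrustes alignment
#'
#' Iteratively rigid-aligns every shape of the dataset to the evolving mean
#' shape (rotation and translation only — no scaling, so size variation is
#' retained), recomputing the mean after each sweep, until the maximum
#' absolute coordinate change of the mean between iterations falls below
#' `tol_mm`.  The Procrustes objective `sum_i ||s_i - s_bar||^2` is
#' non-increasing across iterations.
#'
#' @param dataset a [shape_dataset()] with at least 2 shapes in point
#'   correspondence.
#' @param tol_mm convergence tolerance on the mean shape, mm.
#' @param max_iters iteration cap.
#' @return List with `dataset` (aligned [shape_dataset()]), `mean` (the
#'   3k mean shape vector), `iterations`, and `objective` (per-iteration
#'   `sum_i ||s_i - s_bar||^2` trace).
#' @export
gpa <- function(dataset, tol_mm = 0.001, max_iters = 100L) {
  X <- dataset$shapes
  M <- nrow(X)
  if (M < 2L) stop("GPA needs at least 2 shapes")
  k3 <- ncol(X)
  as_mat <- function(s) matrix(s, ncol = 3L, byrow = TRUE)
  as_vec <- function(m) as.vector(t(m))
  mean_shape <- colMeans(X)
  objective <- numeric(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    mref <- as_mat(mean_shape)
    for (i in seq_len(M)) {
      tr <- kabsch(as_mat(X[i, ]), mref)
      X[i, ] <- as_vec(apply_transform(tr, as_mat(X[i, ])))
    }
    new_mean <- colMeans(X)
    objective <- c(objective, sum(sweep(X, 2L, new_mean)^2))
    delta <- max(abs(new_mean - mean_shape))
    mean_shape <- new_mean
    if (delta < tol_mm || iterations >= max_iters) break
  }
  list(dataset = shape_dataset(X, dataset$topology),
       mean = mean_shape, iterations = iterations, objective = objective)
}
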