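#' Registration configuration
#'
#' Bundles the per-scale schedule of the multi-scale non-rigid registration
#' (coarse to fine: point count, iteration count `N`, regularisation
#' `gamma`, learning rate `eta`), the open-boundary weights `alpha`, the
#' momentum constants, and the displacement-interpolation settings.
#'
#' The default schedule is the three-scale setting used for aortic
#' surfaces: 4,000 / 18,000 / 20,000 points with `N` = 700 / 1,000 / 1,500,
#' `gamma` = 120 / 80 / 50 and `eta` = 0.007 / 0.01 / 0.02, with all
#' boundary weights `alpha = 0.1`.  `gamma` decreases towards fine scales:
#' coarse scales should move large-scale features smoothly, fine scales may
#' recover detail.  For the small synthetic meshes used in examples and
#' tests, pass a reduced schedule via `scales`.
#'
#' @param scales list of lists with fields `point_count`, `iterations`,
#'   `gamma`, `learning_rate`, ordered coarse to fine (strictly increasing
#'   point counts; the last entry is used at native resolution).
#' @param alpha boundary-constraint weight: a single scalar applied to all
#'   labels, or a named vector per label.  `0` disables the constraint.
#' @param momentum use the uniform-Adam momentum optimizer? (`FALSE` gives
#'   plain preconditioned gradient descent.)
#' @param beta1,beta2,eps_adam momentum constants.
#' @param rbf_smoothing,rbf_max_control_points displacement-field
#'   interpolation settings, see [fit_displacement_rbf()].
#' @param seed integer seed recorded with results.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(scales = aorta_scale_schedule(),
                                alpha = 0.1,
                                momentum = TRUE,
                                beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
                                rbf_smoothing = 0,
                                rbf_max_control_points = 5000L,
                                seed = 1L) {
  pc <- vapply(scales, `[[`, 0, "point_count")
  if (any(diff(pc) <= 0))
    stop("scales must have strictly increasing point counts (coarse to fine)")
  structure(list(scales = scales, alpha = alpha, momentum = momentum,
                 beta1 = beta1, beta2 = beta2, eps_adam = eps_adam,
                 rbf_smoothing = rbf_smoothing,
                 rbf_max_control_points = as.integer(rbf_max_control_points),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' @rdname registration_config
#' @export
aorta_scale_schedule <- function() {
  list(list(point_count = 4000L, iterations = 700L, gamma = 120, learning_rate = 0.007),
       list(point_count = 18000L, iterations = 1000L, gamma = 80, learning_rate = 0.01),
       list(point_count = 20000L, iterations = 1500L, gamma = 50, learning_rate = 0.02))
}

# resolve the alpha spec against the labels present on both meshes
resolve_alpha <- function(alpha, source, target) {
  ls <- names(source$boundary_loops); lt <- names(target$boundary_loops)
  if (is.null(names(alpha))) {
    if (length(alpha) != 1L) stop("unnamed `alpha` must be a single scalar")
    if (alpha == 0) return(setNames(numeric(0), character(0)))
    labels <- ls
    alpha <- setNames(rep(alpha, length(labels)), labels)
  }
  alpha <- alpha[alpha > 0]
  miss <- setdiff(names(alpha), intersect(ls, lt))
  if (length(miss) > 0L)
    stop("boundary label(s) missing on source or target: ",
         paste(miss, collapse = ", "))
  alpha
}

#' Boundary-constrained registration objective
#'
#' The Chamfer distance between the full vertex sets plus, for every
#' labeled open boundary `j`, `alpha_j` times the Chamfer distance between
#' the two loops' vertex subsets.  The boundary terms act as anatomical
#' landmarks: they pull each labeled opening of the source onto the
#' same-label opening of the target.
#'
#' @param source,target [surface_mesh()] objects; every label with a
#'   positive weight must be present on both.
#' @param alpha boundary weights (scalar or named vector; default 0.1).
#' @return Scalar objective value (mm^2), with attribute `"terms"` holding
#'   the surface term and each boundary term.
#' @export
objective <- function(source, target, alpha = 0.1) {
  alpha <- resolve_alpha(alpha, source, target)
  surf <- chamfer_distance(source$vertices, target$vertices)
  bnd <- vapply(names(alpha), function(lb) {
    chamfer_distance(source$vertices[source$boundary_loops[[lb]], , drop = FALSE],
                     target$vertices[target$boundary_loops[[lb]], , drop = FALSE])
  }, 0)
  total <- surf + sum(alpha * bnd)
  attr(total, "terms") <- c(surface = surf, setNames(alpha * bnd, names(alpha)))
  total
}

# gradient of the Chamfer distance w.r.t. the rows of S, with
# nearest-neighbour assignments held fixed
chamfer_gradient <- function(S, T) {
  iST <- nn_index(S, T)
  iTS <- nn_index(T, S)
  g <- (2 / nrow(S)) * (S - T[iST, , drop = FALSE])
  pull <- (2 / nrow(T)) * (S[iTS, , drop = FALSE] - T)
  acc <- rowsum(pull, iTS, reorder = FALSE)
  rows <- as.integer(rownames(acc))
  g[rows, ] <- g[rows, , drop = FALSE] + acc
  g
}

#' One preconditioned gradient-descent step
#'
#' `x - eta * (I + gamma * L)^{-1} grad`, solved per coordinate column with
#' a sparse Cholesky factorisation.  The inverse diffuses the gradient over
#' the mesh: the step field is smoother (lower Dirichlet energy) than the
#' raw gradient, which prevents tangling and inverted elements during
#' registration.  `gamma = 0` reduces exactly to plain gradient descent.
#'
#' @param x `k x 3` vertex coordinates.
#' @param grad `k x 3` gradient (must be finite).
#' @param L a `laplacian_operator` for the mesh topology of `x`.
#' @param gamma regularisation weight (>= 0).
#' @param eta learning rate.
#' @param factor optional prefactored `Matrix::Cholesky(I + gamma L)`,
#'   reused across iterations.
#' @return Updated `k x 3` coordinates.
#' @export
preconditioned_step <- function(x, grad, L, gamma, eta, factor = NULL) {
  if (!all(is.finite(grad)))
    stop("non-finite gradient: optimization diverged")
  x - eta * precondition_direction(grad, L, gamma, factor)
}

precondition_direction <- function(grad, L, gamma, factor = NULL) {
  if (gamma == 0) return(grad)
  if (is.null(factor)) factor <- laplacian_factor(L, gamma)
  as.matrix(Matrix::solve(factor, grad))
}

laplacian_factor <- function(L, gamma) {
  M <- if (inherits(L, "laplacian_operator")) L$matrix else L
  A <- Matrix::Diagonal(nrow(M)) + gamma * M
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
}

#' Uniform-Adam momentum steps
#'
#' Adam-style first/second moment accumulation with bias correction, with
#' one modification: the second-moment normaliser is spatially uniform — a
#' single scalar, the maximum of the bias-corrected second moment over all
#' entries — so the update direction is globally rescaled rather than
#' re-weighted per vertex.  Per-vertex normalisation would undo the
#' Laplacian smoothing of the gradient field; a uniform normaliser keeps
#' the direction field intact while still adapting the step magnitude.
#'
#' @param beta1,beta2,eps exponential decay rates and numerical floor.
#' @return `uniform_adam_init()`: an optimizer state.
#'   `uniform_adam_step()`: list with updated `state` and the step
#'   `direction` (same shape as `grad`).
#' @export
uniform_adam_init <- function(beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = NULL, v = NULL, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' @rdname uniform_adam_init
#' @param state optimizer state from `uniform_adam_init()`.
#' @param grad gradient array.
#' @export
uniform_adam_step <- function(state, grad) {
  if (all(grad == 0)) {
    state$t <- state$t + 1L
    return(list(state = state, direction = grad * 0))
  }
  if (is.null(state$m)) {
    state$m <- grad * 0
    state$v <- grad * 0
  }
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  denom <- sqrt(max(vhat)) + state$eps
  list(state = state, direction = mhat / denom)
}

#' Single-scale non-rigid registration
#'
#' Runs a fixed number of iterations of: evaluate the boundary-constrained
#' Chamfer objective, differentiate it with nearest-neighbour assignments
#' held fixed, pass the gradient through the uniform-Adam momentum
#' accumulator, smooth the resulting direction with the Laplacian
#' preconditioner `(I + gamma L)^{-1}`, and take an `eta`-scaled step.
#' Connectivity never changes; only vertex coordinates move.
#'
#' @param source,target [surface_mesh()] objects with labeled loops (for
#'   any label with positive weight).
#' @param iterations fixed iteration count `N`.
#' @param gamma Laplacian regularisation weight.
#' @param learning_rate step size `eta`.
#' @param alpha boundary weights (scalar or named; 0 disables).
#' @param momentum use uniform-Adam momentum? `FALSE` gives plain
#'   preconditioned gradient descent.
#' @param beta1,beta2,eps_adam momentum constants.
#' @param scale_id label recorded in the loss trace.
#' @return A `registration_result`: list with `registered_mesh`,
#'   `loss_trace` (tibble: scale, iteration, objective, surface term and
#'   one column per boundary label), `final_chamfer` (mm^2),
#'   `final_hausdorff` (mm).
#' @export
register <- function(source, target, iterations = 500L, gamma = 50,
                     learning_rate = 0.02, alpha = 0.1, momentum = TRUE,
                     beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
                     scale_id = 1L) {
  alpha <- resolve_alpha(alpha, source, target)
  x <- source$vertices
  Tv <- target$vertices
  L <- build_combinatorial_laplacian(source)
  factor <- if (gamma > 0) laplacian_factor(L, gamma) else NULL
  adam <- uniform_adam_init(beta1, beta2, eps_adam)
  labels <- names(alpha)
  loops_s <- source$boundary_loops[labels]
  loops_t <- target$boundary_loops[labels]

  trace <- matrix(NA_real_, iterations, 2L + length(labels))
  colnames(trace) <- c("iteration", "objective_surface", labels)
  for (it in seq_len(iterations)) {
    surf <- chamfer_distance(x, Tv)
    g <- chamfer_gradient(x, Tv)
    bvals <- numeric(length(labels))
    for (j in seq_along(labels)) {
      Bs <- x[loops_s[[j]], , drop = FALSE]
      Bt <- Tv[loops_t[[j]], , drop = FALSE]
      bvals[j] <- chamfer_distance(Bs, Bt)
      g[loops_s[[j]], ] <- g[loops_s[[j]], , drop = FALSE] +
        alpha[j] * chamfer_gradient(Bs, Bt)
    }
    obj <- surf + sum(alpha * bvals)
    if (!is.finite(obj))
      stop(sprintf("non-finite objective at iteration %d", it))
    trace[it, ] <- c(it, surf, alpha * bvals)
    # smooth the raw gradient first, then let the momentum normaliser set
    # the step length of the (already smooth) direction field; with a
    # spatially uniform normaliser the two orders give parallel directions
    if (!all(is.finite(g)))
      stop(sprintf("non-finite gradient at iteration %d", it))
    dirn <- precondition_direction(g, L, gamma, factor)
    if (momentum) {
      st <- uniform_adam_step(adam, dirn)
      adam <- st$state
      dirn <- st$direction
    }
    x <- x - learning_rate * dirn
  }

  reg <- source
  reg$vertices <- x
  out_trace <- tibble::as_tibble(as.data.frame(trace))
  bnd_sum <- if (length(labels)) rowSums(out_trace[, labels, drop = FALSE]) else 0
  out_trace <- tibble::add_column(out_trace,
    scale = scale_id, .before = 1L)
  out_trace$objective <- out_trace$objective_surface + bnd_sum
  structure(list(registered_mesh = reg,
                 loss_trace = out_trace,
                 final_chamfer = chamfer_distance(x, Tv),
                 final_hausdorff = hausdorff_distance(x, Tv),
                 alpha = alpha),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %d iterations over %d scale(s)\n  final sqrt(Chamfer) %.4g mm, Hausdorff %.4g mm\n",
    nrow(x$loss_trace), length(unique(x$loss_trace$scale)),
    sqrt(x$final_chamfer), x$final_hausdorff))
  invisible(x)
}

#' Radial-basis-function displacement fields
#'
#' Interpolates the displacement `after - before` with a polyharmonic
#' (thin-plate type, kernel `r`) radial basis expansion plus an appended
#' linear polynomial, fitted to the control points.  With `smoothing = 0`
#' the field reproduces the control displacements exactly and, thanks to
#' the polynomial term, reproduces any affine (hence any rigid)
#' displacement exactly everywhere.  Used to transfer the deformation found
#' at a coarse registration scale onto the next finer mesh.
#'
#' @param before,after `n x 3` matrices of control positions and their
#'   displaced positions.
#' @param smoothing ridge term added to the kernel diagonal (>= 0).
#' @param max_control_points systematic subsampling threshold.
#' @return A `displacement_field`; evaluate with [evaluate_field()].
#' @export
fit_displacement_rbf <- function(before, after, smoothing = 0,
                                 max_control_points = 5000L) {
  before <- as_points(before); after <- as_points(after)
  if (nrow(before) != nrow(after))
    stop("`before` and `after` must have the same number of points")
  disp <- after - before
  key <- apply(round(before, 10L), 1L, paste, collapse = ",")
  if (anyDuplicated(key)) {
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    grp <- split(seq_len(nrow(before))[d], key[d])
    for (g in grp)
      if (max(abs(sweep(disp[g, , drop = FALSE], 2L, disp[g[1L], ]))) > 1e-12)
        stop("duplicate control points with conflicting displacements")
    keep <- !duplicated(key)
    before <- before[keep, , drop = FALSE]
    disp <- disp[keep, , drop = FALSE]
  }
  n <- nrow(before)
  if (n > max_control_points) {
    keep <- round(seq(1L, n, length.out = max_control_points))
    before <- before[keep, , drop = FALSE]
    disp <- disp[keep, , drop = FALSE]
    n <- nrow(before)
  }
  # solve in centred, unit-scale coordinates for conditioning
  centre <- colMeans(before)
  scale <- mean(sqrt(rowSums(sweep(before, 2L, centre)^2)))
  if (scale <= 0) scale <- 1
  bs <- sweep(before, 2L, centre) / scale
  K <- as.matrix(stats::dist(bs))
  diag(K) <- 0
  if (smoothing > 0) K <- K + diag(smoothing, n)
  P <- cbind(1, bs)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(disp, matrix(0, 4L, 3L))
  coef <- solve(A, rhs)
  # one step of iterative refinement tightens the interpolation conditions
  coef <- coef + solve(A, rhs - A %*% coef)
  structure(list(control_points = before, centre = centre, scale = scale,
                 weights = coef[seq_len(n), , drop = FALSE],
                 poly = coef[n + 1:4, , drop = FALSE],
                 smoothing = smoothing, kernel = "polyharmonic-r"),
            class = "displacement_field")
}

#' @rdname fit_displacement_rbf
#' @param field a `displacement_field`.
#' @param query `m x 3` matrix of evaluation points.
#' @return `evaluate_field()`: `m x 3` matrix of displacements.
#' @export
evaluate_field <- function(field, query) {
  query <- as_points(query)
  qs <- sweep(query, 2L, field$centre) / field$scale
  cp <- sweep(field$control_points, 2L, field$centre) / field$scale
  n <- nrow(qs)
  out <- matrix(NA_real_, n, 3L)
  # direct coordinate differences (chunked): accurate where the expanded
  # inner-product formula would cancel catastrophically near the controls
  step <- max(1L, floor(2e6 / nrow(cp)))
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(n, i0 + step - 1L)
    D <- sqrt(outer(qs[ii, 1], cp[, 1], "-")^2 +
              outer(qs[ii, 2], cp[, 2], "-")^2 +
              outer(qs[ii, 3], cp[, 3], "-")^2)
    out[ii, ] <- D %*% field$weights
  }
  out + cbind(1, qs) %*% field$poly
}

#' Multi-scale non-rigid registration
#'
#' Coarse-to-fine driver: source and target are decimated to each scale's
#' point count, the coarsest pair is registered, the resulting displacement
#' is interpolated with an RBF field and applied to the next finer source,
#' and the process repeats up to native resolution.  Boundary labels are
#' recovered on each decimated mesh by nearest-centroid matching against
#' the native labeled loops; if recovery fails at some scale, that scale
#' runs unconstrained (`alpha = 0`) with a warning recorded in the result.
#'
#' @param source,target [surface_mesh()] objects with labeled loops.
#' @param config a [registration_config()].
#' @return A `registration_result` whose `registered_mesh` is
#'   isotopological to `source`; `loss_trace` concatenates all scales.
#' @export
multiscale_register <- function(source, target, config = registration_config()) {
  scales <- config$scales
  n <- length(scales)
  src_levels <- vector("list", n)
  tgt_levels <- vector("list", n)
  fallback <- logical(n)
  for (l in seq_len(n)) {
    pc <- scales[[l]]$point_count
    if (pc >= n_vertices(source)) {
      src_levels[[l]] <- source
    } else {
      dm <- decimate_to_count(source, pc)
      lm <- label_loops_nearest(dm, source)
      if (is.null(lm)) { fallback[l] <- TRUE; src_levels[[l]] <- dm }
      else src_levels[[l]] <- lm
    }
    if (pc >= n_vertices(target)) {
      tgt_levels[[l]] <- target
    } else {
      dm <- decimate_to_count(target, pc)
      lm <- label_loops_nearest(dm, target)
      if (is.null(lm)) { fallback[l] <- TRUE; tgt_levels[[l]] <- dm }
      else tgt_levels[[l]] <- lm
    }
  }
  if (any(fallback))
    warning("boundary-label recovery failed at scale(s) ",
            paste(which(fallback), collapse = ", "),
            "; those scales run with alpha = 0")

  field <- NULL
  traces <- vector("list", n)
  res <- NULL
  for (l in seq_len(n)) {
    s_l <- src_levels[[l]]
    if (!is.null(field))
      s_l$vertices <- s_l$vertices + evaluate_field(field, s_l$vertices)
    sc <- scales[[l]]
    res <- register(s_l, tgt_levels[[l]],
                    iterations = sc$iterations, gamma = sc$gamma,
                    learning_rate = sc$learning_rate,
                    alpha = if (fallback[l]) 0 else config$alpha,
                    momentum = config$momentum,
                    beta1 = config$beta1, beta2 = config$beta2,
                    eps_adam = config$eps_adam, scale_id = l)
    traces[[l]] <- res$loss_trace
    if (l < n)
      field <- fit_displacement_rbf(s_l$vertices, res$registered_mesh$vertices,
                                    smoothing = config$rbf_smoothing,
                                    max_control_points = config$rbf_max_control_points)
  }
  res$loss_trace <- bind_traces(traces)
  res$fallback_scales <- which(fallback)
  res
}

# row-bind loss traces whose boundary-term columns may differ across scales
bind_traces <- function(traces) {
  cols <- unique(unlist(lapply(traces, names)))
  filled <- lapply(traces, function(tr) {
    for (cn in setdiff(cols, names(tr))) tr[[cn]] <- NA_real_
    tr[, cols]
  })
  do.call(rbind, filled)
}
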