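#' Fit a PCA statistical shape model
#'
#' Eigendecomposition of the shape covariance `S = 1/(M-1) * sum_i (s_i -
#' s_bar)(s_i - s_bar)^T` of a Procrustes-aligned [shape_dataset()],
#' keeping the `m = min(M - 1, 3k)` principal modes.  Because `3k >> M`,
#' the decomposition is computed through the `M x M` Gram matrix (dual
#' PCA), which is mathematically identical.  Eigenvalues below zero by
#' rounding are clipped to 0; each eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive, for reproducibility.
#'
#' @param dataset a GPA-aligned [shape_dataset()] with `M >= 2` shapes.
#' @return An `ssm_model`: list with `mean` (3k vector), `modes` (`m x 3k`
#'   orthonormal rows), `variances` (eigenvalues, mm^2, descending),
#'   `topology`, `M`.
#' @export
fit_pca <- function(dataset) {
  X <- dataset$shapes
  M <- nrow(X)
  if (M < 2L) stop("PCA needs at least 2 shapes")
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2L, mean_shape)
  m <- min(M - 1L, ncol(X))
  G <- tcrossprod(Xc) / (M - 1)      # M x M Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  lambda <- pmax(eg$values[seq_len(m)], 0)
  # eigenvalues at numerical noise level are true zeros of the covariance
  lambda[lambda <= lambda[1L] * 1e-12] <- 0
  modes <- matrix(0, m, ncol(X))
  for (j in seq_len(m)) {
    if (lambda[j] > 0) {
      v <- crossprod(Xc, eg$vectors[, j]) / sqrt(lambda[j] * (M - 1))
      v <- as.vector(v)
      if (v[which.max(abs(v))] < 0) v <- -v
      modes[j, ] <- v
    }
  }
  structure(list(mean = mean_shape, modes = modes, variances = lambda,
                 topology = dataset$topology, M = M),
            class = "ssm_model")
}

#' @export
print.ssm_model <- function(x, ...) {
  tot <- sum(x$variances)
  cat(sprintf("<ssm_model> %d training shapes, %d vertices, %d modes\n",
              x$M, length(x$mean) %/% 3L, length(x$variances)))
  if (tot > 0)
    cat(sprintf("  leading variances (mm^2): %s\n",
                paste(signif(head(x$variances, 5L), 4L), collapse = ", ")))
  invisible(x)
}

#' Cumulative explained variance
#'
#' Fraction of total shape variance carried by the first `i` modes,
#' `sum_{j<=i} lambda_j / sum_j lambda_j`.  Non-decreasing in `i`, equal to
#' 1 at `i = m`.  For a degenerate dataset with zero total variance the
#' fraction is defined as 1 for every `i`.
#'
#' @param model an `ssm_model`.
#' @param i mode count, `1 <= i <= m` (vectorised).
#' @return Fraction(s) in `[0, 1]`.
#' @export
cumulative_variance <- function(model, i) {
  stopifnot(all(i >= 1L), all(i <= length(model$variances)))
  tot <- sum(model$variances)
  if (tot == 0) return(rep(1, length(i)))
  cumsum(model$variances)[i] / tot
}

#' Generate a shape from mode coefficients
#'
#' `s = s_bar + sum_i omega_i * phi_i`: the mean shape displaced along the
#' principal modes.  Setting a single `omega_i = ±3 * sqrt(lambda_i)` gives
#' the conventional extreme shapes of mode `i`.
#'
#' @param model an `ssm_model`.
#' @param omega numeric coefficient vector (length <= number of modes).
#' @return A [surface_mesh()] with the model topology.
#' @export
generate_shape <- function(model, omega) {
  stopifnot(length(omega) <= nrow(model$modes))
  s <- model$mean
  if (length(omega) > 0L)
    s <- s + as.vector(crossprod(model$modes[seq_along(omega), , drop = FALSE],
                                 omega))
  unpack_shape(s, model$topology)
}

#' Project a shape into the model's latent space
#'
#' Coefficients of the first `K` modes: `omega_i = <s - s_bar, phi_i>`.
#'
#' @param model an `ssm_model`.
#' @param shape a 3k shape vector or [surface_mesh()].
#' @param K number of modes (default: all).
#' @return Numeric vector of length `K`.
#' @export
project_shape <- function(model, shape, K = nrow(model$modes)) {
  if (inherits(shape, "surface_mesh")) shape <- pack_shape(shape)
  if (length(shape) != length(model$mean))
    stop("shape dimension does not match the model")
  stopifnot(K <= nrow(model$modes))
  as.vector(model$modes[seq_len(K), , drop = FALSE] %*% (shape - model$mean))
}

#' Reconstruct a shape from its first K modes
#'
#' @param model an `ssm_model`.
#' @param shape a 3k shape vector or [surface_mesh()].
#' @param K number of modes used.
#' @return The reconstructed 3k shape vector.
#' @export
reconstruct_shape <- function(model, shape, K = nrow(model$modes)) {
  om <- project_shape(model, shape, K)
  model$mean + if (K > 0L)
    as.vector(crossprod(model$modes[seq_len(K), , drop = FALSE], om))
  else 0
}

#' Tidy an SSM into a per-mode tibble
#'
#' @param x an `ssm_model`.
#' @param ... unused.
#' @return A tibble with one row per mode: `mode`, `variance_mm2`,
#'   `sd_mm`, `variance_fraction`, `cumulative_fraction`.
#' @importFrom generics tidy
#' @export
tidy.ssm_model <- function(x, ...) {
  lam <- x$variances
  tot <- sum(lam)
  tibble::tibble(mode = seq_along(lam),
                 variance_mm2 = lam,
                 sd_mm = sqrt(lam),
                 variance_fraction = if (tot > 0) lam / tot else rep(1, length(lam)),
                 cumulative_fraction = cumulative_variance(x, seq_along(lam)))
}

#' @rdname tidy.ssm_model
#' @importFrom generics glance
#' @export
glance.ssm_model <- function(x, ...) {
  tibble::tibble(n_shapes = x$M,
                 n_vertices = length(x$mean) %/% 3L,
                 n_modes = length(x$variances),
                 total_variance_mm2 = sum(x$variances),
                 modes_90pct = modes_for_variance(x, 0.90),
                 modes_99pct = modes_for_variance(x, 0.99))
}

#' Smallest mode count reaching a variance fraction
#'
#' @param model an `ssm_model`.
#' @param fraction target cumulative variance fraction in `(0, 1]`.
#' @return Integer mode count.
#' @export
modes_for_variance <- function(model, fraction) {
  cv <- cumulative_variance(model, seq_along(model$variances))
  as.integer(which(cv >= fraction - 1e-12)[1L])
}

#' Save / load an SSM as plain-text files
#'
#' The mean shape is written as a PLY mesh (`<stem>.mean.ply`), the modes
#' and variances as a compressed-free CSV (`<stem>.modes.csv`: one row per
#' mode, first column the variance) and a small JSON metadata header
#' (`<stem>.meta.json`: k, M, m and the covariance normalisation).
#'
#' @param model an `ssm_model`.
#' @param stem file path stem.
#' @return `save_ssm()`: `stem`, invisibly; `load_ssm()`: an `ssm_model`.
#' @export
save_ssm <- function(model, stem) {
  save_mesh(unpack_shape(model$mean, model$topology),
            paste0(stem, ".mean.ply"), binary = FALSE)
  utils::write.csv(
    cbind(variance = model$variances, model$modes),
    paste0(stem, ".modes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = length(model$mean) %/% 3L, M = model$M,
         m = length(model$variances),
         normalization = "1/(M-1)"),
    paste0(stem, ".meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname save_ssm
#' @export
load_ssm <- function(stem) {
  mesh <- load_mesh(paste0(stem, ".mean.ply"))
  tab <- utils::read.csv(paste0(stem, ".modes.csv"))
  meta <- jsonlite::fromJSON(paste0(stem, ".meta.json"))
  structure(list(mean = pack_shape(mesh),
                 modes = as.matrix(tab[, -1L, drop = FALSE]),
                 variances = tab[[1L]],
                 topology = mesh$faces, M = meta$M),
            class = "ssm_model")
}
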