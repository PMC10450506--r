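# Independent brute-force oracles.  These deliberately share no code with
# the package implementation: plain O(n*m) double loops over dense
# distance matrices.

cross_dist2 <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- sum((A[i, ] - B[j, ])^2)
  out
}

chamfer_brute <- function(A, B) {
  D2 <- cross_dist2(A, B)
  mean(apply(D2, 1L, min)) + mean(apply(D2, 2L, min))
}

hausdorff_brute <- function(A, B) {
  D2 <- cross_dist2(A, B)
  sqrt(max(max(apply(D2, 1L, min)), max(apply(D2, 2L, min))))
}

# straight-line reimplementation of the three intrinsic SSM metrics on a
# raw shape matrix X (rows = packed shapes), plain loops, no package
# calls: rigid Procrustes fits via SVD, iterative alignment to the
# evolving mean, leave-one-out PCA via the dense covariance.
metrics_straightline <- function(X, K, H, seed, gpa_tol = 0.001) {
  as_m <- function(s) matrix(s, ncol = 3, byrow = TRUE)
  as_v <- function(m) as.vector(t(m))
  rigid_fit_sl <- function(P, Q) {       # rotation+translation P -> Q
    mp <- colMeans(P); mq <- colMeans(Q)
    Hm <- t(P - rep(1, nrow(P)) %o% mp) %*% (Q - rep(1, nrow(Q)) %o% mq)
    sv <- svd(Hm)
    dd <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dd)) %*% t(sv$u)
    list(R = R, t = mq - as.vector(R %*% mp))
  }
  apply_sl <- function(tr, P) P %*% t(tr$R) + rep(1, nrow(P)) %o% tr$t
  gpa_sl <- function(Y, tol = gpa_tol, max_it = 100) {
    mu <- colMeans(Y)
    for (it in seq_len(max_it)) {
      for (i in seq_len(nrow(Y))) {
        tr <- rigid_fit_sl(as_m(Y[i, ]), as_m(mu))
        Y[i, ] <- as_v(apply_sl(tr, as_m(Y[i, ])))
      }
      mu_new <- colMeans(Y)
      if (max(abs(mu_new - mu)) < tol) { mu <- mu_new; break }
      mu <- mu_new
    }
    list(Y = Y, mean = mu)
  }
  pca_sl <- function(Y) {
    mu <- colMeans(Y)
    Yc <- Y - rep(1, nrow(Y)) %o% mu
    S <- crossprod(Yc) / (nrow(Y) - 1)
    eg <- eigen(S, symmetric = TRUE)
    m <- min(nrow(Y) - 1, ncol(Y))
    vec <- eg$vectors[, seq_len(m), drop = FALSE]
    for (j in seq_len(m)) {
      vj <- vec[, j]
      if (vj[which.max(abs(vj))] < 0) vec[, j] <- -vj
    }
    list(mean = mu, vec = vec, lam = pmax(eg$values[seq_len(m)], 0))
  }
  vdist <- function(a, b) mean(sqrt(rowSums((as_m(a) - as_m(b))^2)))

  M <- nrow(X)
  # generalisation: leave-one-out, re-align the reduced set, rigid-align
  # the excluded shape to the reduced mean, project on K modes
  eps <- numeric(M)
  for (i in seq_len(M)) {
    red <- gpa_sl(X[-i, , drop = FALSE])
    p <- pca_sl(red$Y)
    tr <- rigid_fit_sl(as_m(X[i, ]), as_m(p$mean))
    s <- as_v(apply_sl(tr, as_m(X[i, ])))
    om <- t(p$vec[, seq_len(K), drop = FALSE]) %*% (s - p$mean)
    rec <- p$mean + as.vector(p$vec[, seq_len(K), drop = FALSE] %*% om)
    eps[i] <- vdist(s, rec)
  }
  G <- mean(eps^2)
  # specificity on the aligned full set
  al <- gpa_sl(X)
  p <- pca_sl(al$Y)
  set.seed(seed)
  epr <- numeric(H)
  for (j in seq_len(H)) {
    om <- rnorm(K, 0, sqrt(p$lam[seq_len(K)]))
    s <- p$mean + as.vector(p$vec[, seq_len(K), drop = FALSE] %*% om)
    dd <- apply(al$Y, 1, function(row) vdist(s, row))
    epr[j] <- min(dd)
  }
  S <- mean(epr)
  C <- sum(p$lam[seq_len(K)]) / sum(p$lam)
  list(G = G, S = S, C = C)
}

principal_angles_deg <- function(A, B) {
  # A, B: matrices with orthonormal rows spanning the two subspaces
  sv <- svd(A %*% t(B))$d
  acos(pmin(1, pmax(-1, sv))) * 180 / pi
}
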