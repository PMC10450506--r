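make_aligned_population <- function(n_vertices = 700, M = 10, seed = 1,
                                    variances = c(9, 4, 1), noise_sd = 0) {
  vt <- small_tree(n_vertices, seed = 2)
  pl <- plant_shape_modes(vt$mesh, variances = variances, M = M, seed = seed,
                          noise_sd = noise_sd)
  list(ds = gpa(shape_dataset(pl$shapes, vt$mesh$faces))$dataset,
       pl = pl, mesh = vt$mesh, tree = vt)
}

test_that("generalisation vanishes for identical shapes and nests in K", {
  tb <- generate_tube(40, 6, 150)
  s <- pack_shape(tb$mesh)
  ident <- shape_dataset(rbind(s, s, s, s), tb$mesh$faces)
  G <- generalisation(ident, c(0, 1))
  expect_equal(unname(G), c(0, 0), tolerance = 1e-16)
  # population with exactly 2 planted modes: K >= 2 not worse than K = 1
  pop <- make_aligned_population(M = 10, variances = c(9, 4))
  G2 <- generalisation(pop$ds, c(0, 1, 2, 3))
  expect_lte(G2[["K2"]], G2[["K1"]])
  expect_lte(G2[["K3"]], G2[["K2"]] + 1e-12)
  # K = 0: squared mean per-vertex distance to the reduced mean
  expect_gt(G2[["K0"]], G2[["K1"]])
})

test_that("specificity is seeded, degenerate-safe and zero for clones", {
  tb <- generate_tube(40, 6, 150)
  s <- pack_shape(tb$mesh)
  ident <- shape_dataset(rbind(s, s, s), tb$mesh$faces)
  mod0 <- fit_pca(ident)
  expect_equal(specificity(ident, mod0, K = 1, H = 20, seed = 1), 0)
  pop <- make_aligned_population(M = 8)
  model <- fit_pca(pop$ds)
  s1 <- specificity(pop$ds, model, K = 2, H = 40, seed = 11)
  s2 <- specificity(pop$ds, model, K = 2, H = 40, seed = 11)
  expect_identical(s1, s2)
  expect_gt(s1, 0)
  # all variances forced to zero: every sample is the mean shape
  model0 <- model
  model0$variances[] <- 0
  sm <- specificity(pop$ds, model0, K = 3, H = 5, seed = 1)
  d_mean <- min(apply(pop$ds$shapes, 1, function(r)
    mean(sqrt(rowSums(matrix(model$mean - r, ncol = 3, byrow = TRUE)^2)))))
  expect_equal(sm, d_mean, tolerance = 1e-10)
  expect_error(specificity(pop$ds, model, K = 2, H = 10), "seed")
})

test_that("compactness matches the planted variance structure", {
  pop <- make_aligned_population(M = 40, noise_sd = 0.02, seed = 3)
  model <- fit_pca(pop$ds)
  expect_gt(compactness(model, 3), 0.9)
  expect_equal(compactness(model, length(model$variances)), 1)
  cv <- compactness(model, 1:5)
  expect_true(all(diff(cv) >= -1e-12))
})

test_that("regional metrics reduce to global ones for the full mask", {
  pop <- make_aligned_population(M = 8)
  k <- ncol(pop$ds$shapes) %/% 3L
  glob <- evaluate_ssm(pop$ds, K_values = 1:2, H = 20, seed = 5)
  regi <- regional_metrics(pop$ds, seq_len(k), K_values = 1:2, H = 20, seed = 5)
  expect_equal(glob$G_mm2, regi$G_mm2, tolerance = 1e-10)
  expect_equal(glob$S_mm, regi$S_mm, tolerance = 1e-10)
  expect_equal(glob$C_fraction, regi$C_fraction, tolerance = 1e-10)
  expect_error(regional_metrics(pop$ds, integer(0), 1:2, H = 5, seed = 1),
               "empty")
})

test_that("a region untouched by the variation has zero generalisation", {
  vt <- small_tree(600, seed = 2)
  base <- pack_shape(vt$mesh)
  k <- n_vertices(vt$mesh)
  # plant variation only on the second half of the vertices
  active <- (k %/% 2L):k
  set.seed(8)
  X <- t(replicate(6, {
    s <- base
    idx <- as.vector(t(outer(active, 1:3, function(v, c) 3 * (v - 1) + c)))
    s[idx] <- s[idx] + rnorm(length(idx), 0, 1)
    s
  }))
  ds <- shape_dataset(X, vt$mesh$faces)
  frozen <- seq_len(k %/% 2L - 1L)
  # the frozen region only moves through the rigid re-alignment of the
  # leave-one-out step, so its error is far below the active region's
  G_frozen <- generalisation(ds, 1, region = frozen)
  G_active <- generalisation(ds, 1, region = active)
  expect_lt(G_frozen[[1]], 0.05 * G_active[[1]])
  # all mode energy lives on the active coordinates
  model <- fit_pca(ds)
  expect_gte(compactness(model, 1, region = active) + 1e-12,
             compactness(model, 1))
  w_frozen <- sum(model$modes[1, as.vector(t(outer(frozen, 1:3,
    function(v, c) 3 * (v - 1) + c)))]^2)
  expect_lt(w_frozen, 0.05)
})

test_that("an independent straight-line implementation agrees on a toy set", {
  vt <- small_tree(700, seed = 6)
  # 5-shape toy set with well-separated planted variances, so that the
  # comparison is not limited by eigenvector conditioning
  pl <- plant_shape_modes(vt$mesh, variances = c(1, 0.25), M = 5, seed = 13)
  aligned <- gpa(shape_dataset(pl$shapes, vt$mesh$faces))$dataset
  K <- 2L; H <- 25L; seed <- 99L
  ours_G <- generalisation(aligned, K)
  model <- fit_pca(aligned)
  ours_S <- specificity(aligned, model, K, H = H, seed = seed)
  ours_C <- compactness(model, K)
  ref <- metrics_straightline(aligned$shapes, K, H, seed)
  expect_lt(abs(ours_G[[1]] - ref$G), 1e-10 * max(1, ref$G))
  expect_lt(abs(ours_S - ref$S), 1e-10 * max(1, ref$S))
  expect_lt(abs(ours_C - ref$C), 1e-10)
})
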