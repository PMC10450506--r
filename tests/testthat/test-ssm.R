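test_that("degenerate datasets give zero variance and the mean shape", {
  tb <- generate_tube(40, 6, 150)
  s <- pack_shape(tb$mesh)
  model <- fit_pca(shape_dataset(rbind(s, s, s, s), tb$mesh$faces))
  expect_true(all(model$variances == 0))
  expect_equal(model$mean, s)
  expect_equal(cumulative_variance(model, 1), 1)   # degenerate convention
  expect_error(fit_pca(shape_dataset(rbind(s), tb$mesh$faces)), "at least 2")
})

test_that("two shapes give one mode along their difference", {
  tb <- generate_tube(40, 6, 150)
  s1 <- pack_shape(tb$mesh)
  set.seed(5)
  s2 <- s1 + rnorm(length(s1), 0, 1)
  model <- fit_pca(shape_dataset(rbind(s1, s2), tb$mesh$faces))
  expect_identical(length(model$variances), 1L)
  expect_gt(model$variances[1], 0)
  # variance of two points: |s1 - s2|^2 / 2 with the 1/(M-1) convention
  expect_equal(model$variances[1], sum((s1 - s2)^2) / 2)
  d <- (s1 - s2) / sqrt(sum((s1 - s2)^2))
  expect_equal(abs(sum(model$modes[1, ] * d)), 1, tolerance = 1e-8)
})

test_that("planted orthonormal modes are recovered", {
  vt <- small_tree(1200, seed = 2)
  pl <- plant_shape_modes(vt$mesh, variances = c(9, 4, 1), M = 60, seed = 7)
  model <- fit_pca(shape_dataset(pl$shapes, vt$mesh$faces))
  expect_lt(max(abs(model$variances[1:3] - c(9, 4, 1)) / c(9, 4, 1)), 0.25)
  ang <- principal_angles_deg(model$modes[1:3, ], pl$modes)
  expect_lt(max(ang), 5)
  # training shapes reconstruct exactly with all modes
  for (i in c(1, 30)) {
    rec <- reconstruct_shape(model, pl$shapes[i, ])
    expect_lt(max(abs(rec - pl$shapes[i, ])), 1e-6)
  }
  # mode rows orthonormal
  GG <- model$modes[1:3, ] %*% t(model$modes[1:3, ])
  expect_lt(max(abs(GG - diag(3))), 1e-8)
  # total variance conservation
  X <- pl$shapes
  tot <- sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
  expect_equal(sum(model$variances), tot, tolerance = 1e-8)
})

test_that("cumulative variance is a non-decreasing fraction ending at 1", {
  model <- structure(list(mean = numeric(6), variances = c(3, 1),
                          modes = diag(6)[1:2, ], topology = NULL, M = 3),
                     class = "ssm_model")
  expect_equal(cumulative_variance(model, 1), 0.75)
  expect_equal(cumulative_variance(model, 2), 1)
  vt <- small_tree(800)
  pl <- plant_shape_modes(vt$mesh, variances = c(4, 2, 1), M = 12, seed = 3,
                          noise_sd = 0.05)
  m2 <- fit_pca(shape_dataset(pl$shapes, vt$mesh$faces))
  cv <- cumulative_variance(m2, seq_along(m2$variances))
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1)
})

test_that("generation and projection are mutually consistent", {
  vt <- small_tree(800)
  pl <- plant_shape_modes(vt$mesh, variances = c(4, 1), M = 20, seed = 9)
  model <- fit_pca(shape_dataset(pl$shapes, vt$mesh$faces))
  # omega = 0 gives the mean shape
  expect_equal(pack_shape(generate_shape(model, numeric(0))), model$mean)
  # projecting mean + 2 phi1 returns (2, 0, ...)
  s <- model$mean + 2 * model$modes[1, ]
  om <- project_shape(model, s, K = 4)
  expect_equal(om, c(2, 0, 0, 0), tolerance = 1e-8)
  # extreme-shape construction at +-3 sd stays on the mode axis
  ext <- generate_shape(model, c(3 * sqrt(model$variances[1])))
  expect_equal(project_shape(model, pack_shape(ext), K = 1),
               3 * sqrt(model$variances[1]), tolerance = 1e-8)
  # reconstruction residual is non-increasing in K
  x <- pl$shapes[3, ]
  resid <- sapply(0:4, function(K)
    sqrt(sum((x - reconstruct_shape(model, x, K))^2)))
  expect_true(all(diff(resid) <= 1e-9))
  expect_error(project_shape(model, x[-1]), "dimension")
})

test_that("tidy and glance summarise the model", {
  vt <- small_tree(800)
  pl <- plant_shape_modes(vt$mesh, variances = c(9, 4, 1), M = 30, seed = 1)
  model <- fit_pca(shape_dataset(pl$shapes, vt$mesh$faces))
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), length(model$variances))
  expect_equal(td$cumulative_fraction[nrow(td)], 1)
  gl <- glance(model)
  expect_identical(gl$n_shapes, 30L)
  expect_lte(gl$modes_90pct, gl$modes_99pct)
})

test_that("SSM serialisation round-trips through plain-text files", {
  vt <- small_tree(600)
  pl <- plant_shape_modes(vt$mesh, variances = c(4, 1), M = 8, seed = 2)
  model <- fit_pca(shape_dataset(pl$shapes, vt$mesh$faces))
  stem <- file.path(withr::local_tempdir(), "ssm")
  save_ssm(model, stem)
  m2 <- load_ssm(stem)
  expect_equal(m2$mean, model$mean, tolerance = 1e-8)
  expect_equal(m2$variances, model$variances, tolerance = 1e-10)
  live <- which(model$variances > 1e-10)
  expect_equal(abs(rowSums(m2$modes[live, ] * model$modes[live, ])),
               rep(1, length(live)), tolerance = 1e-8)
})
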