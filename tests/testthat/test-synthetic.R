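test_that("generated trees are valid, labeled and deterministic", {
  vt <- small_tree(1500, seed = 4)
  expect_s3_class(validate_mesh(vt$mesh), "surface_mesh")
  expect_named(vt$mesh$boundary_loops,
               c("root", "descending", "SA1", "SA2", "SA3"))
  expect_length(extract_boundary_loops(vt$mesh), 5L)
  vt2 <- small_tree(1500, seed = 4)
  expect_identical(vt$mesh$vertices, vt2$mesh$vertices)
  expect_identical(vt$mesh$faces, vt2$mesh$faces)
  # per-vertex annotations are consistent
  expect_length(vt$field, n_vertices(vt$mesh))
  expect_setequal(unique(vt$district), c("main", "SA1", "SA2", "SA3"))
})

test_that("cross-section loops have the analytic circumference", {
  r <- 12
  vt <- generate_vessel_tree(vessel_tree_params(n_vertices = 2000, radius = r,
                                                taper = 1, noise_amplitude = 0))
  lp <- vt$mesh$boundary_loops$root
  pts <- vt$mesh$vertices[lp, ]
  circ <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  expect_lt(abs(circ - 2 * pi * r) / (2 * pi * r), 0.02)
})

test_that("the longitudinal field increases along the tube axis", {
  tb <- generate_tube(100, 8, 600)
  expect_true(all(diff(unique(tb$field)) > 0))
  vt <- small_tree(1200)
  # branch coordinates continue from the branch start value
  for (b in 1:3) {
    lab <- paste0("SA", b)
    on_branch <- vt$field[vt$district == lab]
    expect_true(all(on_branch >= vt$branch_C[b] - 1e-9))
  }
})

test_that("overlapping branch stubs are rejected", {
  expect_error(
    generate_vessel_tree(vessel_tree_params(
      n_vertices = 1200, branch_positions = c(0.45, 0.5, 0.75))),
    "overlap")
})

test_that("population generation plants the requested parameter modes", {
  base <- vessel_tree_params(n_vertices = 700, seed = 1)
  modes <- list(list(direction = c(radius = 1), variance = 1.44))
  # zero variance: identical meshes
  pop0 <- generate_population(base,
    list(list(direction = c(radius = 1), variance = 0)), M = 3, seed = 5)
  expect_identical(pop0$trees[[1]]$mesh$vertices,
                   pop0$trees[[3]]$mesh$vertices)
  pop <- generate_population(base, modes, M = 60, seed = 5)
  # shared connectivity (isotopological population)
  expect_identical(pop$trees[[1]]$mesh$faces, pop$trees[[60]]$mesh$faces)
  # sampled coefficient variance near nominal
  expect_lt(abs(var(pop$omega[, 1]) - 1.44) / 1.44, 0.3)
  # the planted radius coefficient is reflected in the surface area
  areas <- vapply(pop$trees, function(t) surface_area(t$mesh), 0)
  expect_gt(cor(areas, pop$omega[, 1]), 0.95)
  # the coefficient table round-trips through a metadata file
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pop$omega, p, row.names = FALSE)
  expect_equal(as.matrix(utils::read.csv(p)), pop$omega,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("clipping a branch shortens it to the requested length", {
  vt <- generate_vessel_tree(vessel_tree_params(
    n_vertices = 1600, seed = 2, branch_lengths = c(25, 25, 25)))
  reg <- which(vt$district == "SA1")
  Cb <- vt$branch_C[1]
  out <- clip_at_length(vt$mesh, vt$field, C = Cb, L = 18,
                        region = reg, label = "SA1")
  expect_length(out$boundary_loops, 5L)
  f2 <- attr(out, "field")
  lp <- out$boundary_loops$SA1
  expect_lt(abs(mean(f2[lp]) - Cb - 18), mean_edge_length(out))
  expect_length(extract_boundary_loops(out), 5L)
  # clipping beyond the branch extent errors
  expect_error(clip_at_length(vt$mesh, vt$field, C = Cb, L = 40,
                              region = reg), "extent")
})

test_that("length normalisation standardises against the raw cohort", {
  raw <- data.frame(vessel = "desc", length = c(10, 20, 30))
  homo <- data.frame(vessel = "desc", length = c(20, 20, 20))
  nl <- normalize_lengths(raw, homo)
  expect_equal(nl$length_norm[nl$dataset == "raw"], c(-1, 0, 1))
  expect_equal(nl$length_norm[nl$dataset == "homo"], c(0, 0, 0))
  # raw lengths standardise to mean 0, sd 1 per vessel
  set.seed(3)
  raw2 <- data.frame(vessel = rep(c("a", "b"), each = 6),
                     length = c(rnorm(6, 100, 9), rnorm(6, 18, 2)))
  nl2 <- normalize_lengths(raw2, raw2)
  for (v in c("a", "b")) {
    x <- nl2$length_norm[nl2$vessel == v & nl2$dataset == "raw"]
    expect_equal(mean(x), 0, tolerance = 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-12)
  }
  expect_error(normalize_lengths(data.frame(vessel = "a", length = c(5, 5)),
                                 homo), "zero standard deviation")
})
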