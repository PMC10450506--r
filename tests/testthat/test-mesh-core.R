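test_that("surface_mesh enforces its invariants", {
  expect_s3_class(single_triangle(), "surface_mesh")
  expect_error(surface_mesh(rbind(c(0, 0, NA)), matrix(integer(0), 0, 3)),
               "non-finite")
  expect_error(surface_mesh(diag(3), matrix(c(1L, 2L, 4L), 1)),
               "out of range")
  expect_error(surface_mesh(diag(3), matrix(c(1L, 2L, 2L), 1)),
               "degenerate")
  # an edge on three faces is non-manifold
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 2L, 5L))
  expect_error(surface_mesh(v, f), "non-manifold")
})

test_that("surface area and mean edge length match hand values", {
  sq <- unit_square_mesh()
  expect_equal(surface_area(sq), 1)
  expect_equal(mean_edge_length(sq), (4 + sqrt(2)) / 5)
  # uniform scaling: area by c^2, edge length by c
  sc <- sq
  sc$vertices <- sc$vertices * 2.5
  expect_equal(surface_area(sc), 2.5^2 * surface_area(sq))
  expect_equal(mean_edge_length(sc), 2.5 * mean_edge_length(sq))
  # refined icosphere area approaches 4*pi
  expect_equal(surface_area(icosphere(3L)), 4 * pi, tolerance = 0.01)
})

test_that("area-proportional vertex budgets scale linearly", {
  expect_identical(scaled_vertex_count(100, 100, 35000), 35000L)
  expect_identical(scaled_vertex_count(100, 100, 20000), 20000L)
  expect_identical(scaled_vertex_count(200, 100, 35000), 70000L)
  expect_identical(scaled_vertex_count(150, 100, 20000), 30000L)
})

test_that("combinatorial Laplacian matches hand-built matrices", {
  L3 <- as.matrix(build_combinatorial_laplacian(single_triangle())$matrix)
  expect_equal(unname(L3),
               rbind(c(2, -1, -1), c(-1, 2, -1), c(-1, -1, 2)))
  L2 <- as.matrix(build_combinatorial_laplacian(rbind(c(1L, 2L)), n = 2)$matrix)
  expect_equal(unname(L2), rbind(c(1, -1), c(-1, 1)))
})

test_that("Laplacian is symmetric, zero-row-sum and PSD on random meshes", {
  for (seed in 1:20) {
    m <- random_small_mesh(seed)
    L <- build_combinatorial_laplacian(m)$matrix
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
    expect_true(Matrix::isSymmetric(L))
    ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    # quadratic form non-negative for random signals
    for (r in 1:5) {
      f <- rnorm(nrow(L))
      expect_gte(dirichlet_energy(L, f), -1e-10)
    }
  }
})

test_that("Dirichlet energy behaves like a smoothness measure", {
  m <- random_small_mesh(42)
  L <- build_combinatorial_laplacian(m)
  k <- n_vertices(m)
  expect_equal(dirichlet_energy(L, rep(3.7, k)), 0, tolerance = 1e-10)
  # energy equals the sum of squared edge differences
  f <- rnorm(k)
  e <- mesh_edges(m)
  expect_equal(dirichlet_energy(L, f), sum((f[e[, 1]] - f[e[, 2]])^2))
  # invariant under adding a constant
  expect_equal(dirichlet_energy(L, f), dirichlet_energy(L, f + 11.3),
               tolerance = 1e-8)
  # the two-vertex single-edge graph: <f, Lf> = (f1 - f2)^2
  L2 <- build_combinatorial_laplacian(rbind(c(1L, 2L)), n = 2)
  expect_equal(dirichlet_energy(L2, c(0, 1)), 1)
  expect_error(dirichlet_energy(L2, c(1, 2, 3)), "match")
})

test_that("isolated vertices get a zero Laplacian row and a warning", {
  m <- surface_mesh(rbind(diag(3), c(5, 5, 5)), matrix(c(1L, 2L, 3L), 1))
  expect_warning(L <- build_combinatorial_laplacian(m), "isolated")
  expect_equal(as.matrix(L$matrix)[4, ], rep(0, 4), ignore_attr = TRUE)
})
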