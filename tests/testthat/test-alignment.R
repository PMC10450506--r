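test_that("ICP recovers a known rigid motion", {
  set.seed(2)
  fixed <- matrix(runif(300, 0, 50), ncol = 3)
  tr_id <- icp_rigid(fixed, fixed)
  expect_lt(max(abs(tr_id$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(tr_id$translation)), 1e-8)
  R0 <- rotation_z(0.35)
  moving <- sweep(fixed %*% t(R0), 2, -c(4, -6, 9))
  tr <- icp_rigid(moving, fixed)
  expect_lt(max(abs(apply_transform(tr, moving) - fixed)), 1e-6)
  expect_gt(det(tr$rotation), 0)   # never a reflection
  # collinear input is rejected
  line <- cbind(1:10, 2 * (1:10), -1:-10 * 0 + 3)
  expect_error(icp_rigid(line, fixed), "collinear")
})

test_that("shape vectors pack coordinates interleaved per vertex", {
  m <- surface_mesh(rbind(c(1, 2, 3), c(4, 5, 6)),
                    matrix(integer(0), 0, 3), validate = FALSE)
  s <- pack_shape(m)
  expect_identical(s, c(1, 2, 3, 4, 5, 6))
  m2 <- unpack_shape(s, m$faces)
  expect_identical(m2$vertices, m$vertices)
  expect_error(unpack_shape(1:4, m$faces), "divisible")
})

test_that("GPA aligns rigidly moved copies of one shape", {
  tb <- generate_tube(60, 8, 300)
  s <- pack_shape(tb$mesh)
  move <- function(s, th, t0) {
    m <- matrix(s, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% t(rotation_z(th)), 2, -t0)))
  }
  X <- rbind(s, move(s, 0.8, c(10, -3, 6)))
  g <- gpa(shape_dataset(X, tb$mesh$faces))
  expect_lt(max(abs(g$dataset$shapes[1, ] - g$dataset$shapes[2, ])), 1e-6)
})

test_that("identical shapes converge in one iteration to themselves", {
  tb <- generate_tube(60, 8, 200)
  s <- pack_shape(tb$mesh)
  g <- gpa(shape_dataset(rbind(s, s, s), tb$mesh$faces))
  expect_identical(g$iterations, 1L)
  expect_lt(max(abs(g$mean - s)), 1e-12)
})

test_that("GPA is invariant to an extra global rigid motion and keeps size", {
  set.seed(4)
  tb <- generate_tube(60, 8, 300)
  s <- pack_shape(tb$mesh)
  jitter <- function(s) s + rnorm(length(s), 0, 0.5)
  move <- function(s, th, t0) {
    m <- matrix(s, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% t(rotation_z(th)), 2, -t0)))
  }
  X <- rbind(jitter(s), jitter(s), jitter(s), jitter(s))
  g1 <- gpa(shape_dataset(X, tb$mesh$faces))
  Xg <- t(apply(X, 1, move, th = 1.1, t0 = c(5, 5, -2)))
  g2 <- gpa(shape_dataset(Xg, tb$mesh$faces))
  d1 <- dist(g1$dataset$shapes)
  d2 <- dist(g2$dataset$shapes)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-6)
  # objective is non-increasing across iterations
  expect_true(all(diff(g1$objective) <= 1e-9))
  # centroid size is preserved by the rigid alignment
  csize <- function(s) {
    m <- matrix(s, ncol = 3, byrow = TRUE)
    sqrt(sum(sweep(m, 2, colMeans(m))^2))
  }
  for (i in 1:4)
    expect_equal(csize(g1$dataset$shapes[i, ]), csize(X[i, ]),
                 tolerance = 1e-9)
})
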