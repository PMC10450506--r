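# Geometric fixtures built in code.

unit_square_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

single_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               matrix(c(1L, 2L, 3L), 1))
}

# regular icosahedron with circumradius 1
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(1 + p^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f)
}

# icosphere: subdivided icosahedron projected to the unit sphere
icosphere <- function(subdiv = 2L) {
  m <- icosahedron()
  for (s in seq_len(subdiv)) {
    v <- m$vertices
    f <- m$faces
    mid_env <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid_env[[key]]
      if (!is.null(got)) return(got)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(NA_integer_, 4L * nrow(f), 3L)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; cc <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * r - 3L, ] <- c(a, ab, ca)
      nf[4L * r - 2L, ] <- c(b, bc, ab)
      nf[4L * r - 1L, ] <- c(cc, ca, bc)
      nf[4L * r, ] <- c(ab, bc, ca)
    }
    m <- surface_mesh(v, nf)
  }
  m
}

# random valid small mesh: jittered short tube
random_small_mesh <- function(seed) {
  set.seed(seed)
  tb <- generate_tube(length = runif(1, 20, 60), radius = runif(1, 3, 8),
                      n_vertices = sample(60:140, 1))
  m <- tb$mesh
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), 0, 0.3),
                                    ncol = 3L)
  m
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

small_tree <- function(n_vertices = 1200L, seed = 2L, ...) {
  generate_vessel_tree(vessel_tree_params(n_vertices = n_vertices,
                                          seed = seed, ...))
}
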