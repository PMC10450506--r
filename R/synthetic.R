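#' Parameters for the synthetic branched-vessel generator
#'
#' Describes an idealised aorta-like geometry: a curved main tube (vertical
#' ascending segment, semicircular arch with a mild out-of-plane component,
#' vertical descending segment) carrying three branch stubs on the arch
#' ("supra-aortic" branches).  The generated surface is open at five
#' labeled boundaries: `root` (start of the ascending segment),
#' `descending` (end of the descending segment) and `SA1`/`SA2`/`SA3`
#' (branch ends).  All lengths in mm.
#'
#' @param ascending_length,descending_length lengths of the straight
#'   segments, mm.
#' @param arch_radius radius of the arch semicircle, mm.
#' @param out_of_plane amplitude of the arch's out-of-plane excursion, mm
#'   (gives the non-planar S morphology of a real aorta).
#' @param radius main-tube radius at the root, mm.
#' @param taper ratio of distal to proximal main-tube radius.
#' @param aneurysm_amplitude relative radial bump amplitude (0 = none).
#' @param aneurysm_position,aneurysm_width centre (as a fraction of total
#'   centerline length) and width (mm) of the radial bump.
#' @param branch_positions arc-length positions of the three branch stubs,
#'   as fractions of the arch segment.
#' @param branch_radii,branch_lengths,branch_tilts per-branch radius (mm),
#'   length (mm) and tilt from the outward radial direction towards the
#'   flow direction (radians).
#' @param n_vertices target vertex count of the mesh.
#' @param noise_amplitude standard deviation (mm) of the smooth radial
#'   surface perturbation; 0 for an exact parametric surface.
#' @param seed integer seed driving the (optional) noise field.
#' @return A list of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(ascending_length = 60,
                               descending_length = 150,
                               arch_radius = 30,
                               out_of_plane = 8,
                               radius = 12,
                               taper = 0.85,
                               aneurysm_amplitude = 0,
                               aneurysm_position = 0.25,
                               aneurysm_width = 25,
                               branch_positions = c(0.25, 0.5, 0.75),
                               branch_radii = c(4.5, 4, 4),
                               branch_lengths = c(22, 22, 22),
                               branch_tilts = c(-0.35, 0, 0.35),
                               n_vertices = 2000L,
                               noise_amplitude = 0,
                               seed = 1L) {
  p <- list(ascending_length = ascending_length,
            descending_length = descending_length,
            arch_radius = arch_radius,
            out_of_plane = out_of_plane,
            radius = radius,
            taper = taper,
            aneurysm_amplitude = aneurysm_amplitude,
            aneurysm_position = aneurysm_position,
            aneurysm_width = aneurysm_width,
            branch_positions = branch_positions,
            branch_radii = branch_radii,
            branch_lengths = branch_lengths,
            branch_tilts = branch_tilts,
            n_vertices = as.integer(n_vertices),
            noise_amplitude = noise_amplitude,
            seed = as.integer(seed))
  stopifnot(p$radius > 0, all(p$branch_radii > 0),
            all(p$branch_positions > 0 & p$branch_positions < 1),
            p$noise_amplitude >= 0)
  class(p) <- "vessel_tree_params"
  p
}

# dense analytic centerline of the main tube; returns points (n x 3) and
# cumulative arc length
main_centerline <- function(p, n_dense = 600L) {
  La <- p$ascending_length; Ld <- p$descending_length; R <- p$arch_radius
  arc <- pi * R
  total <- La + arc + Ld
  s <- seq(0, total, length.out = n_dense)
  pts <- t(vapply(s, function(si) {
    if (si <= La) c(0, 0, si)
    else if (si <= La + arc) {
      phi <- (si - La) / R
      c(R - R * cos(phi), p$out_of_plane * sin(phi)^2, La + R * sin(phi))
    } else c(2 * R, 0, La - (si - La - arc))
  }, numeric(3)))
  arclen <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, arclen = arclen, nominal = s,
       arch_span = c(La, La + arc))
}

radius_profile <- function(p, s, total) {
  r <- p$radius * (1 + (p$taper - 1) * s / total)
  if (p$aneurysm_amplitude > 0) {
    r <- r + p$radius * p$aneurysm_amplitude *
      exp(-((s - p$aneurysm_position * total) / p$aneurysm_width)^2)
  }
  r
}

# parallel-transport frames along a polyline; returns unit tangent, normal,
# binormal per point
transport_frames <- function(pts) {
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ],
              (pts[3:n, ] - pts[1:(n - 2), ]) / 2,
              pts[n, ] - pts[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  nor <- matrix(0, n, 3)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(0, 1, 0)
  nor[1, ] <- ref - sum(ref * tg[1, ]) * tg[1, ]
  nor[1, ] <- nor[1, ] / sqrt(sum(nor[1, ]^2))
  for (i in 2:n) {
    v <- nor[i - 1, ] - sum(nor[i - 1, ] * tg[i, ]) * tg[i, ]
    nor[i, ] <- v / sqrt(sum(v^2))
  }
  bin <- cbind(tg[, 2] * nor[, 3] - tg[, 3] * nor[, 2],
               tg[, 3] * nor[, 1] - tg[, 1] * nor[, 3],
               tg[, 1] * nor[, 2] - tg[, 2] * nor[, 1])
  list(tangent = tg, normal = nor, binormal = bin)
}

# fixed discretisation layout so that populations generated from perturbed
# parameters stay isotopological (identical connectivity)
plan_layout <- function(p) {
  cl <- main_centerline(p)
  total <- max(cl$arclen)
  rbar <- mean(radius_profile(p, cl$arclen, total))
  n_main <- p$n_vertices
  n_c <- max(16L, as.integer(round(sqrt(n_main * 2 * pi * rbar / total))))
  n_s <- max(24L, as.integer(round(n_main / n_c)))
  ds <- total / (n_s - 1)
  patches <- vector("list", 3L)
  for (b in 1:3) {
    s_b <- cl$arch_span[1] +
      p$branch_positions[b] * diff(cl$arch_span)
    i_b <- 1L + as.integer(round(s_b / ds))
    rb <- p$branch_radii[b]
    di <- max(1L, as.integer(round(rb / ds)))
    dj <- max(1L, as.integer(round(rb / (2 * pi * rbar / n_c))))
    n_rings <- max(4L, as.integer(round(p$branch_lengths[b] / ds)))
    patches[[b]] <- list(i0 = i_b - di, i1 = i_b + di, dj = dj,
                         n_rings = n_rings)
  }
  # overlap check (stations, with one cell margin); angular offsets are
  # assigned below around the outward-up direction, shared across branches,
  # so station overlap is the failure mode
  for (b in 1:2)
    if (patches[[b]]$i1 >= patches[[b + 1L]]$i0)
      stop("branch stubs overlap; move branch_positions apart")
  if (patches[[1]]$i0 < 2L || patches[[3]]$i1 > n_s - 1L)
    stop("branch patch outside the arch segment")
  list(n_s = n_s, n_c = n_c, patches = patches)
}

#' Generate a synthetic branched-vessel surface
#'
#' Builds a triangulated aorta-like tree from [vessel_tree_params()]: the
#' main tube is swept along an analytic centerline with parallel-transport
#' frames, three branch stubs are extruded from rectangular patches opened
#' in the arch, and an optional smooth radial noise field perturbs the
#' surface.  The mesh carries five labeled boundary loops, a per-vertex
#' longitudinal coordinate (arc length along the centerline, continued into
#' the branches), a per-vertex district label, and the analytic centerline
#' polylines.
#'
#' @param params a [vessel_tree_params()].
#' @param layout optional precomputed discretisation layout (used by
#'   [generate_population()] to keep connectivity fixed across a
#'   population); computed from `params` when `NULL`.
#' @return A list of class `vessel_tree`: `mesh` ([surface_mesh()] with
#'   labeled loops), `field` (longitudinal coordinate per vertex, mm),
#'   `district` (character per vertex: `"main"`, `"SA1"`, `"SA2"`,
#'   `"SA3"`), `centerline` (named list of polylines), `params`, `layout`.
#' @export
generate_vessel_tree <- function(params, layout = NULL) {
  p <- params
  if (is.null(layout)) layout <- plan_layout(p)
  n_s <- layout$n_s; n_c <- layout$n_c
  cl <- main_centerline(p)
  total <- max(cl$arclen)
  s_st <- seq(0, total, length.out = n_s)
  # resample centerline at the stations
  ix <- findInterval(s_st, cl$arclen, all.inside = TRUE)
  w <- (s_st - cl$arclen[ix]) / pmax(cl$arclen[ix + 1] - cl$arclen[ix], 1e-12)
  cpts <- cl$points[ix, ] * (1 - w) + cl$points[ix + 1, ] * w
  fr <- transport_frames(cpts)
  radii <- radius_profile(p, s_st, total)

  theta <- 2 * pi * (0:(n_c - 1)) / n_c
  vid <- function(i, j) (i - 1L) * n_c + ((j - 1L) %% n_c) + 1L
  verts <- matrix(NA_real_, n_s * n_c, 3L)
  for (i in seq_len(n_s)) {
    dirs <- outer(cos(theta), fr$normal[i, ]) + outer(sin(theta), fr$binormal[i, ])
    verts[vid(i, 1:n_c), ] <- rep(cpts[i, ], each = n_c) + radii[i] * dirs
  }
  field <- rep(s_st, each = n_c)[order(rep(seq_len(n_s), each = n_c))]
  field <- rep(s_st, each = n_c)          # vid(i,j) = row-major by station
  district <- rep("main", n_s * n_c)

  # patch cells removed per branch: angular window centred on outward-up
  patch_cells <- matrix(FALSE, n_s - 1L, n_c)   # cell (i, j)
  branch_info <- vector("list", 3L)
  for (b in 1:3) {
    pc <- layout$patches[[b]]
    i_mid <- (pc$i0 + pc$i1) %/% 2L
    updir <- c(0, 0, 1)
    radial_z <- cos(theta) * fr$normal[i_mid, 3] + sin(theta) * fr$binormal[i_mid, 3]
    j_mid <- which.max(radial_z)
    j0 <- j_mid - pc$dj; j1 <- j_mid + pc$dj
    branch_info[[b]] <- list(i0 = pc$i0, i1 = pc$i1, j0 = j0, j1 = j1,
                             n_rings = pc$n_rings)
    for (i in pc$i0:(pc$i1 - 1L))
      for (j in j0:(j1 - 1L))
        patch_cells[i, ((j - 1L) %% n_c) + 1L] <- TRUE
  }

  faces <- list()
  for (i in seq_len(n_s - 1L)) {
    for (j in seq_len(n_c)) {
      if (patch_cells[i, j]) next
      v00 <- vid(i, j); v01 <- vid(i, j + 1L)
      v10 <- vid(i + 1L, j); v11 <- vid(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(v00, v10, v11)
      faces[[length(faces) + 1L]] <- c(v00, v11, v01)
    }
  }

  loops <- list(root = vid(1L, 1:n_c),
                descending = vid(n_s, n_c:1))
  centerlines <- list(main = cpts)

  # extrude branches from the patch perimeters
  for (b in 1:3) {
    bi <- branch_info[[b]]
    # ordered perimeter cycle of the rectangular hole
    per <- c(vapply(bi$j0:(bi$j1 - 1L), function(j) vid(bi$i0, j), 1L),
             vapply(bi$i0:(bi$i1 - 1L), function(i) vid(i, bi$j1), 1L),
             vapply(bi$j1:(bi$j0 + 1L), function(j) vid(bi$i1, j), 1L),
             vapply(bi$i1:(bi$i0 + 1L), function(i) vid(i, bi$j0), 1L))
    n_p <- length(per)
    center0 <- colMeans(verts[per, , drop = FALSE])
    i_mid <- (bi$i0 + bi$i1) %/% 2L
    radial <- center0 - cpts[i_mid, ]
    radial <- radial / sqrt(sum(radial^2))
    tilt <- p$branch_tilts[b]
    d <- cos(tilt) * radial + sin(tilt) * fr$tangent[i_mid, ]
    d <- d / sqrt(sum(d^2))
    e1 <- verts[per[1L], ] - center0
    e1 <- e1 - sum(e1 * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    rel <- sweep(verts[per, , drop = FALSE], 2L, center0)
    phi <- atan2(rel %*% e2, rel %*% e1)
    rb <- p$branch_radii[b]; Lb <- p$branch_lengths[b]
    n_r <- bi$n_rings
    prev_ring <- per
    C_b <- mean(field[per])
    bc <- matrix(NA_real_, n_r + 1L, 3L); bc[1L, ] <- center0
    for (m in seq_len(n_r)) {
      t_m <- m / n_r
      cm <- center0 + t_m * Lb * d
      bc[m + 1L, ] <- cm
      wm <- min(1, m / 2)
      circ <- rep(cm, each = n_p) +
        rb * (outer(as.vector(cos(phi)), e1) + outer(as.vector(sin(phi)), e2))
      slid <- verts[per, , drop = FALSE] + rep(t_m * Lb * d, each = n_p)
      ring <- (1 - wm) * slid + wm * circ
      base <- nrow(verts)
      verts <- rbind(verts, ring)
      field <- c(field, rep(C_b + t_m * Lb, n_p))
      district <- c(district, rep(paste0("SA", b), n_p))
      new_ring <- base + seq_len(n_p)
      for (kk in seq_len(n_p)) {
        k2 <- if (kk == n_p) 1L else kk + 1L
        faces[[length(faces) + 1L]] <- c(prev_ring[kk], prev_ring[k2], new_ring[k2])
        faces[[length(faces) + 1L]] <- c(prev_ring[kk], new_ring[k2], new_ring[kk])
      }
      prev_ring <- new_ring
    }
    loops[[paste0("SA", b)]] <- prev_ring
    centerlines[[paste0("SA", b)]] <- bc
    branch_info[[b]]$C <- C_b
  }

  faces <- do.call(rbind, faces)

  if (p$noise_amplitude > 0) {
    # smooth random radial field: iid normals relaxed by neighbour averaging
    set.seed(p$seed)
    g <- rnorm(nrow(verts))
    L <- build_combinatorial_laplacian(surface_mesh(verts, faces, validate = FALSE))
    deg <- Matrix::diag(L$matrix)
    for (it in 1:12) g <- g - 0.6 * as.vector(L$matrix %*% g) / pmax(deg, 1)
    g <- g / stats::sd(g)
    # radial direction: away from the nearest centerline station
    near <- nn_index(verts, cpts)
    rad <- verts - cpts[near, , drop = FALSE]
    rad <- rad / pmax(sqrt(rowSums(rad^2)), 1e-9)
    verts <- verts + p$noise_amplitude * g * rad
  }

  # drop grid vertices buried under the branch patches (not in any face)
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  verts <- verts[used, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3L)
  field <- field[used]; district <- district[used]
  loops <- lapply(loops, function(lp) remap[lp])

  mesh <- surface_mesh(verts, faces, boundary_loops = loops)
  found <- extract_boundary_loops(mesh)
  if (length(found) != 5L)
    stop(sprintf("generator produced %d boundary loops instead of 5", length(found)))
  structure(list(mesh = mesh, field = field, district = district,
                 centerline = centerlines, params = p, layout = layout,
                 branch_C = vapply(branch_info, `[[`, 0, "C")),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d vertices, %d faces, 5 open boundaries\n",
              n_vertices(x$mesh), n_faces(x$mesh)))
  invisible(x)
}

#' Generate a simple open tube
#'
#' A straight (or mildly curved) cylinder segment with two open boundary
#' loops, labeled `root` and `descending`.  Convenience fixture for
#' registration and topology tests.
#'
#' @param length,radius tube dimensions, mm.
#' @param n_vertices target vertex count.
#' @param bend lateral sinusoidal bend amplitude, mm.
#' @return A `vessel_tree`-like list with `mesh`, `field`, `centerline`.
#' @export
generate_tube <- function(length = 100, radius = 10, n_vertices = 600L,
                          bend = 0) {
  n_c <- max(12L, as.integer(round(sqrt(n_vertices * 2 * pi * radius / length))))
  n_s <- max(8L, as.integer(round(n_vertices / n_c)))
  s <- seq(0, length, length.out = n_s)
  cpts <- cbind(bend * sin(pi * s / length), 0, s)
  fr <- transport_frames(cpts)
  theta <- 2 * pi * (0:(n_c - 1)) / n_c
  verts <- matrix(NA_real_, n_s * n_c, 3L)
  vid <- function(i, j) (i - 1L) * n_c + ((j - 1L) %% n_c) + 1L
  for (i in seq_len(n_s)) {
    dirs <- outer(cos(theta), fr$normal[i, ]) + outer(sin(theta), fr$binormal[i, ])
    verts[vid(i, 1:n_c), ] <- rep(cpts[i, ], each = n_c) + radius * dirs
  }
  faces <- matrix(NA_integer_, 2L * (n_s - 1L) * n_c, 3L)
  r <- 1L
  for (i in seq_len(n_s - 1L)) for (j in seq_len(n_c)) {
    faces[r, ] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
    faces[r + 1L, ] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
    r <- r + 2L
  }
  mesh <- surface_mesh(verts, faces,
                       boundary_loops = list(root = vid(1L, 1:n_c),
                                             descending = vid(n_s, n_c:1)))
  list(mesh = mesh, field = rep(s, each = n_c), centerline = list(main = cpts))
}

#' Generate a population of isotopological vessel trees
#'
#' Samples `M` parameter vectors `base + sum_i omega_i * direction_i` with
#' `omega_i ~ Normal(0, variance_i)` and generates one mesh per sample on a
#' shared discretisation layout, so all meshes have identical connectivity.
#' Each direction is a named numeric vector of offsets to scalar fields of
#' [vessel_tree_params()] (e.g. `c(radius = 1)` or
#' `c(arch_radius = 1, out_of_plane = 0.5)`).
#'
#' @param base a [vessel_tree_params()].
#' @param modes list of lists `list(direction = <named numeric>, variance =
#'   <scalar>)`.
#' @param M population size.
#' @param seed integer seed for the mode coefficients.
#' @return List with `trees` (list of `vessel_tree`), `omega` (`M x
#'   length(modes)` matrix of sampled coefficients) and `layout`.
#' @export
generate_population <- function(base, modes, M, seed = 1L) {
  stopifnot(M >= 2L)
  layout <- plan_layout(base)
  set.seed(seed)
  omega <- vapply(modes, function(m) rnorm(M, 0, sqrt(m$variance)), numeric(M))
  omega <- matrix(omega, nrow = M)
  trees <- vector("list", M)
  for (i in seq_len(M)) {
    p <- base
    for (j in seq_along(modes)) {
      dir <- modes[[j]]$direction
      for (nm in names(dir)) {
        p[[nm]] <- p[[nm]] + omega[i, j] * dir[[nm]]
      }
    }
    trees[[i]] <- generate_vessel_tree(p, layout = layout)
  }
  list(trees = trees, omega = omega, layout = layout)
}

#' Plant exact low-rank shape variation on one mesh
#'
#' Builds a population of shape vectors `s_i = s_base + sum_j omega_ij *
#' phi_j` from `n_modes` orthonormalised smooth deformation fields of the
#' base mesh, with `omega_j ~ Normal(0, variance_j)`.  Because the planted
#' modes are exactly orthonormal and the population is exactly low-rank
#' (plus optional isotropic noise), PCA recovery of the subspace and of the
#' variances can be checked quantitatively.
#'
#' @param mesh base [surface_mesh()].
#' @param variances planted mode variances, mm^2 (length = number of modes).
#' @param M population size.
#' @param seed integer seed.
#' @param noise_sd isotropic coordinate noise, mm.
#' @return List with `shapes` (`M x 3k` matrix), `modes` (`n_modes x 3k`,
#'   orthonormal rows), `omega` (`M x n_modes`), `base` (3k vector) and
#'   `topology` (face matrix).
#' @export
plant_shape_modes <- function(mesh, variances = c(9, 4, 1), M = 60L,
                              seed = 1L, noise_sd = 0) {
  v <- mesh$vertices
  k <- nrow(v)
  ctr <- sweep(v, 2L, colMeans(v))
  scale_z <- max(abs(ctr[, 3])) %||% 1
  # smooth candidate fields: radial inflation, axial stretch, bend
  rad <- ctr / pmax(sqrt(rowSums(ctr^2)), 1e-9)
  f1 <- rad
  f2 <- cbind(0, 0, ctr[, 3]) / max(abs(ctr[, 3]))
  f3 <- cbind((ctr[, 3] / max(abs(ctr[, 3])))^2, 0 * ctr[, 3], 0)
  cand <- list(f1, f2, f3)
  n_modes <- length(variances)
  modes <- matrix(0, n_modes, 3L * k)
  for (j in seq_len(n_modes)) {
    m <- as.vector(t(cand[[j]]))          # (x1,y1,z1,...) packing
    if (j > 1L) for (l in seq_len(j - 1L)) m <- m - sum(m * modes[l, ]) * modes[l, ]
    modes[j, ] <- m / sqrt(sum(m^2))
  }
  set.seed(seed)
  omega <- vapply(variances, function(s2) rnorm(M, 0, sqrt(s2)), numeric(M))
  omega <- matrix(omega, nrow = M)
  base <- as.vector(t(v))
  shapes <- rep(1, M) %o% base + omega %*% modes
  if (noise_sd > 0) shapes <- shapes + rnorm(length(shapes), 0, noise_sd)
  list(shapes = shapes, modes = modes, omega = omega, base = base,
       topology = mesh$faces)
}

#' Clip a mesh where a longitudinal coordinate exceeds a threshold
#'
#' Removes the part of the surface whose longitudinal coordinate exceeds
#' `C + L` and re-triangulates the cut so that it closes into a single
#' clean boundary loop (new vertices are placed where mesh edges cross the
#' threshold).  `C` is the average longitudinal coordinate at the branch's
#' start contour; `L` is the retained length.  This homogenises branch
#' lengths across a dataset (e.g. 140 mm for the descending aorta and
#' 18 mm for the supra-aortic branches).
#'
#' @param mesh a [surface_mesh()].
#' @param field numeric per-vertex longitudinal coordinate, mm.
#' @param C longitudinal coordinate of the branch start, mm.
#' @param L retained length beyond `C`, mm.
#' @param region optional integer/logical vertex subset in which clipping is
#'   allowed (vertices outside it are never removed).
#' @param label label assigned to the new boundary loop.
#' @return A [surface_mesh()] with updated boundary loops; the updated
#'   longitudinal field is attached as attribute `"field"`.
#' @export
clip_at_length <- function(mesh, field, C, L, region = NULL,
                           label = "clipped") {
  stopifnot(length(field) == n_vertices(mesh))
  thresh <- C + L
  in_region <- rep(TRUE, n_vertices(mesh))
  if (!is.null(region)) {
    in_region <- rep(FALSE, n_vertices(mesh))
    in_region[region] <- TRUE
  }
  if (thresh >= max(field[in_region]))
    stop("clip length beyond the branch extent")
  if (thresh <= min(field[in_region]) && all(in_region))
    stop("clip would remove the whole mesh")
  removed <- field > thresh & in_region

  v <- mesh$vertices; f <- mesh$faces
  new_pts <- list(); new_field <- numeric(0)
  edge_cut <- new.env(parent = emptyenv())
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    got <- edge_cut[[key]]
    if (!is.null(got)) return(got)
    t <- (thresh - field[a]) / (field[b] - field[a])
    t <- min(max(t, 0), 1)
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    new_field[length(new_field) + 1L] <<- thresh
    id <- nrow(v) + length(new_pts)
    edge_cut[[key]] <- id
    id
  }

  out_faces <- list()
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    rm <- removed[tri]
    if (!any(rm)) { out_faces[[length(out_faces) + 1L]] <- tri; next }
    if (all(rm)) next
    if (sum(rm) == 1L) {
      a <- tri[rm]; kept <- tri[!rm]
      # order kept pair (b, c) as they follow a in the face cycle
      ia <- which(rm)
      b <- tri[(ia %% 3L) + 1L]; cc <- tri[((ia + 1L) %% 3L) + 1L]
      pab <- cut_point(a, b); pca <- cut_point(cc, a)
      out_faces[[length(out_faces) + 1L]] <- c(b, cc, pca)
      out_faces[[length(out_faces) + 1L]] <- c(b, pca, pab)
    } else {
      a <- tri[!rm]
      ia <- which(!rm)
      b <- tri[(ia %% 3L) + 1L]; cc <- tri[((ia + 1L) %% 3L) + 1L]
      pab <- cut_point(a, b); pca <- cut_point(cc, a)
      out_faces[[length(out_faces) + 1L]] <- c(a, pab, pca)
    }
  }
  v2 <- rbind(v, do.call(rbind, new_pts))
  field2 <- c(field, new_field)
  f2 <- do.call(rbind, out_faces)
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2)); remap[used] <- seq_along(used)
  out <- surface_mesh(v2[used, , drop = FALSE],
                      matrix(remap[f2], ncol = 3L), validate = FALSE)
  field_out <- field2[used]

  # carry over surviving labeled loops, then attach the cut loop
  loops <- extract_boundary_loops(out)
  labs <- rep(NA_character_, length(loops))
  old <- mesh$boundary_loops
  if (!is.null(old)) {
    for (nm in names(old)) {
      kept_ids <- remap[old[[nm]][!removed[old[[nm]]]]]
      kept_ids <- kept_ids[kept_ids > 0L]
      if (length(kept_ids) < length(old[[nm]])) next   # loop was clipped away
      hit <- which(vapply(loops, function(lp) all(kept_ids %in% lp), TRUE))
      if (length(hit) == 1L) labs[hit] <- nm
    }
  }
  new_ids <- remap[setdiff(seq_len(nrow(v2)), seq_len(nrow(v)))]
  hit <- which(vapply(loops, function(lp) any(new_ids %in% lp), TRUE))
  labs[hit] <- label
  keep <- !is.na(labs)
  out$boundary_loops <- setNames(loops[keep], labs[keep])
  validate_mesh(out)
  attr(out, "field") <- field_out
  out
}

#' Standardise vessel lengths against the raw cohort
#'
#' Normalises per-vessel lengths by the mean and standard deviation of the
#' *raw* cohort: the raw lengths become z-scores, and the homogenised
#' lengths are expressed on the same raw scale (so a perfectly homogenised
#' cohort collapses towards the raw mean, i.e. towards 0).
#'
#' @param raw,homo data frames with columns `vessel` and `length` (mm),
#'   one row per shape and vessel.
#' @return A tibble with columns `vessel`, `dataset` (`"raw"`/`"homo"`),
#'   `length` and `length_norm`.
#' @export
normalize_lengths <- function(raw, homo) {
  stopifnot(all(c("vessel", "length") %in% names(raw)),
            all(c("vessel", "length") %in% names(homo)))
  stats_raw <- do.call(rbind, lapply(split(raw$length, raw$vessel), function(x) {
    if (length(x) < 2L) stop("need at least 2 raw samples per vessel")
    if (sd(x) == 0) stop("zero standard deviation in raw lengths")
    data.frame(mean = mean(x), sd = sd(x))
  }))
  stats_raw$vessel <- rownames(stats_raw)
  norm1 <- function(df, dataset) {
    m <- stats_raw$mean[match(df$vessel, stats_raw$vessel)]
    s <- stats_raw$sd[match(df$vessel, stats_raw$vessel)]
    tibble::tibble(vessel = df$vessel, dataset = dataset,
                   length = df$length, length_norm = (df$length - m) / s)
  }
  rbind(norm1(raw, "raw"), norm1(homo, "homo"))
}
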