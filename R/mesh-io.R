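#' Read and write triangle meshes
#'
#' `load_mesh()` reads PLY (ASCII or binary little-endian), STL (ASCII or
#' binary) and OBJ files into a [surface_mesh()]; `save_mesh()` writes them.
#' Only triangle faces are supported; files with quads or larger polygons
#' are rejected.  STL files carry no shared-vertex information, so vertices
#' are welded at a tolerance of 1e-8 mm on reading.
#'
#' Boundary-loop labels do not fit any of these formats; they live in a
#' sidecar file `<mesh>.boundaries.json` mapping each label to its ordered
#' vertex-index list.  `load_mesh()` picks the sidecar up automatically when
#' present and `save_mesh()` writes one whenever the mesh has labeled loops.
#'
#' @param path file path; the extension (`.ply`, `.stl`, `.obj`) selects the
#'   format unless `format` is given.
#' @param format one of `"ply"`, `"stl"`, `"obj"`.
#' @param sidecar read/write the boundary-label sidecar file?
#' @return `load_mesh()`: a [surface_mesh()]. `save_mesh()`: `path`,
#'   invisibly.
#' @export
load_mesh <- function(path, format = NULL, sidecar = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  mesh <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop("unsupported mesh format: ", format)
  )
  sc <- paste0(path, ".boundaries.json")
  if (sidecar && file.exists(sc)) {
    loops <- jsonlite::fromJSON(sc, simplifyVector = TRUE)
    mesh$boundary_loops <- lapply(loops, as.integer)
  }
  validate_mesh(mesh)
  mesh
}

#' @rdname load_mesh
#' @param mesh a [surface_mesh()].
#' @param binary write binary PLY/STL (default) or ASCII?
#' @export
save_mesh <- function(mesh, path, format = NULL, binary = TRUE, sidecar = TRUE) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    ply = write_ply(mesh, path, binary = binary),
    stl = write_stl(mesh, path, binary = binary),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: ", format)
  )
  if (sidecar && !is.null(mesh$boundary_loops))
    jsonlite::write_json(mesh$boundary_loops,
                         paste0(path, ".boundaries.json"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a

## ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(name,type,list_count_type))
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element")
      elements[[length(elements) + 1L]] <-
        list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    else if (tok[1L] == "property") {
      i <- length(elements)
      p <- if (tok[2L] == "list")
        list(name = tok[5L], type = tok[4L], list_count_type = tok[3L])
      else list(name = tok[3L], type = tok[2L], list_count_type = NULL)
      elements[[i]]$props[[length(elements[[i]]$props) + 1L]] <- p
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header has no format line")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  vertices <- NULL; faces <- NULL
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 1L
    for (el in elements) {
      rows <- txt[seq.int(pos, length.out = el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
        vertices <- m[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (el$name == "face") {
        parts <- strsplit(trimws(rows), "\\s+")
        cnt <- vapply(parts, function(p) as.integer(p[1L]), 0L)
        if (any(cnt != 3L))
          stop("unsupported topology: PLY contains non-triangle faces")
        faces <- do.call(rbind, lapply(parts, function(p) as.integer(p[2:4]))) + 1L
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        vals <- matrix(NA_real_, el$count, length(el$props))
        for (r in seq_len(el$count))
          for (c in seq_along(el$props))
            vals[r, c] <- ply_read_scalar(con, el$props[[c]]$type)
        vertices <- vals[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1L]]
        faces <- matrix(NA_integer_, el$count, 3L)
        for (r in seq_len(el$count)) {
          cnt <- ply_read_scalar(con, p$list_count_type)
          if (cnt != 3L)
            stop("unsupported topology: PLY contains non-triangle faces")
          faces[r, ] <- vapply(1:3, function(i) ply_read_scalar(con, p$type), 0)
        }
        faces <- faces + 1L
      } else {
        # skip unknown element payload
        for (r in seq_len(el$count))
          for (pp in el$props) {
            if (!is.null(pp$list_count_type)) {
              cnt <- ply_read_scalar(con, pp$list_count_type)
              for (i in seq_len(cnt)) ply_read_scalar(con, pp$type)
            } else ply_read_scalar(con, pp$type)
          }
      }
    }
  }
  if (is.null(vertices)) stop("PLY file has no vertex element")
  surface_mesh(vertices, faces %||% matrix(integer(0), 0L, 3L),
               validate = FALSE)
}

write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    if (nrow(f) > 0L) {
      fm <- t(cbind(3L, f - 1L))
      # interleave the uchar count with int32 indices row by row
      for (r in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[r, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else {
    writeLines(apply(v, 1L, function(p) paste(format(p, digits = 17), collapse = " ")), con)
    if (nrow(f) > 0L)
      writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

## ---- STL ----

weld_vertices <- function(tri_coords, tol = 1e-8) {
  key <- apply(round(tri_coords / tol), 1L, paste, collapse = ",")
  idx <- match(key, key[!duplicated(key)])
  vertices <- tri_coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl <- function(path, weld_tol = 1e-8) {
  raw5 <- readBin(path, "raw", 5L)
  is_ascii <- identical(rawToChar(raw5), "solid") && {
    # binary STL may also start with "solid"; check size consistency
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con); on.exit()
    !(is.finite(n) && sz == 84 + 50 * n)
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(t) as.numeric(t[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    coords <- matrix(NA_real_, 3L * n, 3L)
    for (i in seq_len(n)) {
      rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
      coords[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, byrow = TRUE)
      invisible(readBin(con, "raw", 2L))
    }
  }
  if (nrow(coords) %% 3L != 0L) stop("corrupt STL: vertex count not a multiple of 3")
  w <- weld_vertices(coords, weld_tol)
  surface_mesh(w$vertices, w$faces, validate = FALSE)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (r in seq_len(nrow(f))) {
      writeBin(c(nrm[r, ], t(v[f[r, ], ])), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (r in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[r, 1], nrm[r, 2], nrm[r, 3]), con)
      writeLines("    outer loop", con)
      for (i in 1:3) {
        p <- v[f[r, i], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(t) as.numeric(t[2:4])))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    idx <- vapply(t[-1L], function(s) as.integer(strsplit(s, "/")[[1L]][1L]), 0L)
    if (length(idx) != 3L)
      stop("unsupported topology: OBJ contains non-triangle faces")
    idx
  })
  surface_mesh(vertices, do.call(rbind, faces), validate = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0L)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
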