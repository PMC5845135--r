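#' Construct a triangulated surface mesh
#'
#' A `trimesh` is the package's basic container for a triangulated surface:
#' a numeric `V x 3` vertex matrix in millimetres (canonical frame:
#' x mediolateral, y posteroanterior with heel-to-toe positive, z
#' plantodorsal with the plantar surface near `z = 0`) and an integer
#' `F x 3` face matrix of 1-based vertex indices, counter-clockwise when
#' seen from outside (outward normals).
#'
#' @param vertices numeric `V x 3` matrix of vertex coordinates (mm).
#' @param faces integer `F x 3` matrix of 1-based vertex indices.
#' @param validate check invariants (finite coordinates, in-range indices,
#'   no degenerate faces repeating a vertex).
#' @return An object of class `trimesh` with elements `vertices` and `faces`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "trimesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks that coordinates are finite, that face indices are within range,
#' and that no face repeats a vertex.  Called by [trimesh()] and the mesh
#' readers; exported so generated meshes can be re-checked.
#'
#' @param mesh a `trimesh`.
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L || nrow(v) < 1L)
    stop("mesh vertices must be a non-empty V x 3 matrix")
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) stop("mesh faces must be an F x 3 matrix")
    if (anyNA(f) || min(f) < 1L || max(f) > nrow(v))
      stop("face index out of range (must be in 1..", nrow(v), ")")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      stop("degenerate face repeats a vertex")
  }
  invisible(mesh)
}

format_from_path <- function(path, format = "auto") {
  format <- match.arg(tolower(format), c("auto", "obj", "ply", "stl"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply", "stl"))
    stop("cannot infer mesh format from extension '", ext, "'")
  ext
}

#' Read a triangulated mesh from OBJ, PLY, or STL
#'
#' Supports ASCII OBJ, ASCII and binary little-endian PLY (including an
#' optional per-vertex `distance` scalar property), and binary STL.
#' Non-triangular polygon faces are fan-triangulated.  STL reading merges
#' exactly-coincident vertices so shared edges are welded.
#'
#' @param path file to read.
#' @param format `"auto"` (from the extension), `"obj"`, `"ply"`, or `"stl"`.
#' @return A [trimesh()].  If the file carries a per-vertex scalar, it is
#'   attached as attribute `"scalars"` (named list of numeric vectors).
#' @export
read_mesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format_from_path(path, format),
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Write a triangulated mesh to OBJ, PLY, or STL
#'
#' PLY output can carry a per-vertex scalar map (property `distance`),
#' used to export colour-mapped shape-difference fields.  OBJ and ASCII
#' PLY store coordinates with enough digits for 1e-6 mm round-trips;
#' binary PLY stores doubles exactly.  STL is binary and, per the format
#' standard, stores float32 coordinates.
#'
#' @param mesh a [trimesh()].
#' @param path output file.
#' @param format `"auto"`, `"obj"`, `"ply"`, or `"stl"`.
#' @param vertex_scalars optional numeric vector of length `V`, written as
#'   per-vertex property `distance` (PLY only).
#' @param binary for PLY: write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto", vertex_scalars = NULL,
                       binary = TRUE) {
  validate_mesh(mesh)
  if (!is.null(vertex_scalars)) {
    if (length(vertex_scalars) != nrow(mesh$vertices))
      stop("vertex_scalars must have one value per vertex")
    if (!all(is.finite(vertex_scalars)))
      stop("vertex_scalars must be finite")
  }
  format <- format_from_path(path, format)
  if (!is.null(vertex_scalars) && format != "ply")
    stop("per-vertex scalars are only supported for PLY output")
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, vertex_scalars, binary),
         stl = write_stl(mesh, path))
  invisible(path)
}

## ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v[[:space:]]", lines)
  flines <- grep("^f[[:space:]]", lines)
  if (length(vlines) == 0L) stop("OBJ file has no vertices: ", path)
  vv <- strsplit(trimws(sub("^v", "", lines[vlines])), "[[:space:]]+")
  verts <- t(vapply(vv, function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(verts)) {
    bad <- vlines[which(apply(is.na(verts), 1, any))[1]]
    stop("unparseable OBJ vertex at line ", bad)
  }
  faces <- list()
  if (length(flines) > 0L) {
    ff <- strsplit(trimws(sub("^f", "", lines[flines])), "[[:space:]]+")
    faces <- lapply(seq_along(ff), function(i) {
      idx <- suppressWarnings(as.integer(sub("/.*$", "", ff[[i]])))
      if (anyNA(idx) || length(idx) < 3L)
        stop("unparseable OBJ face at line ", flines[i])
      fan_triangulate(idx)
    })
  }
  fmat <- if (length(faces)) do.call(rbind, faces) else
    matrix(integer(0), 0, 3)
  trimesh(verts, fmat)
}

fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n == 3L) return(matrix(idx, 1, 3))
  cbind(idx[1], idx[2:(n - 1)], idx[3:n])
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# exported by footmorph", con)
  writeLines(sprintf("v %.8f %.8f %.8f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
}

## ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  size <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = n, size = size, endian = "little")
  } else if (type %in% c("uint", "uint32", "ushort", "uint16")) {
    # R has no unsigned 4-byte read; mesh indices fit in signed range
    readBin(con, "integer", n = n, size = size, signed = size < 4L,
            endian = "little")
  } else {
    readBin(con, "integer", n = n, size = size,
            signed = !(type %in% c("uchar", "uint8")), endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header: ", path)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
    if (length(hdr) > 200L) stop("PLY header too long / malformed: ", path)
  }
  if (trimws(hdr[1]) != "ply") stop("not a PLY file (missing 'ply'): ", path)
  fmt_line <- grep("^format", hdr, value = TRUE)
  if (length(fmt_line) != 1L) stop("PLY header has no format line: ", path)
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' (big-endian not supported)")
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, ctype = tok[3], vtype = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, vtype = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || elements$vertex$count < 1L)
    stop("PLY file has no vertices: ", path)

  read_element_ascii <- function(el, lines) {
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    list(tokens = toks)
  }

  verts <- NULL
  scalars <- list()
  fmat <- matrix(integer(0), 0, 3)

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    for (el in elements) {
      lines <- body[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(lines), "[[:space:]]+")
      if (el$name == "vertex") {
        pn <- names(el$props)
        vals <- lapply(seq_along(pn), function(j)
          as.numeric(vapply(toks, `[[`, character(1), j)))
        names(vals) <- pn
        verts <- cbind(vals$x, vals$y, vals$z)
        for (nm in setdiff(pn, c("x", "y", "z"))) scalars[[nm]] <- vals[[nm]]
      } else if (el$name == "face") {
        faces <- lapply(seq_along(toks), function(i) {
          tk <- as.integer(toks[[i]])
          n <- tk[1]
          if (is.na(n) || length(tk) < n + 1L)
            stop("unparseable PLY face entry ", i)
          fan_triangulate(tk[2:(n + 1L)] + 1L)
        })
        fmat <- do.call(rbind, faces)
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- names(el$props)
        types <- vapply(el$props, `[[`, character(1), "vtype")
        if (length(unique(types)) == 1L) {
          raw <- ply_read_scalar(con, types[1], n = el$count * length(pn))
          m <- matrix(raw, ncol = length(pn), byrow = TRUE)
        } else {
          m <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count))
            for (j in seq_along(pn))
              m[i, j] <- ply_read_scalar(con, types[j])
        }
        colnames(m) <- pn
        verts <- m[, c("x", "y", "z"), drop = FALSE]
        for (nm in setdiff(pn, c("x", "y", "z"))) scalars[[nm]] <- m[, nm]
      } else if (el$name == "face") {
        pr <- el$props[[1]]
        faces <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          n <- ply_read_scalar(con, pr$ctype)
          idx <- ply_read_scalar(con, pr$vtype, n = n)
          faces[[i]] <- fan_triangulate(idx + 1L)
        }
        fmat <- do.call(rbind, faces)
      } else {
        # skip unknown fixed-size element
        types <- vapply(el$props, `[[`, character(1), "vtype")
        sz <- sum(ply_type_size[types])
        invisible(readBin(con, "raw", n = el$count * sz))
      }
    }
  }
  dimnames(verts) <- NULL
  mesh <- trimesh(verts, fmat)
  if (length(scalars)) attr(mesh, "scalars") <- scalars
  mesh
}

write_ply <- function(mesh, path, vertex_scalars = NULL, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  nf <- nrow(f)
  vtype <- "double"
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment exported by footmorph",
           sprintf("element vertex %d", nv),
           sprintf("property %s x", vtype),
           sprintf("property %s y", vtype),
           sprintf("property %s z", vtype))
  if (!is.null(vertex_scalars))
    hdr <- c(hdr, sprintf("property %s distance", vtype))
  hdr <- c(hdr,
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    vm <- if (is.null(vertex_scalars)) v else cbind(v, vertex_scalars)
    writeBin(as.numeric(t(vm)), con, size = 8L, endian = "little")
    if (nf > 0L) {
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (is.null(vertex_scalars)) {
      writeLines(sprintf("%.8f %.8f %.8f", v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%.8f %.8f %.8f %.8f", v[, 1], v[, 2], v[, 3],
                         vertex_scalars), con)
    }
    if (nf > 0L)
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
  }
}

## ---- STL (binary) ---------------------------------------------------------

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  if (sz < 84L) stop("not a binary STL file (too short): ", path)
  nf <- readBin(con, "integer", size = 4L, endian = "little")
  if (nf < 1L || sz != 84 + 50 * as.numeric(nf))
    stop("not a valid binary STL file (size mismatch): ", path)
  rec <- readBin(con, "raw", n = 50L * nf)
  rec <- matrix(rec, nrow = 50L)
  # bytes 13..48 of each record: 9 float32 vertex coordinates
  coords <- readBin(as.vector(rec[13:48, , drop = FALSE]), "double",
                    n = 9L * nf, size = 4L, endian = "little")
  tri <- matrix(coords, ncol = 3L, byrow = TRUE)  # (3 * nf) x 3
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  fmat <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(verts, fmat)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) < 1L) stop("cannot write STL with no faces")
  n <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "footmorph binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  # assemble all float32 payloads then interleave the attribute shorts
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

## ---- mesh geometry helpers ------------------------------------------------

#' Per-face unit normals
#' @param mesh a [trimesh()].
#' @return `F x 3` matrix of outward unit normals (CCW winding convention).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Per-vertex unit normals (area-weighted average of incident face normals)
#' @param mesh a [trimesh()].
#' @return `V x 3` matrix of unit normals; zero rows for isolated vertices.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # area-weighted (2A n)
  vn <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate2(f[, k], fn[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate2(f[, k], fn[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate2(f[, k], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, group = bin)
  out[as.integer(rownames(s))] <- s
  out
}

#' Signed volume of a closed mesh (divergence theorem)
#' @param mesh a [trimesh()].
#' @return signed volume in mm^3; positive for outward-oriented closed meshes.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Boundary vertices of an open mesh
#'
#' A vertex is a boundary vertex if it lies on an edge used by exactly one
#' face (e.g. the ring created by cropping above the ankle).
#'
#' @param mesh a [trimesh()].
#' @return integer vector of boundary vertex indices (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(integer(0))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_edges <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  sort(unique(as.vector(open_edges)))
}

## ---- preprocessing --------------------------------------------------------

#' Mirror a foot mesh across the sagittal plane
#'
#' Left-foot scans are mirrored into the right-foot coordinate frame before
#' pooled analysis.  The mirror plane is `x = 0` (sagittal); x-coordinates
#' are negated and the face winding is reversed so outward orientation is
#' preserved.
#'
#' @param mesh a [trimesh()].
#' @return the mirrored [trimesh()].
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  trimesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE], validate = FALSE)
}

#' Crop a mesh above a horizontal plane
#'
#' Removes all geometry above `z = z_cut` (used to cut scans just above the
#' ankle).  Faces entirely above the plane are dropped; faces straddling it
#' are clipped so that boundary vertices lie exactly on `z = z_cut`, which
#' avoids the jagged boundary a face-deletion crop would produce.
#'
#' @param mesh a [trimesh()].
#' @param z_cut cutting height (mm).  Values at or above the mesh maximum
#'   leave the mesh unchanged; values at or below the minimum are an error.
#' @return the cropped [trimesh()].
#' @export
crop_above_ankle <- function(mesh, z_cut) {
  v <- mesh$vertices
  f <- mesh$faces
  if (z_cut <= min(v[, 3])) stop("z_cut is at or below the lowest vertex")
  if (z_cut >= max(v[, 3])) return(mesh)
  below <- v[, 3] <= z_cut
  nb <- below[f[, 1]] + below[f[, 2]] + below[f[, 3]]
  keep <- f[nb == 3L, , drop = FALSE]
  straddle <- f[nb == 1L | nb == 2L, , drop = FALSE]

  new_v <- list()      # interpolated boundary vertices, keyed by edge
  edge_id <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- edge_id[[key]]
    if (!is.null(id)) return(id)
    t <- (z_cut - v[i, 3]) / (v[j, 3] - v[i, 3])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p[3] <- z_cut  # exact
    new_v[[length(new_v) + 1L]] <<- p
    id <- nv0 + length(new_v)
    edge_id[[key]] <- id
    id
  }
  clipped <- list()
  for (r in seq_len(nrow(straddle))) {
    tri <- straddle[r, ]
    # walk the triangle, clipping against z <= z_cut (Sutherland-Hodgman)
    poly <- integer(0)
    for (k in 1:3) {
      i <- tri[k]
      j <- tri[if (k == 3L) 1L else k + 1L]
      if (below[i]) poly <- c(poly, i)
      if (below[i] != below[j]) poly <- c(poly, cut_point(i, j))
    }
    if (length(poly) >= 3L)
      clipped[[length(clipped) + 1L]] <- fan_triangulate(poly)
  }
  allv <- rbind(v, do.call(rbind, new_v))
  allf <- rbind(keep, do.call(rbind, clipped))
  if (nrow(allf) == 0L) stop("cropping removed the entire mesh")
  # drop unused vertices, reindex
  used <- sort(unique(as.vector(allf)))
  remap <- integer(nrow(allv))
  remap[used] <- seq_along(used)
  trimesh(allv[used, , drop = FALSE],
          matrix(remap[allf], ncol = 3L))
}

#' Foot length and breadth from the plantar surface
#'
#' Reproduces the standard scan measurement: principal component analysis
#' of the vertices belonging to the plantar surface (all vertices within
#' `plantar_tol` of the lowest z value); foot length is the extent of those
#' vertices along the first principal axis and foot breadth the extent
#' along the second.
#'
#' The measurement is invariant to rigid motions that preserve the vertical
#' axis (rotations about z, translations), since the plantar band itself is
#' defined by height.
#'
#' @param mesh a [trimesh()].
#' @param plantar_tol height tolerance (mm) defining the plantar band;
#'   the default 3 mm matches a typical scanner mesh resolution.
#' @return list with elements `length` and `breadth` (mm).
#' @export
measure_foot <- function(mesh, plantar_tol = 3) {
  v <- mesh$vertices
  sel <- v[, 3] <= min(v[, 3]) + plantar_tol
  if (sum(sel) < 10L)
    stop("fewer than 10 plantar vertices within the tolerance band")
  p <- v[sel, , drop = FALSE]
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  e1 <- diff(range(pc$x[, 1]))
  e2 <- diff(range(pc$x[, 2]))
  list(length = max(e1, e2), breadth = min(e1, e2))
}
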