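# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

small_template <- function() fixture("tmpl600", function()
  build_template_foot(600))

small_modes <- function() fixture("modes600", function()
  define_modes(small_template()))

# Closed, grid-subdivided axis-aligned box with corner at the origin.
# Subdivision puts >= 10 vertices on the bottom face so plantar
# measurements are well defined.
make_box_mesh <- function(lx = 1, ly = 1, lz = 1, n = 4) {
  n <- as.integer(n)
  xs <- seq(0, lx, length.out = n + 1)
  ys <- seq(0, ly, length.out = n + 1)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i   # grid index
  grid_faces <- function(offset, flip = FALSE) {
    out <- list()
    for (j in seq_len(n)) for (i in seq_len(n)) {
      a <- offset + idx(i, j); b <- offset + idx(i + 1L, j)
      c_ <- offset + idx(i + 1L, j + 1L); d <- offset + idx(i, j + 1L)
      out[[length(out) + 1L]] <- if (flip)
        rbind(c(a, c_, b), c(a, d, c_)) else rbind(c(a, b, c_), c(a, c_, d))
    }
    do.call(rbind, out)
  }
  g <- as.matrix(expand.grid(x = xs, y = ys))
  nb <- nrow(g)
  verts <- rbind(cbind(g, 0), cbind(g, lz))
  faces <- rbind(grid_faces(0L, flip = TRUE),      # bottom, outward = -z
                 grid_faces(nb, flip = FALSE))     # top, outward = +z
  # side walls: walk the grid perimeter counter-clockwise (viewed from +z)
  per <- c(vapply(seq_len(n), function(i) idx(i, 1L), 1L),
           vapply(seq_len(n), function(j) idx(n + 1L, j), 1L),
           vapply(seq_len(n), function(i) idx(n + 2L - i, n + 1L), 1L),
           vapply(seq_len(n), function(j) idx(1L, n + 2L - j), 1L))
  for (k in seq_along(per)) {
    a <- per[k]; b <- per[if (k == length(per)) 1L else k + 1L]
    faces <- rbind(faces, c(a, b, nb + b), c(a, nb + b, nb + a))
  }
  trimesh(verts, faces)
}

# random proper rotation matrices (uniform via quaternions)
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), n)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

apply_similarity <- function(coords, R, s = 1, t = c(0, 0, 0)) {
  s * (coords %*% t(R)) + rep(t, each = nrow(coords))
}

edge_table <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}
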