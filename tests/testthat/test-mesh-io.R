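# Mesh I/O, preprocessing, and plantar measurements.

test_that("minimal OBJ parses and malformed inputs error", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  m <- read_mesh(p)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), p)
  expect_error(read_mesh(p), "out of range")

  writeLines(c("# empty"), p)
  expect_error(read_mesh(p), "no vertices")

  expect_error(read_mesh(file.path(tempdir(), "nope.obj")), "not found")
})

test_that("OBJ and PLY round-trips preserve geometry to 1e-6 mm", {
  mesh <- small_template()
  for (spec in list(list(ext = ".obj", args = list()),
                    list(ext = ".ply", args = list(binary = FALSE)),
                    list(ext = ".ply", args = list(binary = TRUE)))) {
    p <- withr::local_tempfile(fileext = spec$ext)
    do.call(write_mesh, c(list(mesh, p), spec$args))
    back <- read_mesh(p)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
    expect_identical(back$faces, mesh$faces)
  }
})

test_that("binary STL round-trip is bit-stable at float32 precision", {
  mesh <- small_template()
  p1 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh, p1)
  r1 <- read_mesh(p1)
  # float32 quantization: ~1.5e-5 relative at 250 mm scale
  expect_lt(max(abs(r1$vertices[r1$faces[, 1], ] -
                    mesh$vertices[mesh$faces[, 1], ])), 300 * 2^-23)
  expect_equal(nrow(r1$faces), nrow(mesh$faces))
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(r1, p2)
  r2 <- read_mesh(p2)
  expect_identical(r2$vertices, r1$vertices)   # second pass is exact
  expect_identical(r2$faces, r1$faces)
})

test_that("PLY carries per-vertex scalar maps through round-trips", {
  mesh <- small_template()
  sc <- seq_len(nrow(mesh$vertices)) / 7
  for (binary in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, p, vertex_scalars = sc, binary = binary)
    back <- read_mesh(p)
    expect_lt(max(abs(attr(back, "scalars")$distance - sc)), 1e-6)
  }
  # all-zero field round-trips to zeros exactly
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, p, vertex_scalars = numeric(nrow(mesh$vertices)))
  expect_identical(attr(read_mesh(p), "scalars")$distance,
                   numeric(nrow(mesh$vertices)))
  expect_error(write_mesh(mesh, p, vertex_scalars = 1:3),
               "one value per vertex")
})

test_that("mirroring reflects across x = 0 and preserves orientation", {
  mesh <- make_box_mesh(2, 3, 1, n = 3)
  mesh$vertices <- mesh$vertices + rep(c(1, 2, 3), each = nrow(mesh$vertices))
  mm <- mirror_mesh(mesh)
  expect_equal(mm$vertices[, 1], -mesh$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], mesh$vertices[, 2:3])
  # involution
  back <- mirror_mesh(mm)
  expect_identical(back$vertices, mesh$vertices)
  expect_identical(back$faces, mesh$faces)
  # signed volume unchanged in magnitude and sign (winding reversal
  # compensates the reflection)
  expect_equal(signed_volume(mm), signed_volume(mesh), tolerance = 1e-12)
  # all pairwise inter-vertex distances preserved
  i <- c(1, 5, 9, 14)
  expect_equal(as.matrix(dist(mm$vertices[i, ])),
               as.matrix(dist(mesh$vertices[i, ])), tolerance = 1e-12)
})

test_that("cropping clips straddling faces exactly at the plane", {
  cube <- make_box_mesh(1, 1, 1, n = 2)
  cropped <- crop_above_ankle(cube, 0.5)
  expect_equal(max(cropped$vertices[, 3]), 0.5)
  expect_gt(length(boundary_vertices(cropped)), 0)
  # brute-force oracle: every original face clipped against z <= 0.5 has
  # its below-plane area preserved in the cropped mesh
  area <- function(mesh) {
    n <- face_normals(mesh)  # unit; recompute raw cross product lengths
    v <- mesh$vertices; f <- mesh$faces
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    sum(sqrt(rowSums((cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                            a[, 3] * b[, 1] - a[, 1] * b[, 3],
                            a[, 1] * b[, 2] - a[, 2] * b[, 1]))^2))) / 2
  }
  # expected: full bottom (1) + half of 4 sides (4 * 0.5) = 3
  expect_equal(area(cropped), 3, tolerance = 1e-12)

  expect_identical(crop_above_ankle(cube, 2), cube)   # above max: unchanged
  expect_error(crop_above_ankle(cube, -0.1), "below")
  expect_error(crop_above_ankle(cube, 0), "below")
})

test_that("cropping the template yields a valid open mesh", {
  tm <- small_template()
  cr <- crop_above_ankle(tm, 60)
  expect_silent(validate_mesh(cr))
  expect_equal(max(cr$vertices[, 3]), 60)
  ring <- boundary_vertices(cr)
  expect_true(all(abs(cr$vertices[ring, 3] - 60) < 1e-9))
})

test_that("plantar measurements match box extents and are motion-stable", {
  box <- make_box_mesh(250, 95, 60, n = 4)
  m <- measure_foot(box)
  expect_equal(m$length, 250, tolerance = 1e-9)
  expect_equal(m$breadth, 95, tolerance = 1e-9)

  # rotation about z (plantar band preserved): identical within 1e-6
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- trimesh(box$vertices %*% t(R), box$faces)
  mr <- measure_foot(rot)
  expect_equal(mr$length, m$length, tolerance = 1e-6)
  expect_equal(mr$breadth, m$breadth, tolerance = 1e-6)

  # homogeneity under uniform scaling
  sc <- trimesh(box$vertices * 2, box$faces)
  ms <- measure_foot(sc)
  expect_equal(ms$length, 2 * m$length, tolerance = 1e-9)
  expect_equal(ms$breadth, 2 * m$breadth, tolerance = 1e-9)

  # mirrored feet measure identically
  tm <- small_template()
  mt <- measure_foot(tm)
  mtm <- measure_foot(mirror_mesh(tm))
  expect_equal(mtm$length, mt$length, tolerance = 1e-9)
  expect_equal(mtm$breadth, mt$breadth, tolerance = 1e-9)

  # too few plantar vertices
  tiny <- trimesh(matrix(rnorm(9), 3), matrix(c(1, 2, 3), 1))
  expect_error(measure_foot(tiny), "plantar")
})
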