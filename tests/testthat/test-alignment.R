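# Generalized Procrustes Analysis.

test_that("centering and unit scaling satisfy their closed forms", {
  expect_equal(center_shape(matrix(c(3, 4, 5), 1)), matrix(0, 1, 3))
  x <- matrix(rnorm(300), 100)
  centered <- center_shape(x)
  expect_equal(colMeans(centered), c(0, 0, 0), tolerance = 1e-14)
  expect_equal(center_shape(centered), centered)

  # two points at (+-1, 0, 0): size sqrt(2), output at +-1/sqrt(2)
  two <- matrix(c(1, -1, 0, 0, 0, 0), 2)
  su <- scale_to_unit(two)
  expect_equal(su$size, sqrt(2))
  expect_equal(su$coords[, 1], c(1, -1) / sqrt(2))
  # idempotent on its own output
  expect_equal(scale_to_unit(su$coords)$coords, su$coords)
  expect_equal(scale_to_unit(su$coords)$size, 1)
  # homogeneity
  expect_equal(scale_to_unit(3.7 * centered)$size,
               3.7 * scale_to_unit(centered)$size)
  expect_error(scale_to_unit(matrix(0, 4, 3)), "zero-size")
})

test_that("optimal rotation solves the orthogonal Procrustes problem", {
  set.seed(1)
  x <- center_shape(matrix(rnorm(30), 10))
  expect_equal(optimal_rotation(x, x), diag(3), tolerance = 1e-12)

  R0 <- random_rotations(1)[[1]]
  expect_equal(optimal_rotation(x, x %*% t(R0)), R0, tolerance = 1e-10)
  expect_equal(det(optimal_rotation(x, x %*% t(R0))), 1, tolerance = 1e-12)

  # brute-force oracle: the analytic optimum beats every sampled rotation
  y4 <- center_shape(matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 3, -1, 1, 0.5), 4,
                            byrow = TRUE))
  t4 <- center_shape(matrix(rnorm(12), 4))
  Ropt <- optimal_rotation(y4, t4)
  obj <- function(R) sum((y4 %*% t(R) - t4)^2)
  sampled <- vapply(random_rotations(50000), obj, 0)
  expect_lte(obj(Ropt), min(sampled))

  # degenerate (collinear) configurations are rejected
  line <- cbind(seq_len(5), 0, 0)
  expect_error(optimal_rotation(center_shape(line), center_shape(line)),
               "degenerate")
})

test_that("identical shapes under random similarity transforms superimpose", {
  set.seed(2)
  base <- small_template()$vertices
  shapes <- t(vapply(seq_len(12), function(i) {
    R <- random_rotations(1)[[1]]
    coords_to_vec(apply_similarity(base, R, s = runif(1, 0.5, 2),
                                   t = runif(3, -50, 50)))
  }, numeric(3 * nrow(base))))
  al <- gpa(shapes)
  rmsd <- max(dist(al$shapes)) / sqrt(nrow(base))
  expect_lt(rmsd, 1e-8)
  # centroid sizes recorded in original units
  expect_equal(length(al$centroid_sizes), 12L)
  expect_true(all(al$centroid_sizes > 0))
})

test_that("aligned shapes are centered, unit size, and GPA is a fixed point", {
  set.seed(3)
  shapes <- matrix(rnorm(20 * 60, sd = 2), 20) +
    rep(coords_to_vec(matrix(rnorm(60), 20)), each = 20)
  al <- gpa(shapes)
  for (i in seq_len(nrow(al$shapes))) {
    m <- vec_to_coords(al$shapes[i, ])
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_lt(abs(sqrt(sum(m^2)) - 1), 1e-9)
  }
  expect_equal(al$mean_shape, colMeans(al$shapes))
  al2 <- gpa(al$shapes)
  expect_lt(max(abs(al2$shapes - al$shapes)), 1e-9)
})

test_that("the GPA objective is non-increasing over iterations", {
  set.seed(4)
  shapes <- matrix(rnorm(20 * 90), 20)
  al <- gpa(shapes)
  expect_true(all(diff(al$objective_trace) <= 1e-12))
})

test_that("GPA is invariant to a common similarity transform of all inputs", {
  set.seed(5)
  shapes <- matrix(rnorm(8 * 45), 8)
  al1 <- gpa(shapes)
  R <- random_rotations(1)[[1]]
  shapes2 <- t(apply(shapes, 1, function(v)
    coords_to_vec(apply_similarity(vec_to_coords(v), R, s = 1.7,
                                   t = c(4, -2, 9)))))
  al2 <- gpa(shapes2)
  # identical up to one global rotation of the whole set
  Rg <- optimal_rotation(vec_to_coords(al2$shapes[1, ]),
                         vec_to_coords(al1$shapes[1, ]))
  for (i in seq_len(8)) {
    expect_lt(max(abs(vec_to_coords(al2$shapes[i, ]) %*% t(Rg) -
                      vec_to_coords(al1$shapes[i, ]))), 1e-8)
  }
  expect_error(gpa(shapes[1, , drop = FALSE]), "at least two")
})
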