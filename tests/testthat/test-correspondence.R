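# Elastic template-to-target registration.
# Small meshes keep these unit tests fast; the full-scale accuracy study
# lives in the acceptance suite.

reg_fixture <- function() fixture("reg600", function() {
  tm <- small_template()
  modes <- small_modes()
  list(template = tm, modes = modes, M = modes_matrix(modes))
})

test_that("registering a mesh to itself is the identity", {
  fx <- reg_fixture()
  cs <- elastic_register(fx$template, fx$template, scan_id = "self")
  expect_lt(cs$residual, 0.01)
  expect_lt(mean(sqrt(rowSums((cs$coords - fx$template$vertices)^2))), 0.1)
  err <- correspondence_error(cs, fx$template$vertices)
  expect_lt(err$mean, 0.1)
})

test_that("affine ICP recovers known similarity transforms", {
  fx <- reg_fixture()
  v <- fx$template$vertices
  th <- 10 * pi / 180
  R0 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  target <- trimesh(apply_similarity(v, R0, t = c(5, 5, 5)),
                    fx$template$faces)
  aff <- affine_align(fx$template, target)
  expect_lt(max(abs(aff$A - R0)), 1e-4)
  expect_lt(max(abs(aff$t - c(5, 5, 5))), 1e-2)

  # pure scaling: polar decomposition of the linear part
  target2 <- trimesh(v * 1.05, fx$template$faces)
  aff2 <- affine_align(fx$template, target2)
  s_rec <- svd(aff2$A)$d
  expect_lt(max(abs(s_rec - 1.05)), 0.01)

  # identity when target equals reference
  aff3 <- affine_align(fx$template, fx$template)
  expect_lt(max(abs(aff3$A - diag(3))), 1e-8)
  expect_lt(max(abs(aff3$t)), 1e-6)
})

test_that("a smooth deformation is recovered below 1 mm mean error", {
  fx <- reg_fixture()
  set.seed(31)
  w <- c(50, -35, 25, 18, -12, 9)
  gt <- fx$template$vertices + matrix(fx$M %*% w, ncol = 3)
  R <- random_rotations(1)[[1]]
  posed <- apply_similarity(gt, R, s = 1.02, t = c(12, -8, 5))
  target <- trimesh(posed, fx$template$faces)
  cs <- suppressWarnings(elastic_register(fx$template, target,
                                          scan_id = "bump"))
  err <- correspondence_error(cs, posed)
  expect_lt(err$mean, 1)
  # output vertex count and ordering match the template
  expect_equal(dim(cs$coords), dim(fx$template$vertices))
})

test_that("stage residuals are non-increasing along the beta schedule", {
  fx <- reg_fixture()
  set.seed(32)
  w <- c(40, -30, 20, 15, -10, 8)
  target <- trimesh(fx$template$vertices + matrix(fx$M %*% w, ncol = 3),
                    fx$template$faces)
  cs <- suppressWarnings(elastic_register(fx$template, target,
                                          scan_id = "mono"))
  expect_true(all(diff(cs$stage_residuals) <= 1e-6))
})

test_that("registration is equivariant under rigid motion of the target", {
  fx <- reg_fixture()
  set.seed(33)
  w <- c(30, -20, 15, 10, -8, 6)
  base <- fx$template$vertices + matrix(fx$M %*% w, ncol = 3)
  target <- trimesh(base, fx$template$faces)
  cs1 <- suppressWarnings(elastic_register(fx$template, target,
                                           scan_id = "a"))
  R <- random_rotations(1)[[1]]
  t <- c(7, -4, 3)
  target2 <- trimesh(apply_similarity(base, R, t = t), fx$template$faces)
  cs2 <- suppressWarnings(elastic_register(fx$template, target2,
                                           scan_id = "b"))
  unrot <- (cs2$coords - rep(t, each = nrow(cs2$coords))) %*% R
  expect_lt(mean(sqrt(rowSums((unrot - cs1$coords)^2))), 0.1)
})

test_that("correspondence errors are plain per-vertex distances", {
  est <- matrix(rnorm(60), 20)
  expect_equal(correspondence_error(est, est)$distances, rep(0, 20))
  off <- est
  off[, 1] <- off[, 1] + 1
  ce <- correspondence_error(est, off)
  expect_equal(ce$distances, rep(1, 20))
  expect_equal(ce$mean, 1)
  u <- matrix(rnorm(60), 20)
  u <- u / sqrt(rowSums(u^2))
  expect_equal(correspondence_error(est, est + u)$mean, 1,
               tolerance = 1e-12)
  expect_error(correspondence_error(est, matrix(0, 5, 3)), "mismatch")
})

test_that("degenerate and incompatible inputs are rejected", {
  fx <- reg_fixture()
  tiny <- trimesh(matrix(rnorm(30), 10),
                  cbind(1:8, 2:9, c(3:10)))
  expect_error(elastic_register(fx$template, tiny), "degenerate")
  expect_error(registration_params(beta_schedule = numeric(0)), "non-empty")
  expect_error(registration_params(beta_schedule = c(3, 1)), "increasing")
})
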