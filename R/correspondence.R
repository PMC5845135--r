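## Dense shape correspondence by elastic template-to-target registration.
##
## A reference (template) mesh is deformed onto each target so that all
## scans share the template's vertex count and ordering, with vertices at
## matching anatomical positions.  The deformation X = T(reference) + d is
## solved by alternating two subproblems: an affine transform T fitted by
## iterative closest points, and a per-vertex elastic displacement d fitted
## under a graph-Laplacian smoothness penalty whose weight is 1/beta.  The
## elasticity beta is increased over a schedule of stages, gradually
## allowing more deformation as the alignment improves.

#' Registration parameters
#'
#' @param beta_schedule increasing elasticity values, one per stage; larger
#'   beta permits more non-rigid deformation (the smoothness penalty weight
#'   is `1/beta`).
#' @param outer_iters_max maximum correspondence/solve iterations per stage.
#' @param inner_tol convergence threshold (mm) on the maximum vertex motion
#'   within a stage.
#' @param nn_distance_cap matches farther than this (mm) are rejected.
#' @param normal_angle_cap matches whose surface normals disagree by more
#'   than this angle (degrees) are rejected.
#' @return object of class `registration_params`.
#' @export
registration_params <- function(beta_schedule = c(0.1, 0.3, 1, 3, 10),
                                outer_iters_max = 12,
                                inner_tol = 0.05,
                                nn_distance_cap = 15,
                                normal_angle_cap = 60) {
  if (length(beta_schedule) < 1) stop("beta_schedule must be non-empty")
  if (any(diff(beta_schedule) <= 0))
    stop("beta_schedule must be increasing (more deformation per stage)")
  structure(list(beta_schedule = beta_schedule,
                 outer_iters_max = as.integer(outer_iters_max),
                 inner_tol = inner_tol,
                 nn_distance_cap = nn_distance_cap,
                 normal_angle_cap = normal_angle_cap),
            class = "registration_params")
}

# sparse combinatorial graph Laplacian of the mesh's edge graph
mesh_laplacian <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  V <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(V, V))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

match_points <- function(X, Xn, target, tn, mask, params) {
  .nn_match_cpp(X, Xn, target$vertices, tn, mask,
                params$nn_distance_cap,
                cos(params$normal_angle_cap * pi / 180))
}

# Symmetric correspondence constraints: forward (template vertex -> nearest
# target vertex) plus reverse (target vertex -> nearest template vertex).
# The reverse matches keep uncovered target regions pulling on the
# template, which prevents tangential sliding along the foot axis.
# Returns per-template-vertex constraint weight and weighted target sum.
symmetric_constraints <- function(X, Xn, target, tn, mask, params) {
  fwd <- match_points(X, Xn, target, tn, mask, params)
  mincos <- cos(params$normal_angle_cap * pi / 180)
  rev <- .nn_match_cpp(target$vertices, tn, X, Xn,
                       rep(TRUE, nrow(X)), params$nn_distance_cap, mincos)
  w <- numeric(nrow(X))
  rhs <- matrix(0, nrow(X), 3)
  ok <- fwd$index > 0L
  w[ok] <- 1
  rhs[ok, ] <- target$vertices[fwd$index[ok], , drop = FALSE]
  rok <- rev$index > 0L & mask
  if (any(rok)) {
    ridx <- rev$index[rok]
    w <- w + tabulate2(ridx, rep(1, length(ridx)), nrow(X))
    for (k in 1:3)
      rhs[, k] <- rhs[, k] +
        tabulate2(ridx, target$vertices[rok, k], nrow(X))
  }
  list(w = w, rhs = rhs, n_ok = sum(ok))
}

# principal-axes frame of a vertex cloud, signs fixed by the third moment
# of the projections (feet are skew along every axis), right-handed
pca_frame <- function(v) {
  c0 <- colMeans(v)
  vc <- sweep(v, 2, c0)
  E <- eigen(cov(vc), symmetric = TRUE)$vectors
  for (k in 1:3) {
    m3 <- sum((vc %*% E[, k])^3)
    if (m3 < 0) E[, k] <- -E[, k]
  }
  if (det(E) < 0) E[, 3] <- -E[, 3]
  list(centre = c0, axes = E)
}

# weighted similarity fit (rotation + uniform scale + translation)
# minimizing sum w_i |s R x_i + t - c_i|^2 (Umeyama's closed form)
fit_similarity <- function(X, C, w) {
  W <- sum(w)
  xb <- colSums(X * w) / W
  cb <- colSums(C * w) / W
  Xc <- sweep(X, 2, xb)
  Cc <- sweep(C, 2, cb)
  S <- crossprod(Cc * w, Xc) / W
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(w * rowSums(Xc^2)) / W
  s <- sum(sv$d * diag(D)) / varx
  list(A = s * R, t = cb - s * as.vector(R %*% xb))
}

#' Affine alignment of a reference mesh to a target (affine ICP)
#'
#' Iteratively matches each reference vertex to its nearest compatible
#' target vertex and solves the least-squares affine transform (3x3 linear
#' part plus translation) minimizing the summed squared distances to the
#' matches, until the mean residual stabilizes.
#'
#' @param reference,target [trimesh()] objects.
#' @param params a [registration_params()]; only the matching caps are
#'   used.
#' @param max_iters maximum ICP iterations.
#' @return list with `A` (3x3), `t` (length 3), `residual` (mean match
#'   distance, mm).
#' @export
affine_align <- function(reference, target, params = registration_params(),
                         max_iters = 50) {
  X0 <- reference$vertices
  tn <- vertex_normals(target)
  mask <- rep(TRUE, nrow(target$vertices))
  mask[boundary_vertices(target)] <- FALSE
  # initialize by aligning principal-axes frames (robust to large initial
  # rotations, which stall plain ICP in a wrong-assignment fixed point);
  # the third-moment sign disambiguation can flip under strong shape
  # differences, so all four proper sign combinations are scored by a
  # short uncapped similarity ICP and the best is kept
  fr_ref <- pca_frame(X0)
  fr_tgt <- pca_frame(target$vertices)
  Xh <- cbind(X0, 1)
  nocap <- registration_params(beta_schedule = params$beta_schedule,
                               nn_distance_cap = -1,
                               normal_angle_cap = 180)
  coarse_step <- function(A, tr, iters) {
    res <- Inf
    for (it in seq_len(iters)) {
      X <- X0 %*% t(A) + rep(tr, each = nrow(X0))
      Xn <- vertex_normals(trimesh(X, reference$faces, validate = FALSE))
      sc <- symmetric_constraints(X, Xn, target, tn, mask, nocap)
      use <- sc$w > 0
      C <- sc$rhs[use, , drop = FALSE] / sc$w[use]
      fit <- fit_similarity(X0[use, , drop = FALSE], C, sc$w[use])
      A <- fit$A
      tr <- fit$t
      Xnew <- X0 %*% t(A) + rep(tr, each = nrow(X0))
      res <- mean(sqrt(rowSums((Xnew[use, ] - C)^2)))
    }
    list(A = A, t = tr, res = res)
  }
  best <- NULL
  for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    A0 <- fr_tgt$axes %*% diag(s) %*% t(fr_ref$axes)
    t0 <- fr_tgt$centre - as.vector(A0 %*% fr_ref$centre)
    cand <- coarse_step(A0, t0, iters = 3)
    if (is.null(best) || cand$res < best$res) best <- cand
  }
  A <- best$A
  tr <- best$t
  # coarse phase without caps (robust to the initial pose offset), then a
  # refinement phase with the configured caps
  uncapped <- registration_params(beta_schedule = params$beta_schedule,
                                  nn_distance_cap = -1,
                                  normal_angle_cap = 180)
  # phase 1: similarity-constrained ICP without caps (robust to the
  # initial pose); phase 2: full affine with the configured caps
  for (phase in c("similarity", "affine")) {
    pp <- if (phase == "similarity") uncapped else params
    prev <- Inf
    for (it in seq_len(max_iters)) {
      X <- X0 %*% t(A) + rep(tr, each = nrow(X0))
      Xn <- vertex_normals(trimesh(X, reference$faces, validate = FALSE))
      sc <- symmetric_constraints(X, Xn, target, tn, mask, pp)
      if (sc$n_ok < 4L)
        stop("no mutually compatible point pairs within the matching caps")
      use <- sc$w > 0
      C <- sc$rhs[use, , drop = FALSE] / sc$w[use]
      if (phase == "similarity") {
        fit <- fit_similarity(X0[use, , drop = FALSE], C, sc$w[use])
        A <- fit$A
        tr <- fit$t
      } else {
        # weighted LS on the constraint centroids c_i = rhs_i / w_i
        Xw <- Xh[use, , drop = FALSE] * sc$w[use]
        beta_hat <- solve(crossprod(Xh[use, , drop = FALSE], Xw),
                          crossprod(Xw, C))
        A <- t(beta_hat[1:3, ])
        tr <- beta_hat[4, ]
      }
      Xnew <- X0 %*% t(A) + rep(tr, each = nrow(X0))
      res <- mean(sqrt(rowSums((Xnew[use, ] - C)^2)))
      if (is.finite(prev) && abs(prev - res) < 1e-8 * max(prev, 1e-12)) break
      prev <- res
    }
  }
  list(A = A, t = tr, residual = prev)
}

#' Elastic registration of the template to a target mesh
#'
#' Alternates, per elasticity stage, an affine solve (deformation fixed)
#' and an elastic solve (affine fixed).  The elastic solve moves each
#' template vertex toward its matched target point under a graph-Laplacian
#' smoothness penalty weighted by `1/beta`; unmatched vertices (all
#' candidates rejected by the caps) take the smoothness-interpolated
#' position.  Target boundary vertices (the crop ring) are excluded as
#' match candidates.  A stage terminates when the maximum vertex motion
#' falls below `inner_tol` or after `outer_iters_max` iterations.
#'
#' @param reference the study template [trimesh()].
#' @param target a target scan [trimesh()].
#' @param params a [registration_params()].
#' @param scan_id identifier stored with the result.
#' @return object of class `corresponded_shape`: list with `coords`
#'   (`V x 3`, template ordering, on the target surface), `scan_id`,
#'   `residual` (mean distance to the target surface, mm),
#'   `p95_residual`, `converged`, and `stage_residuals`.
#' @export
elastic_register <- function(reference, target,
                             params = registration_params(),
                             scan_id = "scan") {
  if (nrow(target$vertices) < 50)
    stop("degenerate target (fewer than 50 vertices)")
  aff <- affine_align(reference, target, params)
  X0 <- reference$vertices
  Xaff <- X0 %*% t(aff$A) + rep(aff$t, each = nrow(X0))
  V <- nrow(X0)
  L <- Matrix::forceSymmetric(mesh_laplacian(reference))
  chol_cache <- NULL
  tn <- vertex_normals(target)
  mask <- rep(TRUE, nrow(target$vertices))
  mask[boundary_vertices(target)] <- FALSE

  A <- aff$A
  tr <- aff$t
  d <- matrix(0, V, 3)
  converged <- TRUE
  stage_res <- numeric(0)
  for (beta in params$beta_schedule) {
    alpha <- 1 / beta
    stage_done <- FALSE
    for (it in seq_len(params$outer_iters_max)) {
      Xaff <- X0 %*% t(A) + rep(tr, each = V)
      X <- Xaff + d
      Xn <- vertex_normals(trimesh(X, reference$faces, validate = FALSE))
      sc <- symmetric_constraints(X, Xn, target, tn, mask, params)
      if (sc$n_ok < 4L)
        stop("no mutually compatible point pairs within the matching caps")
      use <- sc$w > 0
      cons <- sc$rhs
      cons[use, ] <- cons[use, , drop = FALSE] / sc$w[use]

      # affine step: fit A, t to the constraint centroids, d held fixed
      Xh <- cbind(X0[use, , drop = FALSE], 1)
      Xw <- Xh * sc$w[use]
      bh <- solve(crossprod(Xh, Xw),
                  crossprod(Xw, cons[use, , drop = FALSE] -
                                  d[use, , drop = FALSE]))
      A <- t(bh[1:3, ])
      tr <- bh[4, ]
      Xaff <- X0 %*% t(A) + rep(tr, each = V)

      # elastic step: (W + alpha L) d = W (c - Xaff), W = diag(weights);
      # the sparsity pattern is fixed, so the symbolic Cholesky
      # factorization is computed once and updated numerically
      S <- Matrix::forceSymmetric(Matrix::Diagonal(x = sc$w) + alpha * L)
      chol_cache <- if (is.null(chol_cache)) Matrix::Cholesky(S) else
        Matrix::update(chol_cache, S)
      rhs <- (cons - Xaff) * sc$w
      d_new <- as.matrix(Matrix::solve(chol_cache, rhs))
      motion <- max(sqrt(rowSums((Xaff + d_new - X)^2)))
      d <- d_new
      if (motion < params$inner_tol) {
        stage_done <- TRUE
        break
      }
    }
    if (!stage_done) converged <- FALSE
    Xcur <- Xaff + d
    stage_res <- c(stage_res,
                   mean(.closest_point_cpp(Xcur, target$vertices,
                                           target$faces)$dist))
  }
  coords <- Xaff + d
  dist <- .closest_point_cpp(coords, target$vertices, target$faces)$dist
  if (!converged)
    warning("elastic registration did not fully converge for ", scan_id,
            "; returning best result")
  structure(list(coords = coords, scan_id = scan_id,
                 residual = mean(dist),
                 p95_residual = as.numeric(quantile(dist, 0.95)),
                 converged = converged,
                 stage_residuals = stage_res),
            class = "corresponded_shape")
}

#' @export
print.corresponded_shape <- function(x, ...) {
  cat(sprintf(
    "corresponded_shape '%s': %d vertices, residual %.3f mm (p95 %.3f)%s\n",
    x$scan_id, nrow(x$coords), x$residual, x$p95_residual,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Per-vertex correspondence error against a ground-truth map
#'
#' @param estimate a `corresponded_shape` (or `V x 3` coordinate matrix).
#' @param truth_map `V x 3` matrix of true template-vertex positions (e.g.
#'   from [scan_truth_map()]).
#' @return list with `distances` (V), `mean`, and `p95` (mm).
#' @export
correspondence_error <- function(estimate, truth_map) {
  est <- if (inherits(estimate, "corresponded_shape")) estimate$coords else
    as.matrix(estimate)
  truth_map <- as.matrix(truth_map)
  if (!all(dim(est) == dim(truth_map)))
    stop("vertex count mismatch between estimate and truth map")
  d <- sqrt(rowSums((est - truth_map)^2))
  list(distances = d, mean = mean(d), p95 = as.numeric(quantile(d, 0.95)))
}
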