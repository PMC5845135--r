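## Procedural template foot and its deformation modes.
##
## The template is a closed, outward-oriented surface built from a foot-like
## plantar outline (heel, waisted midfoot, ball, five toe lobes) extruded
## into a dorsal height field with an arch concavity underneath and a
## flat-capped ankle stub.  It is fully procedural so that every vertex has
## a known anatomical meaning, which gives downstream stages exact ground
## truth to validate against.

# Plantar outline control points (x, y) in mm, right foot, hallux on the
# medial (negative x) side.  Radii are interpolated periodically around the
# outline centre.
foot_outline_points <- function() {
  rbind(
    c(0, -2),     # heel, posterior apex
    c(22, 2), c(-22, 2),      # heel shoulders
    c(33, 18), c(-33, 18),    # heel sides
    c(42, 80),                # lateral midfoot
    c(-34, 85),               # medial waist (arch side)
    c(-39, 112),              # medial midfoot
    c(45, 112),               # lateral midfoot (forward)
    c(46, 140), c(-44, 140),  # forefoot sides
    c(47, 170), c(-46, 172),  # ball
    c(36, 212), c(29, 206),   # little toe tip, 4|5 groove
    c(23, 227), c(15, 219),   # 4th toe tip, 3|4 groove
    c(8, 237),  c(0, 228),    # 3rd toe tip, 2|3 groove
    c(-9, 244), c(-19, 233),  # 2nd toe tip, 1|2 groove
    c(-30, 248),              # hallux tip
    c(-40, 225)               # hallux medial side
  )
}

foot_outline_fun <- function() {
  ctr <- c(0, 115)
  pts <- foot_outline_points()
  rel <- sweep(pts, 2, ctr)
  phi <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  r <- sqrt(rowSums(rel^2))
  o <- order(phi)
  phi <- phi[o]
  r <- r[o]
  sf <- stats::splinefun(c(phi, phi[1] + 2 * pi), c(r, r[1]),
                         method = "periodic")
  list(centre = ctr, radius = function(a) sf(a %% (2 * pi)))
}

foot_dome_fun <- function() {
  stats::splinefun(c(-10, 20, 55, 90, 120, 160, 200, 235, 255),
                   c(16, 40, 46, 44, 40, 31, 21, 11, 4),
                   method = "natural")
}

#' Build the procedural template foot mesh
#'
#' Constructs a closed, consistently outward-oriented triangulated surface
#' resembling a right foot: an elongated body with heel bulge, waisted
#' midfoot with a medial arch concavity on the plantar side, five toe
#' lobes, and an ankle stub truncated by a flat cap.  Overall length is
#' about 250 mm in the canonical frame (x mediolateral, y posteroanterior
#' with heel at y ~ 0, z plantodorsal with the plantar surface near z = 0).
#' Output is deterministic for a fixed `resolution`.
#'
#' @param resolution target vertex count (within about 10%); at least 200
#'   so the toe lobes can be resolved.
#' @return a [trimesh()] with approximately `resolution` vertices.
#' @export
build_template_foot <- function(resolution = 2500) {
  if (resolution < 200) stop("resolution too small to realize toe lobes ",
                             "(need at least 200 vertices)")
  nr <- max(6L, round(sqrt(resolution) / 2))
  nv <- max(12L, round((resolution - 2) / (2 * nr - 1)))
  outline <- foot_outline_fun()
  dome <- foot_dome_fun()
  ctr <- outline$centre

  phi <- 2 * pi * (seq_len(nv) - 1) / nv
  rho <- seq_len(nr) / nr
  rb <- outline$radius(phi)   # boundary radius per angle

  ring_xy <- function(p) cbind(ctr[1] + p * rb * cos(phi),
                               ctr[2] + p * rb * sin(phi))
  arch_z <- function(x, y, p) {
    9 * exp(-0.5 * ((x + 14) / 20)^2 - 0.5 * ((y - 95) / 42)^2) * (1 - p^2)
  }
  bottom_z <- function(x, y, p) 0.6 * (1 - p^2) + p^8 + arch_z(x, y, p)
  top_z <- function(x, y, p) {
    z <- 1 + (dome(y) - 1) * pmax(0, 1 - p^2.8)^0.7
    d <- sqrt((x / 1.1)^2 + (y - 80)^2)            # ankle stub footprint
    cap <- 86 * pmin(1, pmax(0, (36 - d) / 16))^2  # flat for d <= 20
    pmax(z, cap)
  }

  nvert <- 2L + (2L * nr - 1L) * nv
  verts <- matrix(0, nvert, 3)
  verts[1, ] <- c(ctr, bottom_z(ctr[1], ctr[2], 0))            # bottom pole
  bot <- function(j) 1L + (j - 1L) * nv + seq_len(nv)          # ring indices
  top <- function(j) {                                         # j in 1..nr
    if (j == nr) return(bot(nr))                               # shared ring
    1L + nr * nv + (nr - 1L - j) * nv + seq_len(nv)
  }
  for (j in seq_len(nr)) {
    xy <- ring_xy(rho[j])
    verts[bot(j), ] <- cbind(xy, if (j == nr) 1 else
      bottom_z(xy[, 1], xy[, 2], rho[j]))
  }
  for (j in seq_len(nr - 1L)) {
    xy <- ring_xy(rho[j])
    verts[top(j), ] <- cbind(xy, top_z(xy[, 1], xy[, 2], rho[j]))
  }
  verts[nvert, ] <- c(ctr, top_z(ctr[1], ctr[2], 0))           # top pole

  nxt <- c(seq_len(nv)[-1], 1L)
  quads <- function(inner, outer, up) {
    # two triangles per quad; `up` = TRUE gives CCW-in-xy (outward for the
    # top surface), FALSE the reverse (outward for the plantar surface)
    if (up) rbind(cbind(inner, outer, outer[nxt]),
                  cbind(inner, outer[nxt], inner[nxt]))
    else    rbind(cbind(inner, inner[nxt], outer[nxt]),
                  cbind(inner, outer[nxt], outer))
  }
  faces <- list()
  r1 <- bot(1L)
  faces[[1]] <- cbind(1L, r1[nxt], r1)                         # bottom fan
  for (j in seq_len(nr - 1L))
    faces[[length(faces) + 1L]] <- quads(bot(j), bot(j + 1L), up = FALSE)
  for (j in seq_len(nr - 1L))
    faces[[length(faces) + 1L]] <- quads(top(j), top(j + 1L), up = TRUE)
  t1 <- top(1L)
  faces[[length(faces) + 1L]] <- cbind(nvert, t1, t1[nxt])     # top fan
  trimesh(verts, do.call(rbind, faces))
}

## ---- deformation modes ----------------------------------------------------

gaussw <- function(t, m, s) exp(-0.5 * ((t - m) / s)^2)

# Raw (pre-orthogonalization) displacement fields, each V x 3.  The fields
# mimic the principal anatomical axes of variation of healthy feet: arch
# height, ball width + toe spread, global width, hallux orientation, toe
# length type (hallux vs second toe), midfoot width.
raw_mode_fields <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  z <- vertices[, 3]
  zero <- numeric(length(x))
  f <- list()
  # 1: arch flattening (positive weight lowers the medial arch) with a
  #    slight posterior heel/Achilles protrusion
  f[[1]] <- cbind(zero,
                  -0.3 * gaussw(y, 6, 15) * gaussw(z, 28, 14),
                  -(gaussw(x, -14, 20) * gaussw(y, 95, 45) *
                      exp(-pmax(z, 0) / 18)))
  # 2: ball width and toe spread
  f[[2]] <- cbind((x / 47) * (gaussw(y, 170, 22) + 1.2 * gaussw(y, 225, 22)),
                  zero, zero)
  # 3: global foot width (including ankle)
  f[[3]] <- cbind(x / 47, zero, zero)
  # 4: hallux orientation (valgus-varus), a rotation of the hallux lobe
  #    about a vertical axis at the ball
  h4 <- gaussw(x, -32, 11) * stats::plogis((y - 205) / 8)
  f[[4]] <- cbind(h4 * (y - 205) / 40, -h4 * (x + 32) / 40, zero)
  # 5: relative hallux vs second-toe length (Egyptian vs Greek foot)
  f[[5]] <- cbind(zero,
                  gaussw(x, -32, 10) * stats::plogis((y - 210) / 8) -
                    gaussw(x, -9, 8) * stats::plogis((y - 210) / 8),
                  zero)
  # 6: midfoot width
  f[[6]] <- cbind((x / 40) * gaussw(y, 95, 28), zero, zero)
  f
}

# Auxiliary fields used by the cohort generator: a bilateral-asymmetry
# pattern (forefoot lateral lean) and a loading response (arch flattening
# with mild forefoot widening).  Orthogonalized against the modes so that
# side/loading effects do not leak into the mode-weight ground truth.
raw_aux_fields <- function(vertices) {
  x <- vertices[, 1]
  y <- vertices[, 2]
  z <- vertices[, 3]
  zero <- numeric(length(x))
  asym <- cbind(0.8 * gaussw(y, 180, 45) + 0.3 * (z / 50) * gaussw(y, 60, 40),
                zero, zero)
  load <- cbind(0.35 * (x / 47) * gaussw(y, 150, 60),
                zero,
                -gaussw(x, -15, 26) * gaussw(y, 100, 50) *
                  exp(-pmax(z, 0) / 22))
  list(asym = asym, load = load)
}

# basis of the similarity-transform tangent space at a configuration:
# 3 translations, 3 infinitesimal rotations, 1 uniform scaling
similarity_tangent_basis <- function(vertices) {
  V <- nrow(vertices)
  c0 <- sweep(vertices, 2, colMeans(vertices))
  zero <- numeric(V)
  one <- rep(1, V)
  fields <- list(cbind(one, zero, zero), cbind(zero, one, zero),
                 cbind(zero, zero, one),
                 cbind(zero, -c0[, 3], c0[, 2]),    # rotation about x
                 cbind(c0[, 3], zero, -c0[, 1]),    # rotation about y
                 cbind(-c0[, 2], c0[, 1], zero),    # rotation about z
                 c0)                                # scaling
  vapply(fields, as.vector, numeric(3 * V))
}

# Gram-Schmidt orthonormalization of displacement fields.  When `vertices`
# is given, the similarity tangent space (translation, rotation, scaling)
# is projected out first, so the resulting modes are pure shape changes:
# Procrustes superimposition then removes pose without distorting the
# planted mode content.
orthonormalize_fields <- function(fields, vertices = NULL) {
  m <- vapply(fields, as.vector, numeric(3 * nrow(fields[[1]])))
  nsim <- 0L
  if (!is.null(vertices)) {
    sim <- similarity_tangent_basis(vertices)
    nsim <- ncol(sim)
    m <- cbind(sim, m)
  }
  q <- qr.Q(qr(m))
  # keep each column's dominant direction aligned with the raw field
  for (k in seq_len(ncol(q))) if (sum(q[, k] * m[, k]) < 0) q[, k] <- -q[, k]
  q <- q[, (nsim + 1L):ncol(q), drop = FALSE]
  lapply(seq_len(ncol(q)), function(k) matrix(q[, k], ncol = 3))
}

#' Define the template's deformation modes
#'
#' Returns up to six smooth, mutually orthogonal, unit-norm per-vertex
#' displacement fields emulating the main axes of healthy foot-shape
#' variation: (1) arch height (positive weight flattens the arch), (2) ball
#' width with toe spread, (3) global foot width, (4) hallux
#' orientation (valgus-varus), (5) hallux-versus-second-toe length
#' (Egyptian vs Greek foot), (6) midfoot width.  The raw anatomical fields
#' are orthonormalized (Gram-Schmidt in mode order) so that planted mode
#' weights are identifiable by principal component analysis.
#'
#' @param template the template [trimesh()] from [build_template_foot()].
#' @param n_modes number of modes, at most 6.
#' @return list of `n_modes` matrices (`V x 3`), each with unit Frobenius
#'   norm, mutually orthogonal as 3V-vectors.
#' @export
define_modes <- function(template, n_modes = 6) {
  if (n_modes > 6) stop("only six deformation modes are defined")
  if (n_modes < 1) stop("n_modes must be at least 1")
  fields <- orthonormalize_fields(raw_mode_fields(template$vertices),
                                  template$vertices)
  fields[seq_len(n_modes)]
}

#' Stack deformation modes into a 3V x K matrix
#'
#' Columns are the column-major vectorizations of the per-vertex
#' displacement fields, in mode order.
#'
#' @param modes list of `V x 3` displacement fields from [define_modes()].
#' @return `3V x K` numeric matrix with unit-norm columns.
#' @export
modes_matrix <- function(modes) {
  vapply(modes, as.vector, numeric(3 * nrow(modes[[1]])))
}
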