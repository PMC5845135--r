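## Synthetic foot-cohort generator.
##
## Emulates a scan study of healthy adults: a balanced cohort of men and
## women, four scans per subject (left/right x half/full loaded), factor
## distributions matching published cohort demographics, mode weights
## linearly driven by standardized factors plus residual anatomical noise,
## per-vertex measurement noise at the scanner's accuracy, random similarity
## pose, and optional remeshing with vertex shuffling so that shape
## correspondence is genuinely exercised.  Ground truth (mode weights, true
## corresponded coordinates, pose) is retained for validation.

cohort_factor_names <- c("sex", "age", "shoe_size", "sport_hours", "bmi",
                         "loading", "side")

default_effect_matrix <- function(n_modes = 6) {
  B <- matrix(0, 7, n_modes,
              dimnames = list(cohort_factor_names,
                              paste0("mode", seq_len(n_modes))))
  # three active factors, each driving primarily one mode; amplitudes in
  # mode-weight units (see mode_sds) chosen so effects are strong but do
  # not dominate the anatomical residual variation
  B["sex", 1] <- 25
  if (n_modes >= 2) B["shoe_size", 2] <- 15
  if (n_modes >= 3) B["sport_hours", 3] <- 12
  B
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the emulated study conditions: 62 adults scanned four
#' times each (left/right foot, half/full loaded), six anatomical
#' deformation modes with strictly decreasing weight SDs, 0.3 mm per-vertex
#' scanner noise, a bilateral-asymmetry field, an arch-flattening loading
#' response, and a moderate random similarity pose per scan.
#'
#' @param n_subjects number of subjects (4 scans each).
#' @param n_modes number of deformation modes (at most 6).
#' @param mode_sds strictly decreasing SDs of the residual (factor-free)
#'   mode weights, in weight units of the unit-norm mode fields.
#' @param effect_matrix `7 x n_modes` matrix of ground-truth regression
#'   coefficients from standardized factors (rows `sex`, `age`,
#'   `shoe_size`, `sport_hours`, `bmi`, `loading`, `side`) to mode weights.
#' @param noise_sd per-vertex, per-coordinate measurement noise SD (mm).
#' @param asymmetry_sd SD (mm-scale weight) of the per-subject bilateral
#'   asymmetry amplitude.
#' @param loading_effect weight of the arch-flattening field applied to
#'   fully loaded scans.
#' @param pose_jitter list with `rot_deg`, `trans_mm`, `scale` giving the
#'   ranges of the random similarity pose applied to each scan.
#' @param remesh re-triangulate each scan at a different resolution and
#'   shuffle its vertices, so vertex order carries no correspondence.
#' @param resolution template vertex-count target.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 62,
                             n_modes = 6,
                             mode_sds = c(60, 40, 30, 22, 16, 12),
                             effect_matrix = default_effect_matrix(n_modes),
                             noise_sd = 0.3,
                             asymmetry_sd = 2,
                             loading_effect = 6,
                             pose_jitter = list(rot_deg = 10, trans_mm = 30,
                                                scale = 0.03),
                             remesh = FALSE,
                             resolution = 2500,
                             seed = 1L) {
  if (n_modes > 6 || n_modes < 1) stop("n_modes must be between 1 and 6")
  mode_sds <- mode_sds[seq_len(n_modes)]
  if (any(diff(mode_sds) >= 0))
    stop("mode_sds must be strictly decreasing (keeps PC order identifiable)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  effect_matrix <- as.matrix(effect_matrix)
  if (nrow(effect_matrix) != 7L || ncol(effect_matrix) != n_modes)
    stop("effect_matrix must be 7 x n_modes (factors ",
         paste(cohort_factor_names, collapse = ", "), " by modes)")
  storage.mode(effect_matrix) <- "double"
  dimnames(effect_matrix) <- list(cohort_factor_names,
                                  paste0("mode", seq_len(n_modes)))
  structure(list(n_subjects = as.integer(n_subjects), n_modes = n_modes,
                 mode_sds = mode_sds, effect_matrix = effect_matrix,
                 noise_sd = noise_sd, asymmetry_sd = asymmetry_sd,
                 loading_effect = loading_effect, pose_jitter = pose_jitter,
                 remesh = isTRUE(remesh), resolution = resolution,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# truncated normal via inverse-CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

random_rotation <- function(max_deg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

sample_subjects <- function(n) {
  sex <- rep(c(1, 0), length.out = n)
  age <- rtnorm(n, 38.9, 13.5, 18, 60)
  shoe <- ifelse(sex == 1, rtnorm(n, 43.9, 1.6, 36, 46),
                 rtnorm(n, 39.8, 2.2, 36, 46))
  height <- ifelse(sex == 1, rtnorm(n, 181, 6.5, 156, 196),
                   rtnorm(n, 168.5, 6.2, 156, 196))
  z_age <- (age - 38.9) / 13.5
  bmi <- rtnorm(n, 23.7 + 3.5 * 0.35 * z_age, 3.5 * sqrt(1 - 0.35^2),
                18.6, 35.8)
  weight <- bmi * (height / 100)^2
  sport <- rtnorm(n, 3.7, 4.1, 0, 15)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), sex = sex,
             age = age, shoe_size = shoe, weight = weight, height = height,
             bmi = bmi, sport_hours = sport, stringsAsFactors = FALSE)
}

#' Generate a synthetic foot cohort with ground truth
#'
#' Draws subject factors within realistic cohort ranges (with the
#' sex/shoe-size and age/BMI correlations built in), then builds four scans
#' per subject.  Each scan's true corresponded shape is
#' `template + modes %*% w + asymmetry + loading + noise`, with mode
#' weights `w = t(effect_matrix) %*% standardized factors + residual`.
#' The raw scan mesh is the true shape mirrored for left feet, optionally
#' remeshed at a different resolution with shuffled vertex order, and posed
#' by a random similarity transform.
#'
#' @param config a [generator_config()].
#' @return object of class `foot_cohort`: list with `subjects` (data frame),
#'   `factors` (one row per scan, columns `sex`, `age`, `shoe_size`,
#'   `sport_hours`, `bmi`, `loading`, `side`), `scans` (list of scan
#'   records, each with `mesh`, `gt_coords`, `true_mode_weights`, `pose`),
#'   `template`, `modes`, `aux_fields`, and `config`.
#' @export
sample_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  template <- build_template_foot(config$resolution)
  V <- nrow(template$vertices)
  all_fields <- orthonormalize_fields(
    c(raw_mode_fields(template$vertices), raw_aux_fields(template$vertices)),
    template$vertices)
  modes <- all_fields[seq_len(config$n_modes)]
  aux <- list(asym = all_fields[[7]], load = all_fields[[8]])
  Mmat <- modes_matrix(modes)

  subjects <- sample_subjects(config$n_subjects)

  # one factor row per scan: subject factors x side x loading
  grid <- expand.grid(side = c(0, 1), loading = c(0, 1))
  factors <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    data.frame(subject_id = s$subject_id,
               scan_id = sprintf("%s_%s_%s", s$subject_id,
                                 ifelse(grid$side == 1, "R", "L"),
                                 ifelse(grid$loading == 1, "half", "full")),
               sex = s$sex, age = s$age, shoe_size = s$shoe_size,
               sport_hours = s$sport_hours, bmi = s$bmi,
               loading = grid$loading, side = grid$side,
               stringsAsFactors = FALSE)
  }))
  Fm <- as.matrix(factors[, cohort_factor_names])
  csd <- apply(Fm, 2, sd)
  Z <- scale(Fm, scale = ifelse(csd > 0, csd, 1))  # constant columns -> 0
  n_scans <- nrow(factors)

  # ground-truth mode weights: factor-driven part + residual, per scan
  W <- Z %*% config$effect_matrix +
    matrix(rnorm(n_scans * config$n_modes), n_scans) %*%
      diag(config$mode_sds, config$n_modes)

  asym_amp <- rnorm(config$n_subjects, 0, config$asymmetry_sd)
  asym_amp <- rep(asym_amp, each = nrow(grid))

  remesh_map <- NULL
  alt_template <- NULL
  if (config$remesh) {
    alt_template <- build_template_foot(round(config$resolution * 1.31))
    cp <- .closest_point_cpp(alt_template$vertices, template$vertices,
                             template$faces)
    remesh_map <- list(face = cp$face, bary = cp$bary)
  }

  pj <- config$pose_jitter
  scans <- vector("list", n_scans)
  for (k in seq_len(n_scans)) {
    side <- factors$side[k]
    loading <- factors$loading[k]
    disp <- matrix(Mmat %*% W[k, ], ncol = 3)
    disp <- disp + (if (side == 1) 0.5 else -0.5) * asym_amp[k] * aux$asym
    if (loading == 0) disp <- disp + config$loading_effect * aux$load
    gt <- template$vertices + disp +
      matrix(rnorm(3 * V, 0, config$noise_sd), V)

    if (config$remesh) {
      fc <- template$faces[remesh_map$face, , drop = FALSE]
      mv <- remesh_map$bary[, 1] * gt[fc[, 1], , drop = FALSE] +
            remesh_map$bary[, 2] * gt[fc[, 2], , drop = FALSE] +
            remesh_map$bary[, 3] * gt[fc[, 3], , drop = FALSE]
      perm <- sample.int(nrow(mv))
      inv <- integer(length(perm))
      inv[perm] <- seq_along(perm)
      mesh <- trimesh(mv[perm, , drop = FALSE],
                      matrix(inv[alt_template$faces], ncol = 3),
                      validate = FALSE)
    } else {
      mesh <- trimesh(gt, template$faces, validate = FALSE)
    }
    if (side == 0) mesh <- mirror_mesh(mesh)

    R <- random_rotation(pj$rot_deg)
    s <- exp(runif(1, -1, 1) * log1p(pj$scale))
    t <- runif(3, -pj$trans_mm, pj$trans_mm)
    centre <- colMeans(mesh$vertices)
    mesh$vertices <- s * (mesh$vertices %*% t(R)) +
      rep(centre + t - s * as.vector(R %*% centre), each = nrow(mesh$vertices))

    scans[[k]] <- list(subject_id = factors$subject_id[k],
                       scan_id = factors$scan_id[k],
                       side = side, loading = loading,
                       mesh = mesh,
                       gt_coords = gt,
                       true_mode_weights = W[k, ],
                       pose = list(R = R, s = s, t = t, centre = centre,
                                   mirrored = side == 0))
  }
  structure(list(subjects = subjects, factors = factors, scans = scans,
                 template = template, modes = modes, aux_fields = aux,
                 config = config),
            class = "foot_cohort")
}

#' @export
print.foot_cohort <- function(x, ...) {
  cat(sprintf("foot_cohort: %d subjects, %d scans, %d modes, %d vertices\n",
              nrow(x$subjects), length(x$scans), x$config$n_modes,
              nrow(x$template$vertices)))
  invisible(x)
}

#' True template-vertex positions of a scan, in the scan's frame
#'
#' Applies the scan's stored mirroring and pose to its ground-truth
#' corresponded coordinates, yielding the true position of every template
#' vertex on the scan surface.  With `processed = TRUE` the positions are
#' given in the frame of the preprocessed scan (left feet mirrored back to
#' the right-foot frame), which is what a registration estimate should be
#' compared against.
#'
#' @param scan one element of a cohort's `scans` list.
#' @param processed return positions in the mirrored-back frame (default)
#'   or in the raw scan frame.
#' @return `V x 3` matrix of true template-vertex positions.
#' @export
scan_truth_map <- function(scan, processed = TRUE) {
  v <- scan$gt_coords
  p <- scan$pose
  if (p$mirrored) v[, 1] <- -v[, 1]
  v <- p$s * (v %*% t(p$R)) +
    rep(p$centre + p$t - p$s * as.vector(p$R %*% p$centre),
        each = nrow(v))
  if (processed && p$mirrored) v[, 1] <- -v[, 1]
  v
}

#' The factor table of a cohort, one row per scan
#'
#' @param cohort a `foot_cohort`.
#' @return data frame with the seven analysis factors, coded as in the
#'   regression model (`sex` 1 = male, `loading` 1 = half loaded, `side`
#'   1 = right foot).
#' @export
cohort_factor_table <- function(cohort) {
  cohort$factors[, cohort_factor_names]
}
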