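# Synthetic cohort generator: determinism, factor ranges, ground truth.

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- generator_config(n_subjects = 4, resolution = 300, seed = 7,
                          remesh = TRUE)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$factors, b$factors)
  for (k in seq_along(a$scans)) {
    expect_identical(a$scans[[k]]$mesh$vertices, b$scans[[k]]$mesh$vertices)
    expect_identical(a$scans[[k]]$true_mode_weights,
                     b$scans[[k]]$true_mode_weights)
  }
})

test_that("factors fall inside the configured cohort ranges", {
  coh <- fixture("cohort62small", function()
    sample_cohort(generator_config(n_subjects = 62, resolution = 300,
                                   seed = 3)))
  s <- coh$subjects
  expect_equal(sum(s$sex == 1), 31)
  expect_true(all(s$age >= 18 & s$age <= 60))
  expect_true(all(s$shoe_size >= 36 & s$shoe_size <= 46))
  expect_true(all(s$bmi >= 18.6 & s$bmi <= 35.8))
  expect_true(all(s$sport_hours >= 0 & s$sport_hours <= 15))
  expect_true(all(abs(s$bmi - s$weight / (s$height / 100)^2) < 0.1))
  # built-in confounds: males have larger shoe sizes; BMI-age correlation
  expect_gt(mean(s$shoe_size[s$sex == 1]) - mean(s$shoe_size[s$sex == 0]), 2)
  expect_gt(cor(s$age, s$bmi), 0.1)
  # four scans per subject, 2 sides x 2 loadings
  tab <- table(coh$factors$subject_id)
  expect_true(all(tab == 4))
  expect_true(all(coh$factors$side %in% c(0, 1)))
  expect_true(all(coh$factors$loading %in% c(0, 1)))
})

test_that("with zero effects, factors and mode weights are uncorrelated", {
  cfg <- generator_config(n_subjects = 500, resolution = 300,
                          effect_matrix = matrix(0, 7, 6), seed = 5,
                          pose_jitter = list(rot_deg = 0, trans_mm = 0,
                                             scale = 0))
  coh <- sample_cohort(cfg)
  W <- do.call(rbind, lapply(coh$scans, function(s) s$true_mode_weights))
  Fm <- as.matrix(cohort_factor_table(coh))
  rho <- suppressWarnings(cor(Fm, W))
  expect_lt(max(abs(rho)), 0.15)
})

test_that("mode-weight covariance converges to its configured value", {
  cfg <- generator_config(n_subjects = 250, resolution = 300,
                          effect_matrix = matrix(0, 7, 6), seed = 9)
  coh <- sample_cohort(cfg)
  W <- do.call(rbind, lapply(coh$scans, function(s) s$true_mode_weights))
  v_emp <- apply(W, 2, var)
  expect_true(all(abs(v_emp / cfg$mode_sds^2 - 1) < 0.15))
})

test_that("loading and asymmetry fields act only on their own contrast", {
  # anatomical variation switched off so the side/loading contrasts
  # isolate exactly the planted asymmetry and loading fields
  cfg <- generator_config(n_subjects = 3, resolution = 400, noise_sd = 0,
                          seed = 2, mode_sds = (6:1) * 1e-9,
                          effect_matrix = matrix(0, 7, 6),
                          pose_jitter = list(rot_deg = 0, trans_mm = 0,
                                             scale = 0))
  coh <- sample_cohort(cfg)
  f <- coh$factors
  lf <- as.vector(coh$aux_fields$load)
  af <- as.vector(coh$aux_fields$asym)
  for (sid in coh$subjects$subject_id) {
    rows <- which(f$subject_id == sid)
    gt <- lapply(coh$scans[rows], `[[`, "gt_coords")
    # same side, half (loading=1) minus full (loading=0): -loading_effect
    # along the load field, nothing along the asymmetry field
    for (sd_ in c(0, 1)) {
      i_half <- rows[f$side[rows] == sd_ & f$loading[rows] == 1][1]
      i_full <- rows[f$side[rows] == sd_ & f$loading[rows] == 0][1]
      d <- as.vector(coh$scans[[i_half]]$gt_coords -
                     coh$scans[[i_full]]$gt_coords)
      expect_equal(sum(d * lf), -cfg$loading_effect, tolerance = 1e-6)
      expect_equal(sum(d * af), 0, tolerance = 1e-6)
      expect_lt(sqrt(sum((d - sum(d * lf) * lf)^2)), 1e-6)
    }
    # same loading, right minus left: asymmetry field only
    for (ld in c(0, 1)) {
      i_r <- rows[f$side[rows] == 1 & f$loading[rows] == ld][1]
      i_l <- rows[f$side[rows] == 0 & f$loading[rows] == ld][1]
      d <- as.vector(coh$scans[[i_r]]$gt_coords -
                     coh$scans[[i_l]]$gt_coords)
      expect_equal(sum(d * lf), 0, tolerance = 1e-6)
      expect_lt(sqrt(sum((d - sum(d * af) * af)^2)), 1e-6)
    }
  }
})

test_that("generated meshes pass validity checks, remeshed or not", {
  for (remesh in c(FALSE, TRUE)) {
    coh <- sample_cohort(generator_config(n_subjects = 1, resolution = 300,
                                          remesh = remesh, seed = 4))
    for (s in coh$scans) expect_silent(validate_mesh(s$mesh))
  }
})

test_that("remeshed scans have different vertex counts and shuffled order", {
  coh <- sample_cohort(generator_config(n_subjects = 1, resolution = 400,
                                        remesh = TRUE, seed = 6))
  sc <- coh$scans[[2]]
  expect_false(nrow(sc$mesh$vertices) == nrow(coh$template$vertices))
  # the truth map still lies on the scan surface
  cp <- footmorph:::.closest_point_cpp(scan_truth_map(sc, processed = FALSE),
                                       sc$mesh$vertices, sc$mesh$faces)
  expect_lt(mean(cp$dist), 1)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(generator_config(mode_sds = c(10, 20, 5, 4, 3, 2)),
               "decreasing")
  expect_error(generator_config(noise_sd = -1), "non-negative")
  expect_error(generator_config(effect_matrix = matrix(0, 3, 6)), "7 x")
  expect_error(generator_config(n_modes = 7), "between 1 and 6")
})
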