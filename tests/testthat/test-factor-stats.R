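# Factor regression, BIC forward selection, power, correlations,
# deviation fields.

test_that("forward selection recovers planted predictor sets", {
  set.seed(11)
  hits <- 0L
  for (rep in seq_len(20)) {
    n <- 248
    W <- matrix(rnorm(n * 20), n)
    B <- matrix(rnorm(9, sd = 2), 3, 3)
    Fm <- W[, c(1, 3, 5)] %*% B + matrix(rnorm(n * 3, sd = 0.5), n)
    sel <- forward_select_pcs(W, Fm)
    if (identical(as.integer(sel), c(1L, 3L, 5L))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("pure-noise responses select no principal components", {
  set.seed(12)
  for (rep in seq_len(5)) {
    W <- matrix(rnorm(248 * 40), 248)
    Fm <- matrix(rnorm(248 * 7), 248)
    expect_length(forward_select_pcs(W, Fm), 0L)
  }
})

test_that("the BIC trace decreases strictly along accepted additions", {
  set.seed(13)
  W <- matrix(rnorm(200 * 10), 200)
  Fm <- W[, 1:4] %*% matrix(rnorm(8), 4) + matrix(rnorm(400, sd = 0.3), 200)
  sel <- forward_select_pcs(W, Fm)
  trace <- attr(sel, "bic_trace")
  expect_gte(length(sel), 1L)
  expect_true(all(diff(trace) < 0))
})

test_that("noise-free planted coefficients are recovered exactly", {
  set.seed(14)
  W <- matrix(rnorm(60 * 4), 60)
  B_true <- rbind(c(0.5, -1), matrix(rnorm(8), 4))
  Fm <- cbind(1, W) %*% B_true
  colnames(Fm) <- c("f1", "f2")
  fm <- fit_factor_model(W, Fm)
  expect_lt(max(abs(fm$B - B_true)), 1e-8)
  expect_equal(unname(fm$r_squared), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(fm$power), c(1, 1))
})

test_that("coefficient confidence intervals have nominal coverage", {
  set.seed(15)
  n <- 100
  W <- matrix(rnorm(n * 3), n)
  B_true <- rbind(0.3, matrix(c(1, -0.5, 0.25, 0.4, 0, -1), 3))
  X <- cbind(1, W)
  XtXi <- solve(crossprod(X))
  cover <- 0L
  total <- 0L
  for (rep in seq_len(200)) {
    Fm <- X %*% B_true + matrix(rnorm(n * 2), n)
    colnames(Fm) <- c("a", "b")
    fm <- fit_factor_model(W, Fm)
    tcrit <- qt(0.975, n - 4)
    for (j in 1:2) {
      se <- sqrt(diag(XtXi)) * fm$residual_sd[j]
      lo <- fm$B[, j] - tcrit * se
      hi <- fm$B[, j] + tcrit * se
      cover <- cover + sum(B_true[, j] >= lo & B_true[, j] <= hi)
      total <- total + 4L
    }
  }
  expect_gte(cover / total, 0.93)
  expect_lte(cover / total, 0.97)
})

test_that("null R-squared follows its Beta reference distribution", {
  set.seed(16)
  n <- 248
  k <- 6
  r2s <- replicate(400, {
    W <- matrix(rnorm(n * k), n)
    y <- rnorm(n)
    fm <- fit_factor_model(W, matrix(y, dimnames = list(NULL, "y")))
    fm$r_squared
  })
  # under the null, R2 ~ Beta(k/2, (n-k-1)/2)
  for (q in c(0.25, 0.5, 0.75, 0.95)) {
    expect_lt(abs(mean(r2s <= qbeta(q, k / 2, (n - k - 1) / 2)) - q), 0.07)
  }
  # a factor independent of all PCs stays inside the null band
  expect_lt(median(r2s), qbeta(0.75, k / 2, (n - k - 1) / 2))
})

test_that("post-hoc power matches its closed-form contracts", {
  expect_equal(posthoc_power(0, 100, 6), 0.05, tolerance = 1e-12)
  expect_equal(posthoc_power(0, 50, 3, alpha = 0.1), 0.1, tolerance = 1e-12)
  # monotone in r2 and n
  r2g <- seq(0, 0.5, by = 0.05)
  pw <- vapply(r2g, posthoc_power, 0, n = 100, k = 6)
  expect_true(all(diff(pw) > 0))
  ng <- c(20, 50, 100, 200, 400)
  pw2 <- vapply(ng, function(n) posthoc_power(0.15, n, 6), 0)
  expect_true(all(diff(pw2) > 0))
  expect_error(posthoc_power(1, 100, 6), "r2")
  expect_error(posthoc_power(-0.1, 100, 6), "r2")
})

test_that("power agrees with a Monte-Carlo simulation at one grid point", {
  # smaller version of the full calibration (which uses 50,000 reps over a
  # grid); here 20,000 reps at one point
  set.seed(17)
  n <- 100
  k <- 6
  r2 <- 0.12
  mc <- mc_power(r2, n, k, reps = 20000)
  expect_lt(abs(mc - posthoc_power(r2, n, k)), 0.015)
})

test_that("correlation tables behave like cor.test", {
  set.seed(18)
  W <- matrix(rnorm(100 * 2), 100)
  Fm <- cbind(copy = W[, 1], indep = rnorm(100))
  tab <- pc_factor_correlations(W, Fm)
  row <- tab[tab$pc == 1 & tab$factor == "copy", ]
  expect_equal(row$rho, 1, tolerance = 1e-12)
  expect_lt(row$p, 1e-10)
  expect_true(row$significant)
  # invariance under affine rescaling of either variable
  Fm2 <- cbind(copy = 5 - 3 * W[, 1], indep = Fm[, 2] * 100 + 4)
  tab2 <- pc_factor_correlations(W, Fm2)
  expect_equal(abs(tab2$rho), abs(tab$rho), tolerance = 1e-12)
  expect_equal(tab2$p, tab$p, tolerance = 1e-12)
  # Spearman variant available
  tabs <- pc_factor_correlations(W, Fm, method = "spearman")
  expect_equal(tabs$rho[tab$pc == 1 & tab$factor == "copy"][1], 1)
  # constant columns give NA with a warning
  expect_warning(tabc <- pc_factor_correlations(W, cbind(const = rep(1, 100))),
                 "constant")
  expect_true(all(is.na(tabc$rho)))
})

test_that("deviation fields measure per-vertex distances symmetrically", {
  a <- matrix(rnorm(30), 10)
  expect_equal(as.numeric(deviation_field(a, a)), rep(0, 10))
  b <- a
  b[, 1] <- b[, 1] + 1
  expect_equal(as.numeric(deviation_field(a, b)), rep(1, 10))
  expect_equal(deviation_field(a, b), deviation_field(b, a))
  expect_error(deviation_field(a, matrix(0, 5, 3)), "mismatch")
  # random unit-norm offsets: all distances exactly 1
  off <- matrix(rnorm(30), 10)
  off <- off / sqrt(rowSums(off^2))
  expect_equal(as.numeric(deviation_field(a, a + off)), rep(1, 10),
               tolerance = 1e-12)
})

test_that("deviation regression recovers a planted BMI effect", {
  set.seed(19)
  n <- 62
  V <- 200
  bmi <- rnorm(n, 24, 3.5)
  pattern <- abs(rnorm(V))
  fields <- 2 + outer((bmi - mean(bmi)) / sd(bmi), pattern) +
    matrix(rnorm(n * V, sd = 0.3), n)
  Fs <- data.frame(sex = rep(0:1, length.out = n), age = rnorm(n, 40, 10),
                   bmi = bmi)
  reg <- deviation_regression(fields, Fs)
  expect_true("bmi" %in% names(which(reg$model$significant)))
  expect_gt(reg$model$r_squared["bmi"],
            qbeta(0.95, reg$model$k / 2, (n - reg$model$k - 1) / 2))
  expect_error(deviation_regression(matrix(0, n, V), Fs), "constant")
})

test_that("pure-noise deviation fields yield no spurious factor effects", {
  # At these sample sizes the BIC gate keeps selection shut under the
  # null, so the select-then-test procedure rarely reports anything.
  # (At small n the same procedure is anti-conservative after selection;
  # see the methods vignette.)
  set.seed(20)
  flagged_reps <- 0L
  for (rep in seq_len(10)) {
    fields <- matrix(rnorm(248 * 150), 248)
    Fs <- data.frame(sex = rep(0:1, length.out = 248),
                     age = rnorm(248, 40, 10), bmi = rnorm(248, 24, 3))
    reg <- deviation_regression(fields, Fs)
    if (!is.null(reg$model) && any(reg$model$significant))
      flagged_reps <- flagged_reps + 1L
  }
  expect_lte(flagged_reps, 2L)
})

test_that("predicted shapes respond linearly to the varied factor", {
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 60), n)
  model <- fit_pca(X, n_components = 5)
  W <- model$scores[, 1:3]
  B <- rbind(c(24, 0.4), matrix(c(2, -1, 0.5, 0, 0, 0), 3))
  Fm <- cbind(1, W) %*% B + matrix(rnorm(n * 2, sd = 0.05), n)
  colnames(Fm) <- c("bmi", "flat")
  fm <- fit_factor_model(W, Fm, selected_pcs = 1:3)

  pr <- predict_shape(fm, model, vary = "bmi", range_rule = "mean_pm_2sd")
  # midpoint prediction is the midpoint of the endpoint shapes
  mid <- predict_shape(fm, model, vary = "bmi", range = rep(mean(pr$range), 2))
  expect_equal(mid$shape_low, (pr$shape_low + pr$shape_high) / 2,
               tolerance = 1e-8)
  expect_equal(unclass(mid$field), rep(0, 20), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a factor with (near) zero fitted effect moves nothing
  fm0 <- fm
  fm0$B[-1, 2] <- 0
  pr0 <- predict_shape(fm0, model, vary = "flat")
  expect_equal(pr0$shape_low, pr0$shape_high, tolerance = 1e-10)
  expect_lt(max(pr0$field), 1e-10)

  expect_error(predict_shape(fm, model, vary = "nope"), "unknown factor")
  # quantile90 range equals the 5th/95th percentiles of the cohort factor
  pr9 <- predict_shape(fm, model, vary = "bmi", range_rule = "quantile90")
  expect_equal(pr9$range,
               as.numeric(quantile(fm$factor_table$bmi, c(0.05, 0.95))))
})

test_that("R-squared is monotone in nested predictor sets", {
  set.seed(22)
  W <- matrix(rnorm(150 * 8), 150)
  Fm <- cbind(y = W[, 1] + rnorm(150))
  r2_sub <- fit_factor_model(W[, 1:3], Fm)$r_squared
  r2_all <- fit_factor_model(W, Fm)$r_squared
  expect_gte(r2_all + 1e-12, r2_sub)
})

test_that("permuting a factor column destroys its significance", {
  set.seed(23)
  n <- 248
  W <- matrix(rnorm(n * 3), n)
  y <- W[, 1] * 2 + rnorm(n)
  p_perm <- replicate(40, {
    fit_factor_model(W, cbind(y = sample(y)))$p_value
  })
  expect_gte(mean(p_perm > 0.05), 0.9)
})
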