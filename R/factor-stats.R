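## Relating subject factors to shape.
##
## The regression follows the multivariate linear model F = W B + E: the
## factor matrix F (one column per subject factor) is regressed on the
## matrix W of principal-component scores, with E ~ N(0, sigma^2 I).  The
## subset of PCs entering W is chosen by greedy sequential forward
## selection under the Bayesian information criterion.  Per factor, the
## fit is summarized by R-squared, the overall F-test p-value, and the
## post-hoc power of that test.

#' Sequential forward selection of principal components by BIC
#'
#' Greedy selection for the multivariate regression of all factor columns
#' on PC scores: starting from the empty set, at each step the PC whose
#' addition most decreases the total BIC (summed over factor columns,
#' Gaussian likelihood, counting one variance parameter per column) is
#' added; selection stops when no addition decreases BIC.  Ties are broken
#' by the lower PC index, so the result is deterministic.
#'
#' @param W `N x n` matrix of PC scores (candidates).
#' @param F_table data frame or matrix of factors, one row per scan.
#' @param max_pcs optional cap on the number of selected PCs.
#' @return integer vector of selected PC indices (possibly empty), with
#'   attribute `"bic_trace"` giving the total BIC after each accepted
#'   addition (first element: intercept-only model).
#' @export
forward_select_pcs <- function(W, F_table, max_pcs = ncol(W)) {
  W <- as.matrix(W)
  Fm <- as.matrix(F_table)
  n <- nrow(W)
  if (n < 2) stop("need at least two scans")
  if (nrow(Fm) != n) stop("factor table and score matrix row mismatch")
  m <- ncol(Fm)
  # incremental orthogonalization: Q holds an orthonormal basis of the
  # current design (intercept + selected PCs); RSS per factor column is
  # updated from projections onto each newly added basis vector.
  Q <- matrix(1 / sqrt(n), n, 1)
  rss <- colSums(Fm^2) - colSums((crossprod(Q, Fm))^2)
  # BIC with p = k + 2 parameters per column (intercept, k slopes, sigma^2)
  bic_total <- function(rss, k) sum(n * log(pmax(rss, 1e-300) / n)) +
    m * (k + 2) * log(n)
  selected <- integer(0)
  bic_cur <- bic_total(rss, 0)
  trace <- bic_cur
  candidates <- setdiff(seq_len(ncol(W)), selected)
  while (length(selected) < max_pcs && length(candidates) > 0 &&
         length(selected) + 2 < n) {
    # residualize every candidate against the current basis at once
    Wres <- W[, candidates, drop = FALSE] -
      Q %*% crossprod(Q, W[, candidates, drop = FALSE])
    norms <- sqrt(colSums(Wres^2))
    usable <- norms > 1e-8 * sqrt(n)
    if (!any(usable)) break
    best_bic <- Inf
    best_j <- NA_integer_
    best_q <- NULL
    for (jj in which(usable)) {
      q <- Wres[, jj] / norms[jj]
      rss_new <- pmax(rss - as.vector(crossprod(q, Fm))^2, 0)
      b <- bic_total(rss_new, length(selected) + 1)
      if (b < best_bic - 1e-12) {   # strict improvement; ties keep lower idx
        best_bic <- b
        best_j <- candidates[jj]
        best_q <- q
      }
    }
    if (!is.finite(best_bic) || best_bic >= bic_cur) break
    selected <- c(selected, best_j)
    Q <- cbind(Q, best_q)
    rss <- pmax(rss - as.vector(crossprod(best_q, Fm))^2, 0)
    bic_cur <- best_bic
    trace <- c(trace, bic_cur)
    candidates <- setdiff(candidates, best_j)
  }
  structure(sort(selected), bic_trace = trace, selection_order = selected)
}

#' Fit the factor regression model F = W B + E
#'
#' Least-squares fit of every factor column on the selected PC scores
#' (plus intercept).  Per factor the fit reports R-squared, the overall
#' F-test p-value, the residual SD, and post-hoc power at the given alpha.
#'
#' @param W_selected `N x k` matrix of selected PC scores.
#' @param F_table data frame of factors (columns are responses).
#' @param alpha significance level used for the power computation and
#'   significance flags.
#' @param selected_pcs optional indices (bookkeeping only, stored).
#' @return object of class `factor_model`: list with `B` (`(k+1) x m`
#'   coefficients, intercept row first), `r_squared`, `p_value`, `power`,
#'   `residual_sd`, `significant`, `selected_pcs`, `n`, `k`, and
#'   `factor_stats` (per-factor mean/sd/quantiles used for prediction
#'   ranges).
#' @export
fit_factor_model <- function(W_selected, F_table, alpha = 0.05,
                             selected_pcs = NULL) {
  W <- as.matrix(W_selected)
  Fm <- as.matrix(F_table)
  n <- nrow(Fm)
  k <- ncol(W)
  if (k == 0) stop("no predictors: select at least one PC")
  X <- cbind(`(intercept)` = 1, W)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  B <- qr.coef(qx, Fm)
  fitted <- X %*% B
  res <- Fm - fitted
  rss <- colSums(res^2)
  tss <- colSums(sweep(Fm, 2, colMeans(Fm))^2)
  r2 <- 1 - rss / tss
  df2 <- n - k - 1
  fstat <- (r2 / k) / ((1 - r2) / df2)
  p <- pf(fstat, k, df2, lower.tail = FALSE)
  pow <- vapply(r2, function(r) {
    if (r >= 1 - 1e-12) 1 else posthoc_power(max(r, 0), n, k, alpha)
  }, 0)
  fs <- lapply(as.data.frame(Fm), function(col)
    list(mean = mean(col), sd = sd(col),
         q05 = as.numeric(quantile(col, 0.05)),
         q95 = as.numeric(quantile(col, 0.95)),
         min = min(col), max = max(col)))
  structure(list(B = B, r_squared = r2, p_value = p, power = pow,
                 residual_sd = sqrt(rss / df2),
                 significant = p < alpha,
                 selected_pcs = selected_pcs %||% seq_len(k),
                 n = n, k = k, alpha = alpha,
                 factor_names = colnames(Fm),
                 factor_stats = fs,
                 factor_table = as.data.frame(Fm)),
            class = "factor_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d scans, %d PCs (%s)\n", x$n, x$k,
              paste(x$selected_pcs, collapse = ", ")))
  print(data.frame(r_squared = round(x$r_squared, 4),
                   p = signif(x$p_value, 3),
                   power = round(x$power, 4),
                   significant = x$significant))
  invisible(x)
}

#' Post-hoc power of the overall regression F-test
#'
#' Power of the F-test of a multiple regression with `k` predictors and
#' `n` observations against the effect size actually observed: effect size
#' `f2 = r2 / (1 - r2)`, noncentrality `lambda = f2 * n`, degrees of
#' freedom `(k, n - k - 1)`.
#'
#' @param r2 observed R-squared, in `[0, 1)`.
#' @param n number of observations.
#' @param k number of predictors.
#' @param alpha significance level.
#' @return power in `[alpha, 1]`.
#' @export
posthoc_power <- function(r2, n, k, alpha = 0.05) {
  if (r2 < 0 || r2 >= 1) stop("r2 must be in [0, 1)")
  df2 <- n - k - 1
  if (df2 < 1) stop("n too small for k predictors")
  lambda <- n * r2 / (1 - r2)
  crit <- qf(1 - alpha, k, df2)
  pf(crit, k, df2, ncp = lambda, lower.tail = FALSE)
}

#' Monte-Carlo power of the overall regression F-test
#'
#' Brute-force check of [posthoc_power()]: simulates regressions with a
#' fixed orthonormal design and a signal of noncentrality
#' `n * r2 / (1 - r2)`, and counts rejections of the overall F-test.
#' Independent of the noncentral-F closed form, so it serves as a
#' calibration oracle.
#'
#' @param r2 population R-squared of the simulated alternative.
#' @param n,k observations and predictors.
#' @param alpha significance level.
#' @param reps number of simulated datasets.
#' @param chunk simulation block size (memory control).
#' @return estimated rejection probability.
#' @export
mc_power <- function(r2, n, k, alpha = 0.05, reps = 50000, chunk = 10000) {
  lambda <- n * r2 / (1 - r2)
  # k orthonormal predictor columns orthogonal to the intercept
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n))))[, -1, drop = FALSE]
  mu <- as.vector(X %*% c(sqrt(lambda), rep(0, k - 1)))
  crit <- qf(1 - alpha, k, n - k - 1)
  rej <- 0L
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    Y <- mu + matrix(rnorm(n * m), n)
    Yc <- sweep(Y, 2, colMeans(Y))
    ssr <- colSums(crossprod(X, Yc)^2)
    sse <- colSums(Yc^2) - ssr
    fstat <- (ssr / k) / (sse / (n - k - 1))
    rej <- rej + sum(fstat > crit)
    done <- done + m
  }
  rej / reps
}

#' Correlations between PC scores and subject factors
#'
#' Pairwise correlation between each score column and each factor, with
#' two-sided p-values and a significance flag at `alpha`.  Pearson
#' correlation (with t-distributed p) is the default; Spearman is
#' available since a rank correlation is equally defensible for ordinal
#' factors.  Constant columns yield `NA` for their pairs, with a warning.
#'
#' @param W `N x j` matrix of PC scores.
#' @param F_table data frame of factors.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level for the flag.
#' @return data frame with one row per (PC, factor) pair: `pc`, `factor`,
#'   `rho`, `p`, `significant`.
#' @export
pc_factor_correlations <- function(W, F_table, method = c("pearson",
                                                          "spearman"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  W <- as.matrix(W)
  Fm <- as.matrix(F_table)
  n <- nrow(W)
  out <- expand.grid(pc = seq_len(ncol(W)),
                     factor = colnames(Fm) %||% seq_len(ncol(Fm)),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$p <- NA_real_
  warned <- FALSE
  for (r in seq_len(nrow(out))) {
    wv <- W[, out$pc[r]]
    fv <- Fm[, out$factor[r]]
    if (sd(wv) == 0 || sd(fv) == 0) {
      if (!warned) {
        warning("constant column; NA returned for the affected pair(s)")
        warned <- TRUE
      }
      next
    }
    ct <- suppressWarnings(stats::cor.test(wv, fv, method = method,
                                           exact = FALSE))
    out$rho[r] <- unname(ct$estimate)
    out$p[r] <- ct$p.value
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Per-vertex deviation field between two corresponded shapes
#'
#' The Euclidean distance between corresponding vertices of two aligned
#' shapes; used as the non-binary bilateral-asymmetry measure (right vs
#' mirrored left foot) and the loading measure (half vs full loaded foot).
#'
#' @param shape_a,shape_b 3V shape vectors or `V x 3` matrices from the
#'   same correspondence template.
#' @param kind `"asymmetry"`, `"loading"`, or `"generic"` (bookkeeping).
#' @return numeric vector of V non-negative distances with attribute
#'   `"kind"`; symmetric in its shape arguments.
#' @export
deviation_field <- function(shape_a, shape_b,
                            kind = c("generic", "asymmetry", "loading")) {
  kind <- match.arg(kind)
  A <- if (is.matrix(shape_a)) shape_a else vec_to_coords(shape_a)
  B <- if (is.matrix(shape_b)) shape_b else vec_to_coords(shape_b)
  if (!all(dim(A) == dim(B))) stop("vertex count mismatch")
  structure(sqrt(rowSums((A - B)^2)), kind = kind)
}

#' PCA + factor regression of per-subject deviation fields
#'
#' Implements the analysis of the non-binary asymmetry/loading measures:
#' PCA of the per-subject vectors of vertex distances, then BIC forward
#' selection and multivariate regression of the remaining subject factors
#' on the deviation PCs.
#'
#' @param fields `N_subjects x V` matrix, one deviation field per subject.
#' @param F_subject data frame of subject-level factors (the binary
#'   `side`/`loading` columns are excluded by the caller as appropriate).
#' @param alpha significance level.
#' @param max_pcs cap on candidate deviation PCs (default: full rank).
#' @return list with `model` (a `factor_model`), `pca` (a `shape_model`-
#'   style PCA of the fields), and `selected_pcs`.
#' @export
deviation_regression <- function(fields, F_subject, alpha = 0.05,
                                 max_pcs = NULL) {
  fields <- as.matrix(fields)
  if (nrow(fields) != nrow(F_subject))
    stop("one deviation field per subject is required")
  if (all(apply(fields, 2, sd) == 0))
    stop("deviation fields are constant; PCA is undefined")
  pca <- fit_pca(fields)
  if (is.null(max_pcs)) max_pcs <- length(pca$sds)
  sel <- forward_select_pcs(pca$scores, F_subject, max_pcs = max_pcs)
  if (length(sel) == 0) {
    return(list(model = NULL, pca = pca, selected_pcs = integer(0),
                note = "no deviation PC improved BIC; no linear relation"))
  }
  model <- fit_factor_model(pca$scores[, sel, drop = FALSE], F_subject,
                            alpha = alpha, selected_pcs = sel)
  list(model = model, pca = pca, selected_pcs = sel)
}

#' Predict foot shapes from the factor model while varying one factor
#'
#' Inverts the fitted linear map (factors regressed on scores) with the
#' least-squares pseudo-inverse of the coefficient matrix to obtain the
#' expected PC scores at a low and a high setting of one factor, holding
#' all other factors fixed; both shapes are synthesized through the shape
#' model and their per-vertex deviation field is returned for
#' colour-mapping.
#'
#' The low/high settings follow `range_rule`: `"quantile90"` uses the
#' 5th/95th percentiles of the varied factor over the (optionally
#' subsetted) cohort, `"mean_pm_2sd"` uses the factor mean plus/minus two
#' SDs, `"minmax"` the observed extremes; or give explicit `range`.
#'
#' @param factor_model a `factor_model` (fitted on the shape-model scores).
#' @param shape_model the `shape_model` whose components the factor model
#'   indexes via `selected_pcs`.
#' @param vary name of the factor to vary.
#' @param factor_values named list/vector fixing the other factors
#'   (defaults: cohort means).
#' @param range_rule `"quantile90"`, `"mean_pm_2sd"`, or `"minmax"`.
#' @param range explicit `c(low, high)` overriding `range_rule`.
#' @param subset optional logical vector over cohort scans; range
#'   statistics are computed within the subgroup (e.g. one sex).
#' @return list with `shape_low`, `shape_high` (3V vectors), `field`
#'   (deviation field, mm), `scores_low`, `scores_high`, `range`.
#' @export
predict_shape <- function(factor_model, shape_model, vary,
                          factor_values = NULL,
                          range_rule = c("quantile90", "mean_pm_2sd",
                                         "minmax"),
                          range = NULL, subset = NULL) {
  range_rule <- match.arg(range_rule)
  fn <- factor_model$factor_names
  if (!vary %in% fn) stop("unknown factor '", vary, "'")
  if (is.null(range)) {
    col <- factor_model$factor_table[[vary]]
    if (!is.null(subset)) {
      if (length(subset) != length(col))
        stop("subset length must match the fitted cohort")
      col <- col[subset]
    }
    range <- switch(range_rule,
                    quantile90 = as.numeric(quantile(col, c(0.05, 0.95))),
                    mean_pm_2sd = mean(col) + c(-2, 2) * sd(col),
                    minmax = range(col))
  }
  base <- vapply(fn, function(f) factor_model$factor_stats[[f]]$mean, 0)
  if (!is.null(factor_values)) {
    unknown <- setdiff(names(factor_values), fn)
    if (length(unknown))
      stop("unknown factor(s): ", paste(unknown, collapse = ", "))
    base[names(factor_values)] <- unlist(factor_values)
  }
  b0 <- factor_model$B[1, ]
  Bc <- factor_model$B[-1, , drop = FALSE]      # k x m
  solve_scores <- function(fvec) {
    # least-squares scores w minimizing |fvec - (b0 + t(Bc) w)|^2
    as.vector(MASS::ginv(t(Bc)) %*% (fvec - b0))
  }
  f_low <- f_high <- base
  f_low[vary] <- range[1]
  f_high[vary] <- range[2]
  w_low <- solve_scores(f_low)
  w_high <- solve_scores(f_high)
  expand <- function(w) {
    full <- numeric(length(shape_model$sds))
    full[factor_model$selected_pcs] <- w
    full
  }
  s_low <- synthesize(shape_model, expand(w_low))
  s_high <- synthesize(shape_model, expand(w_high))
  list(shape_low = s_low, shape_high = s_high,
       field = deviation_field(s_low, s_high),
       scores_low = w_low, scores_high = w_high, range = range)
}
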