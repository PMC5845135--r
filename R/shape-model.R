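## Principal-component point distribution model.
##
## Every shape is modelled as X = M + sum_i P_i w_i: the mean shape plus a
## weighted sum of orthonormal principal components.  The decomposition is
## computed by singular value decomposition of the centered N x 3V data
## matrix (never the 3V x 3V covariance), which is the only feasible route
## at scan-scale vertex counts.

#' Fit a PCA shape model to aligned shapes
#'
#' Components are ordered by decreasing variance; per-component score SDs
#' use the `N - 1` denominator.  A deterministic sign convention is
#' applied: the entry of largest magnitude in each component is positive.
#'
#' @param aligned an `aligned_shapes` object from [gpa()], or an `N x 3V`
#'   matrix of superimposed shape vectors.
#' @param n_components number of components to retain, or `"full"` for the
#'   maximal rank `min(N - 1, 3V)`.
#' @return object of class `shape_model`: list with `mean` (3V),
#'   `components` (`n x 3V` orthonormal rows), `sds` (per-component score
#'   SD), `scores` (`N x n`), `explained_fraction`, `total_variance`, and
#'   `scan_ids`.
#' @export
fit_pca <- function(aligned, n_components = "full") {
  X <- if (inherits(aligned, "aligned_shapes")) aligned$shapes else
    as.matrix(aligned)
  ids <- if (inherits(aligned, "aligned_shapes")) aligned$scan_ids else
    rownames(X)
  n <- nrow(X)
  if (n < 2) stop("PCA needs at least two shapes")
  rank <- min(n - 1L, ncol(X))
  if (identical(n_components, "full")) n_components <- rank
  if (n_components > rank)
    stop("n_components exceeds the maximal rank ", rank)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = rank, nv = rank)
  d <- sv$d[seq_len(rank)]
  # deterministic sign: largest-|entry| coordinate of each component > 0
  P <- t(sv$v)
  U <- sv$u
  for (k in seq_len(rank)) {
    j <- which.max(abs(P[k, ]))
    if (P[k, j] < 0) {
      P[k, ] <- -P[k, ]
      U[, k] <- -U[, k]
    }
  }
  vars <- d^2 / (n - 1)
  total <- sum(Xc^2) / (n - 1)
  keep <- seq_len(n_components)
  scores <- U[, keep, drop = FALSE] %*% diag(d[keep], n_components)
  rownames(scores) <- ids
  structure(list(mean = mu,
                 components = P[keep, , drop = FALSE],
                 sds = sqrt(vars[keep]),
                 scores = scores,
                 explained_fraction = vars[keep] / total,
                 total_variance = total,
                 scan_ids = ids),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  k <- min(6L, length(x$sds))
  cat(sprintf("shape_model: %d components over %d vertices, %d shapes\n",
              length(x$sds), length(x$mean) / 3, nrow(x$scores)))
  cat(sprintf("  first %d PCs explain %.2f%% of total variance\n", k,
              100 * sum(x$explained_fraction[seq_len(k)])))
  invisible(x)
}

#' Synthesize a shape from model weights
#'
#' Evaluates `M + sum_i P_i w_i`.  With `sigma_units = TRUE` the weights
#' are interpreted in per-component SD units (so `c(3, 0, 0)` is the mean
#' plus three SDs along PC 1, as used to visualize component extremes).
#'
#' @param model a `shape_model`.
#' @param weights numeric vector, length at most the number of components.
#' @param sigma_units interpret weights in units of the component SDs.
#' @return 3V shape vector.
#' @export
synthesize <- function(model, weights, sigma_units = FALSE) {
  if (!all(is.finite(weights))) stop("weights must be finite")
  k <- length(weights)
  if (k > length(model$sds)) stop("more weights than model components")
  if (sigma_units) weights <- weights * model$sds[seq_len(k)]
  if (k == 0) return(model$mean)
  model$mean + as.vector(crossprod(model$components[seq_len(k), ,
                                                    drop = FALSE], weights))
}

#' Project a shape onto the model components
#'
#' Computes the score of each component, `w_i = P_i . (X - M)`.
#'
#' @param model a `shape_model`.
#' @param coords 3V shape vector (same vertex count as the model).
#' @return numeric vector of scores, one per model component.
#' @export
project <- function(model, coords) {
  if (length(coords) != length(model$mean))
    stop("vertex count mismatch between shape and model")
  as.vector(model$components %*% (coords - model$mean))
}

#' Explained-variance report
#'
#' Per-component and cumulative fractions of total shape variance for the
#' first `k` components (the fractions are relative to the total variance
#' of the centered data, so the cumulative value reaches 1 at full rank).
#'
#' @param model a `shape_model`.
#' @param k number of leading components to report.
#' @return data frame with `pc`, `sd`, `fraction`, `cumulative`.
#' @export
explained_variance_report <- function(model, k = 6) {
  if (k > length(model$sds)) stop("k exceeds the number of components")
  fr <- model$explained_fraction[seq_len(k)]
  data.frame(pc = seq_len(k), sd = model$sds[seq_len(k)], fraction = fr,
             cumulative = cumsum(fr))
}

#' Save / load a shape model
#'
#' The model is stored as a small JSON metadata file plus raw little-endian
#' double arrays, so round-trips are numerically exact.
#'
#' @param model a `shape_model`.
#' @param dir directory to create/use.
#' @return `save_shape_model`: `dir`, invisibly. `read_shape_model`: the
#'   restored `shape_model`.
#' @export
save_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n_components = length(model$sds),
               n_coords = length(model$mean),
               n_shapes = nrow(model$scores),
               total_variance_hex = format_hex(model$total_variance),
               scan_ids = model$scan_ids)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE)
  writevec <- function(x, name) {
    con <- file(file.path(dir, name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  writevec(model$mean, "mean.bin")
  writevec(t(model$components), "components.bin")  # column-major by PC
  writevec(model$sds, "sds.bin")
  writevec(model$scores, "scores.bin")
  writevec(model$explained_fraction, "explained.bin")
  invisible(dir)
}

format_hex <- function(x) sprintf("%a", x)

#' @rdname save_shape_model
#' @export
read_shape_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  readvec <- function(name, n) {
    con <- file(file.path(dir, name), "rb")
    on.exit(close(con))
    readBin(con, "double", n = n, size = 8L, endian = "little")
  }
  k <- meta$n_components
  p <- meta$n_coords
  n <- meta$n_shapes
  structure(list(mean = readvec("mean.bin", p),
                 components = matrix(readvec("components.bin", k * p),
                                     nrow = k, byrow = TRUE),
                 sds = readvec("sds.bin", k),
                 scores = {
                   s <- matrix(readvec("scores.bin", n * k), nrow = n)
                   rownames(s) <- meta$scan_ids
                   s
                 },
                 explained_fraction = readvec("explained.bin", k),
                 total_variance = strtoi_hex(meta$total_variance_hex),
                 scan_ids = meta$scan_ids),
            class = "shape_model")
}

strtoi_hex <- function(s) as.numeric(s)
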