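## End-to-end study orchestration: simulate -> register (with reference
## updates) -> align -> shape model -> factor statistics -> reports.
##
## All stage outputs are written under one study directory together with a
## manifest (stage, parameters, files, content hashes); re-running with the
## same configuration and seed reproduces every CSV output bitwise.

#' Pipeline configuration
#'
#' @param generator a [generator_config()] describing the simulated cohort
#'   (or the cohort to load).
#' @param registration a [registration_params()].
#' @param reference_update_iters number of correspondence/alignment passes;
#'   after each pass the population mean becomes the new registration
#'   reference, removing reference bias (default 3).
#' @param n_pcs_to_report leading PCs for the explained-variance report,
#'   the PC-factor correlation table, and the exported component shapes.
#' @param alpha significance level for all tests.
#' @param use_true_correspondence skip registration and use the
#'   generator's ground-truth correspondence (for validation studies).
#' @param write_meshes export per-scan PLY meshes (off by default; the
#'   statistical outputs do not need them).
#' @param report_factors factors for which predicted-shape deviation maps
#'   are produced.
#' @param seed master seed; per-stage seeds are derived as `seed + stage
#'   offset` (documented in the manifest).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            registration = registration_params(),
                            reference_update_iters = 3,
                            n_pcs_to_report = 6,
                            alpha = 0.05,
                            use_true_correspondence = FALSE,
                            write_meshes = FALSE,
                            report_factors = "bmi",
                            seed = 1L) {
  structure(list(generator = generator, registration = registration,
                 reference_update_iters = as.integer(reference_update_iters),
                 n_pcs_to_report = as.integer(n_pcs_to_report),
                 alpha = alpha,
                 use_true_correspondence = isTRUE(use_true_correspondence),
                 write_meshes = isTRUE(write_meshes),
                 report_factors = report_factors,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The configuration round-trips losslessly (numbers are serialized at
#' full precision).
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path`, invisibly;
#'   `read_pipeline_config`: the restored [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gj <- j$generator
  em <- gj$effect_matrix
  if (is.list(em)) em <- do.call(rbind, lapply(em, unlist))
  gj$effect_matrix <- em
  gen <- do.call(generator_config, gj)
  reg <- do.call(registration_params, j$registration)
  pipeline_config(generator = gen, registration = reg,
                  reference_update_iters = j$reference_update_iters,
                  n_pcs_to_report = j$n_pcs_to_report,
                  alpha = j$alpha,
                  use_true_correspondence = j$use_true_correspondence,
                  write_meshes = j$write_meshes,
                  report_factors = j$report_factors,
                  seed = j$seed)
}

#' Export a simulated cohort to disk
#'
#' Writes the factor tables as CSV, the ground-truth mode weights as CSV
#' with a JSON sidecar describing the generator, and (optionally) each
#' scan mesh as binary PLY.
#'
#' @param cohort a `foot_cohort`.
#' @param dir output directory (created if needed).
#' @param meshes write per-scan PLY files.
#' @return character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, meshes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "subjects.csv")
  write.csv(cohort$subjects, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "factors.csv")
  write.csv(cohort$factors, p, row.names = FALSE)
  files <- c(files, p)
  wt <- do.call(rbind, lapply(cohort$scans, function(s) s$true_mode_weights))
  wt <- data.frame(scan_id = vapply(cohort$scans, `[[`, "", "scan_id"), wt)
  names(wt)[-1] <- paste0("mode", seq_len(ncol(wt) - 1))
  p <- file.path(dir, "true_mode_weights.csv")
  write.csv(wt, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "generator.json")
  jsonlite::write_json(unclass_deep(cohort$config), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p)
  if (meshes) {
    mdir <- file.path(dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    for (s in cohort$scans) {
      mp <- file.path(mdir, paste0(s$scan_id, ".ply"))
      write_mesh(s$mesh, mp)
      files <- c(files, mp)
    }
  }
  invisible(files)
}

pipeline_log <- function(state, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  if (state$verbose) message(msg)
  cat(msg, "\n", file = state$logfile, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> register (with `reference_update_iters` reference
#' updates) -> Procrustes alignment -> PCA shape model -> factor
#' regression (BIC forward selection, power), the asymmetry and loading
#' deviation analyses, and predicted-shape deviation reports, writing all
#' tables, shapes, and a hash manifest under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir study output directory.
#' @param verbose print progress messages.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `corresponded`, `aligned`, `model`, `selection`, `factor_model`,
#'   `correlations`, `asymmetry`, `loading`, `reports`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logfile = file.path(out_dir, "pipeline.log"),
                verbose = verbose)
  cat("", file = state$logfile)  # truncate
  manifest <- list()
  t_start <- Sys.time()
  add_stage <- function(name, params, files) {
    files <- files[file.exists(files)]
    manifest[[length(manifest) + 1L]] <<- list(
      stage = name, parameters = params,
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
  }
  fail <- function(stage, e) {
    tail_log <- utils::tail(readLines(state$logfile), 5)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "\nlast log lines:\n", paste(tail_log, collapse = "\n"),
         call. = FALSE)
  }

  # --- simulate -------------------------------------------------------------
  pipeline_log(state, "simulate: %d subjects (seed %d)",
               config$generator$n_subjects, config$generator$seed)
  gen <- config$generator
  gen$seed <- config$seed + 1L   # stage seed = master seed + stage offset
  cohort <- tryCatch(sample_cohort(gen), error = function(e)
    fail("simulate", e))
  cdir <- file.path(out_dir, "cohort")
  files <- write_cohort(cohort, cdir, meshes = config$write_meshes)
  add_stage("simulate", list(seed = gen$seed,
                             n_subjects = gen$n_subjects), files)

  # --- correspondence (with reference updates) ------------------------------
  V <- nrow(cohort$template$vertices)
  n_scans <- length(cohort$scans)
  shapes <- matrix(0, n_scans, 3 * V)
  rownames(shapes) <- vapply(cohort$scans, `[[`, "", "scan_id")
  residuals <- data.frame(scan_id = rownames(shapes),
                          mean_residual_mm = NA_real_,
                          p95_residual_mm = NA_real_, converged = NA)
  aligned <- NULL
  if (config$use_true_correspondence) {
    pipeline_log(state, "register: using ground-truth correspondence")
    for (i in seq_len(n_scans))
      shapes[i, ] <- coords_to_vec(cohort$scans[[i]]$gt_coords)
    residuals$mean_residual_mm <- 0
    residuals$p95_residual_mm <- 0
    residuals$converged <- TRUE
    aligned <- gpa(shapes, scan_ids = rownames(shapes))
  } else {
    reference <- cohort$template
    for (pass in seq_len(config$reference_update_iters)) {
      pipeline_log(state, "register: pass %d/%d", pass,
                   config$reference_update_iters)
      for (i in seq_len(n_scans)) {
        sc <- cohort$scans[[i]]
        mesh <- if (sc$side == 0) mirror_mesh(sc$mesh) else sc$mesh
        cs <- tryCatch(
          suppressWarnings(elastic_register(reference, mesh,
                                            config$registration,
                                            scan_id = sc$scan_id)),
          error = function(e) fail("register", e))
        shapes[i, ] <- coords_to_vec(cs$coords)
        residuals$mean_residual_mm[i] <- cs$residual
        residuals$p95_residual_mm[i] <- cs$p95_residual
        residuals$converged[i] <- cs$converged
        pipeline_log(state, "  %s residual %.3f mm (converged: %s)",
                     sc$scan_id, cs$residual, cs$converged)
      }
      aligned <- gpa(shapes, scan_ids = rownames(shapes))
      if (pass < config$reference_update_iters) {
        ref_coords <- vec_to_coords(aligned$mean_shape) *
          mean(aligned$centroid_sizes)
        reference <- trimesh(ref_coords, cohort$template$faces,
                             validate = FALSE)
      }
    }
  }
  rdir <- file.path(out_dir, "registration")
  dir.create(rdir, showWarnings = FALSE)
  rfile <- file.path(rdir, "residuals.csv")
  write.csv(residuals, rfile, row.names = FALSE)
  add_stage("register",
            list(reference_update_iters = config$reference_update_iters,
                 use_true_correspondence = config$use_true_correspondence),
            rfile)

  # --- alignment ------------------------------------------------------------
  pipeline_log(state, "align: %d shapes, objective %.4e", n_scans,
               aligned$objective_trace[length(aligned$objective_trace)])
  adir <- file.path(out_dir, "aligned")
  dir.create(adir, showWarnings = FALSE)
  sfile <- file.path(adir, "centroid_sizes.csv")
  write.csv(data.frame(scan_id = aligned$scan_ids,
                       centroid_size_mm = aligned$centroid_sizes),
            sfile, row.names = FALSE)
  bfile <- file.path(adir, "shapes.bin")
  con <- file(bfile, "wb")
  writeBin(as.numeric(aligned$shapes), con, size = 8L, endian = "little")
  close(con)
  add_stage("align", list(n = n_scans, v = V), c(sfile, bfile))

  # --- shape model ----------------------------------------------------------
  model <- tryCatch(fit_pca(aligned), error = function(e) fail("model", e))
  evr <- explained_variance_report(model,
                                   min(config$n_pcs_to_report,
                                       length(model$sds)))
  pipeline_log(state, "model: first %d PCs explain %.2f%% of variance",
               nrow(evr), 100 * evr$cumulative[nrow(evr)])
  mdir <- file.path(out_dir, "model")
  save_shape_model(model, mdir)
  efile <- file.path(mdir, "explained_variance.csv")
  write.csv(evr, efile, row.names = FALSE)
  scfile <- file.path(mdir, "scores.csv")
  sc_out <- data.frame(scan_id = model$scan_ids,
                       model$scores[, seq_len(min(config$n_pcs_to_report,
                                                  ncol(model$scores))),
                                    drop = FALSE])
  names(sc_out)[-1] <- paste0("pc", seq_len(ncol(sc_out) - 1))
  write.csv(sc_out, scfile, row.names = FALSE)
  size_mm <- mean(aligned$centroid_sizes)
  shape_files <- character(0)
  for (k in seq_len(min(config$n_pcs_to_report, length(model$sds)))) {
    for (s in c(-3, 3)) {
      w <- numeric(k)
      w[k] <- s
      shp <- vec_to_coords(synthesize(model, w, sigma_units = TRUE)) * size_mm
      fp <- file.path(mdir, sprintf("pc%d_%+dsd.ply", k, s))
      write_mesh(trimesh(shp, cohort$template$faces, validate = FALSE), fp)
      shape_files <- c(shape_files, fp)
    }
  }
  fp <- file.path(mdir, "mean_shape.ply")
  write_mesh(trimesh(vec_to_coords(model$mean) * size_mm,
                     cohort$template$faces, validate = FALSE), fp)
  shape_files <- c(shape_files, fp)
  add_stage("model", list(n_components = length(model$sds)),
            c(file.path(mdir, "model.json"), efile, scfile, shape_files))

  # --- factor regression ----------------------------------------------------
  Ft <- cohort_factor_table(cohort)
  sel <- tryCatch(forward_select_pcs(model$scores, Ft),
                  error = function(e) fail("regress", e))
  pipeline_log(state, "regress: selected %d PCs (%s)", length(sel),
               paste(sel, collapse = ", "))
  gdir <- file.path(out_dir, "regression")
  dir.create(gdir, showWarnings = FALSE)
  fm <- NULL
  t2file <- file.path(gdir, "factor_significance.csv")
  if (length(sel) > 0) {
    fm <- fit_factor_model(model$scores[, sel, drop = FALSE], Ft,
                           alpha = config$alpha, selected_pcs = sel)
    write.csv(data.frame(factor = fm$factor_names,
                         r_squared = fm$r_squared, p = fm$p_value,
                         power = fm$power, significant = fm$significant),
              t2file, row.names = FALSE)
  } else {
    write.csv(data.frame(factor = names(Ft), r_squared = NA, p = NA,
                         power = NA, significant = FALSE),
              t2file, row.names = FALSE)
  }
  k6 <- min(config$n_pcs_to_report, ncol(model$scores))
  corr <- pc_factor_correlations(model$scores[, seq_len(k6), drop = FALSE],
                                 Ft, alpha = config$alpha)
  t3file <- file.path(gdir, "pc_factor_correlations.csv")
  write.csv(corr, t3file, row.names = FALSE)
  selfile <- file.path(gdir, "selected_pcs.json")
  jsonlite::write_json(list(selected_pcs = as.integer(sel)), selfile)
  add_stage("regress", list(alpha = config$alpha), c(t2file, t3file, selfile))

  # --- asymmetry / loading deviation analyses -------------------------------
  dev_out <- list()
  ddir <- file.path(out_dir, "deviation")
  dir.create(ddir, showWarnings = FALSE)
  dev_files <- character(0)
  for (kind in c("asymmetry", "loading")) {
    res <- tryCatch(
      cohort_deviation_analysis(aligned, cohort, kind, alpha = config$alpha,
                                size_mm = size_mm),
      error = function(e) fail(paste0("deviation-", kind), e))
    dev_out[[kind]] <- res
    f1 <- file.path(ddir, paste0(kind, "_significance.csv"))
    if (!is.null(res$regression$model)) {
      m <- res$regression$model
      write.csv(data.frame(factor = m$factor_names, r_squared = m$r_squared,
                           p = m$p_value, power = m$power,
                           significant = m$significant),
                f1, row.names = FALSE)
    } else {
      write.csv(data.frame(factor = res$factor_names, r_squared = NA,
                           p = NA, power = NA, significant = FALSE),
                f1, row.names = FALSE)
    }
    f2 <- file.path(ddir, paste0("mean_", kind, "_field.ply"))
    write_mesh(trimesh(vec_to_coords(model$mean) * size_mm,
                       cohort$template$faces, validate = FALSE),
               f2, vertex_scalars = res$mean_field_mm)
    dev_files <- c(dev_files, f1, f2)
    pipeline_log(state, "deviation (%s): mean per-vertex %.3f mm", kind,
                 mean(res$mean_field_mm))
  }
  add_stage("deviation", list(), dev_files)

  # --- predicted-shape reports ----------------------------------------------
  reports <- list()
  rep_files <- character(0)
  if (!is.null(fm)) {
    pdir <- file.path(out_dir, "reports")
    dir.create(pdir, showWarnings = FALSE)
    for (fac in intersect(config$report_factors, fm$factor_names)) {
      pr <- predict_shape(fm, model, vary = fac)
      reports[[fac]] <- pr
      for (side in c("low", "high")) {
        shp <- vec_to_coords(pr[[paste0("shape_", side)]]) * size_mm
        fp <- file.path(pdir, sprintf("%s_%s.ply", fac, side))
        write_mesh(trimesh(shp, cohort$template$faces, validate = FALSE),
                   fp, vertex_scalars = pr$field * size_mm)
        rep_files <- c(rep_files, fp)
      }
      pipeline_log(state,
                   "report (%s): range [%.2f, %.2f], max deviation %.3f mm",
                   fac, pr$range[1], pr$range[2], max(pr$field) * size_mm)
    }
    add_stage("report", list(factors = config$report_factors), rep_files)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(created = "footmorph pipeline",
                            seed = config$seed,
                            seed_rule = "stage seed = master seed + offset",
                            elapsed_s = as.numeric(Sys.time() - t_start,
                                                   units = "secs"),
                            stages = manifest),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 8)
  pipeline_log(state, "done in %.1f s",
               as.numeric(Sys.time() - t_start, units = "secs"))
  invisible(list(cohort = cohort, aligned = aligned, model = model,
                 selection = sel, factor_model = fm, correlations = corr,
                 asymmetry = dev_out$asymmetry, loading = dev_out$loading,
                 reports = reports, residuals = residuals,
                 manifest_path = manifest_path))
}

#' Per-subject asymmetry or loading deviation analysis
#'
#' Builds the per-subject deviation fields from aligned shapes (asymmetry:
#' right vs mirrored-left foot at matched loading; loading: half vs full
#' loaded foot at matched side), averages the paired fields per subject,
#' and runs the PCA + regression of the fields on the remaining factors.
#'
#' @param aligned an `aligned_shapes` for the whole cohort.
#' @param cohort the `foot_cohort` the shapes came from.
#' @param kind `"asymmetry"` or `"loading"`.
#' @param alpha significance level.
#' @param size_mm scale (mean centroid size) used to express fields in mm.
#' @return list with `fields` (subjects x V, mm), `mean_field_mm`,
#'   `regression` (from [deviation_regression()]), `factor_names`.
#' @export
cohort_deviation_analysis <- function(aligned, cohort, kind, alpha = 0.05,
                                      size_mm = NULL) {
  stopifnot(kind %in% c("asymmetry", "loading"))
  if (is.null(size_mm)) size_mm <- mean(aligned$centroid_sizes)
  fct <- cohort$factors
  ids <- aligned$scan_ids
  subj <- cohort$subjects
  V <- length(aligned$mean_shape) / 3
  fields <- matrix(0, nrow(subj), V)
  for (i in seq_len(nrow(subj))) {
    sid <- subj$subject_id[i]
    rows <- which(fct$subject_id == sid)
    pairs <- if (kind == "asymmetry") {
      lapply(unique(fct$loading[rows]), function(ld)
        rows[fct$loading[rows] == ld])
    } else {
      lapply(unique(fct$side[rows]), function(sd_)
        rows[fct$side[rows] == sd_])
    }
    acc <- numeric(V)
    np <- 0
    for (p in pairs) {
      if (length(p) != 2) next
      ia <- match(fct$scan_id[p[1]], ids)
      ib <- match(fct$scan_id[p[2]], ids)
      acc <- acc + deviation_field(aligned$shapes[ia, ],
                                   aligned$shapes[ib, ], kind = kind)
      np <- np + 1
    }
    if (np == 0) stop("subject ", sid, " has no complete scan pair for ",
                      kind)
    fields[i, ] <- acc / np * size_mm
  }
  drop_cols <- if (kind == "asymmetry") "side" else "loading"
  keep <- setdiff(cohort_factor_names, c(drop_cols,
                                         if (kind == "asymmetry") "loading"
                                         else "side"))
  Fs <- subj[, intersect(keep, names(subj)), drop = FALSE]
  reg <- deviation_regression(fields, Fs, alpha = alpha)
  list(fields = fields, mean_field_mm = colMeans(fields),
       regression = reg, factor_names = names(Fs))
}
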