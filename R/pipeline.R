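#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Input is
#' either a simulation block (a [phantom_spec()], realised on the fly) or
#' paths to a 4D DWI NIfTI plus bval/bvec text files and a tissue-label
#' NIfTI. ROIs are rectangular slice blocks over the cortex, given as a list
#' of `list(region =, axis =, slices = c(from, to))`.
#'
#' @param out_dir Output directory (created if absent).
#' @param phantom Optional [phantom_spec()] for simulated input.
#' @param dwi,bval,bvec,labels Input file paths (ignored when `phantom` is
#'   given).
#' @param rois List of ROI blocks; `NULL` gives one whole-cortex ROI per
#'   axis-2 slice range (`region = "cortex"`).
#' @param subject Subject identifier for output rows.
#' @param tol,max_iter Laplace solver controls.
#' @param step Profile integration step in mm (default quarter voxel).
#' @param interpolation Metric sampling along profiles.
#' @param seed Seed forwarded to stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, phantom = NULL, dwi = NULL, bval = NULL,
                            bvec = NULL, labels = NULL, rois = NULL,
                            subject = "subject", tol = 1e-6, max_iter = 1e4,
                            step = NULL, interpolation = "nearest",
                            seed = 1L) {
  if (is.null(phantom)) {
    for (f in c(dwi = dwi, bval = bval, bvec = bvec, labels = labels)) {
      if (is.null(f)) stop("file-based runs need dwi, bval, bvec and labels paths",
                           call. = FALSE)
    }
    for (nm in c("dwi", "bval", "bvec", "labels")) {
      f <- get(nm)
      if (!file.exists(f))
        stop(sprintf("input '%s' not found: %s", nm, f), call. = FALSE)
    }
  } else stopifnot(inherits(phantom, "phantom_spec"))
  structure(list(out_dir = out_dir, phantom = phantom, dwi = dwi, bval = bval,
                 bvec = bvec, labels = labels, rois = rois, subject = subject,
                 tol = tol, max_iter = max_iter, step = step,
                 interpolation = interpolation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `phantom:` block is
#' passed to [phantom_spec()].
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    if (!is.null(ph$tangential_layer)) ph$tangential_layer <- as.numeric(ph$tangential_layer)
    if (!is.null(ph$snr) && identical(ph$snr, "inf")) ph$snr <- Inf
    cfg$phantom <- do.call(phantom_spec, ph)
  }
  cfg$out_dir <- out_dir %||% cfg$out_dir
  do.call(pipeline_config, cfg)
}

#' Run the cortical diffusivity pipeline
#'
#' Executes the full analysis in order: tensor fit, eigendecomposition,
#' cortical Laplace potential, radial field, profile tracing, voxel metric
#' maps, and ROI summaries. Each stage's outputs are written to `out_dir`
#' before the next stage begins: FA/MD/AngleR/ParlPD/PerpPD maps and the
#' potential as NIfTI, the tensor as a 6-volume NIfTI, profiles and ROI
#' metrics as CSV, plus a config snapshot and a run log recording package
#' version, seeds, solver iterations and per-stage counts. Reruns with an
#' identical configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the ROI metrics data.frame and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("cortexdti %s", as.character(packageVersion("cortexdti"))),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s: done", name))
    res
  }

  if (!is.null(config$phantom)) {
    sim <- stage("simulate", {
      ph <- make_phantom(config$phantom)
      scheme <- default_scheme()
      dwi <- synthesize_dwi(ph$tensors, scheme, s0 = 1000,
                            snr = config$phantom$snr, seed = config$seed)
      write_volume(ph$truth$labels, ph$tensors$affine,
                   file.path(config$out_dir, "labels.nii.gz"))
      write_scheme(scheme, file.path(config$out_dir, "dwi.bval"),
                   file.path(config$out_dir, "dwi.bvec"))
      list(dwi = dwi, labels = ph$truth$labels, affine = ph$tensors$affine,
           mask = ph$tensors$mask)
    })
    dwi <- sim$dwi; labels <- sim$labels; affine <- sim$affine
  } else {
    loaded <- stage("load", {
      vol <- read_volume(config$dwi)
      lab <- read_volume(config$labels)
      scheme <- read_scheme(config$bval, config$bvec)
      list(vol = vol, lab = lab, scheme = scheme)
    })
    labels <- as_label_array(array(as.integer(round(loaded$lab$data)),
                                   dim(loaded$lab$data)))
    affine <- loaded$vol$affine
    dwi <- structure(list(signal = loaded$vol$data, scheme = loaded$scheme,
                          affine = affine, mask = labels == LBL_CORTEX,
                          s0 = NA, snr = NA, seed = config$seed),
                     class = "dwi_volume")
  }

  tensors <- stage("fit", fit_tensor_loglinear(dwi))
  stage("write_tensor", write_volume(tensors$D, affine,
                                     file.path(config$out_dir, "tensor.nii.gz")))
  eig <- stage("eigen", eigendecompose(tensors))
  fa <- fa_map(eig); md <- md_map(eig)
  write_volume(fa$data, affine, file.path(config$out_dir, "fa.nii.gz"))
  write_volume(md$data, affine, file.path(config$out_dir, "md.nii.gz"))

  pot <- stage("potential", solve_cortical_potential(labels, affine,
                                                     tol = config$tol,
                                                     max_iter = config$max_iter))
  write_volume(pot$data, affine, file.path(config$out_dir, "potential.nii.gz"))
  log_lines <- c(log_lines, sprintf("laplace iterations: %d",
                                    attr(pot, "iterations")))
  field <- stage("field", radial_field(pot, labels))
  profs <- stage("profiles", trace_profiles(field, pot, labels,
                                            step = config$step))
  log_lines <- c(log_lines,
                 sprintf("profiles: %d kept, %d discarded, %d flagged seeds",
                         length(profs$profiles), profs$n_discarded,
                         profs$n_seeds_flagged))
  write.csv(profiles_to_df(profs), file.path(config$out_dir, "profiles.csv"),
            row.names = FALSE, quote = FALSE)

  metrics <- stage("metrics", compute_cortical_metrics(eig, field))
  for (nm in c("angleR", "parlPD", "perpPD"))
    write_volume(metrics[[nm]], affine,
                 file.path(config$out_dir, paste0(tolower(nm), ".nii.gz")))

  rois <- config$rois
  if (is.null(rois)) {
    rng <- range(which(apply(labels == LBL_CORTEX, 2, any)))
    rois <- list(list(region = "cortex", axis = 2L, slices = rng))
  }
  roi_rows <- stage("roi", {
    rows <- lapply(rois, function(r) {
      m <- array(FALSE, dim(labels))
      sl <- rep(FALSE, dim(labels)[r$axis])
      sl[seq.int(r$slices[1], r$slices[2])] <- TRUE
      m <- (labels == LBL_CORTEX) & slice_mask(dim(labels), r$axis, sl)
      roi <- roi_definition(m, r$region, axis = r$axis,
                            slice_range = r$slices)
      roi_summarize(metrics, profs, roi, subject = config$subject,
                    interpolation = config$interpolation)
    })
    do.call(rbind, rows)
  })
  roi_path <- file.path(config$out_dir, "roi_metrics.csv")
  write_metrics_csv(roi_rows, roi_path)

  snap <- config
  snap$phantom <- if (!is.null(config$phantom)) unclass(config$phantom) else NULL
  snap_path <- file.path(config$out_dir, "config_snapshot.yaml")
  yaml::write_yaml(lapply(unclass(snap), function(x)
    if (is.numeric(x) && any(is.infinite(x))) "inf" else x), snap_path)
  log_lines <- c(log_lines, sprintf("config md5: %s",
                                    unname(tools::md5sum(snap_path))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(roi_metrics = roi_rows,
                 paths = list(roi_metrics = roi_path, log = file.path(
                   config$out_dir, "run_log.txt"))))
}

slice_mask <- function(d, axis, keep) {
  a <- array(FALSE, d)
  idx <- which(keep)
  if (axis == 1L) a[idx, , ] <- TRUE
  if (axis == 2L) a[, idx, ] <- TRUE
  if (axis == 3L) a[, , idx] <- TRUE
  a
}

#' Cohort statistics from a long cohort table
#'
#' Convenience wrapper running the correlation screen
#' ([correlation_battery()]) and the split-plot repeated-measures ANOVA for
#' each diffusion metric, writing both as CSV.
#'
#' @param table Long cohort table (columns subject, group, region, measure,
#'   value).
#' @param out_dir Output directory.
#' @param metrics,histology Measure names passed to the screen.
#' @return Invisibly, list with `correlations` and `anova` data.frames.
#' @export
run_cohort_stats <- function(table, out_dir,
                             metrics = c("AngleR", "PerpPD", "ParlPD", "FA", "MD"),
                             histology = c("minicolumn_width", "neuropil_spacing",
                                           "core_width", "microsegment_number",
                                           "bundle_spacing", "bundle_width")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corr <- correlation_battery(table, metrics = metrics, histology = histology)
  an <- do.call(rbind, lapply(metrics, function(m) {
    res <- mixed_rm_anova(table, m)
    res$metric <- m
    res
  }))
  write_metrics_csv(corr, file.path(out_dir, "correlations.csv"))
  write_metrics_csv(an, file.path(out_dir, "anova.csv"))
  invisible(list(correlations = corr, anova = an))
}
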