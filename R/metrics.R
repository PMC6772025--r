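#' Radiality angle of a voxel
#'
#' Angle between the principal diffusion direction and the local radial
#' direction: `acos(|e1 . r|)`, in `[0, pi/2]` radians. Both the PDD and the
#' radial direction are axes rather than signed vectors, so the angle is
#' invariant to a sign flip of either input.
#'
#' @param e1 Unit vector (length 3) or n x 3 matrix of principal diffusion
#'   directions.
#' @param radial Unit vector or n x 3 matrix of radial directions.
#' @return Angle(s) in radians.
#' @examples
#' voxel_angleR(c(0, 0, 1), c(0, 0, 1))       # 0
#' voxel_angleR(c(1, 0, 0), c(0, 0, 1))       # pi/2
#' @export
voxel_angleR <- function(e1, radial) {
  e1 <- rbind_vec(e1); radial <- rbind_vec(radial)
  check_unit(e1, "e1"); check_unit(radial, "radial")
  acos(pmin(1, abs(rowSums(e1 * radial))))
}

rbind_vec <- function(v) if (is.matrix(v)) v else matrix(v, ncol = 3)

check_unit <- function(m, name) {
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop(sprintf("'%s' must contain unit vectors (tolerance 1e-6)", name),
         call. = FALSE)
  invisible(m)
}

#' Parallel and perpendicular projections of the principal diffusion component
#'
#' Projects the principal diffusion component (magnitude `lambda1` along the
#' PDD) onto the radial axis and onto the plane perpendicular to it: with
#' `theta = voxel_angleR(e1, radial)`, `parlPD = lambda1 * cos(theta)` and
#' `perpPD = lambda1 * sin(theta)`, so `parlPD^2 + perpPD^2 = lambda1^2`.
#' Voxels with negative `lambda1` are returned as NA (flagged for exclusion).
#'
#' @param lambda1 Largest eigenvalue(s), mm^2/s.
#' @param e1,radial Unit vectors or n x 3 matrices.
#' @return A matrix with columns `parlPD` and `perpPD`.
#' @export
voxel_projections <- function(lambda1, e1, radial) {
  theta <- voxel_angleR(e1, radial)
  out <- cbind(parlPD = lambda1 * cos(theta), perpPD = lambda1 * sin(theta))
  out[lambda1 < 0, ] <- NA_real_
  out
}

#' Voxel-wise cortical radiality metric maps
#'
#' Combines the eigensystem with the radial field to produce per-voxel maps
#' of AngleR, ParlPD, PerpPD, FA and MD over the cortex, together with an
#' exclusion flag. A voxel is flagged when its PDD is degenerate
#' (`lambda1 ~ lambda2`), its radial direction is unavailable, or its
#' leading eigenvalue is negative; flagged voxels are skipped by profile and
#' ROI averages.
#'
#' @param eig An [eigendecompose()] result.
#' @param field A [radial_field()].
#' @return A list of class `metric_maps`: 3D arrays `angleR` (radians),
#'   `parlPD`, `perpPD`, `md` (mm^2/s), `fa`, logical `flagged`, plus
#'   `affine` and `mask`.
#' @export
compute_cortical_metrics <- function(eig, field) {
  stopifnot(inherits(eig, "eigen_volume"), inherits(field, "radial_field"))
  d <- dim(eig$mask)
  mask <- eig$mask & field$mask
  idx <- which(mask)
  sub <- arrayInd(idx, d)
  e1 <- cbind(eig$vectors[cbind(sub, 1L, 1L)],
              eig$vectors[cbind(sub, 2L, 1L)],
              eig$vectors[cbind(sub, 3L, 1L)])
  rad <- cbind(field$vectors[cbind(sub, 1L)],
               field$vectors[cbind(sub, 2L)],
               field$vectors[cbind(sub, 3L)])
  l1 <- eig$values[cbind(sub, 1L)]
  flagged <- eig$pdd_degenerate[idx] | field$flagged[idx] |
    !is.finite(rowSums(rad)) | l1 < 0

  theta <- rep(NA_real_, length(idx))
  ok <- !flagged
  theta[ok] <- voxel_angleR(e1[ok, , drop = FALSE], rad[ok, , drop = FALSE])

  put <- function(vals) { a <- array(NA_real_, d); a[idx] <- vals; a }
  fa <- fa_map(eig); md <- md_map(eig)
  flag_arr <- array(FALSE, d); flag_arr[idx] <- flagged
  flag_arr[!mask] <- TRUE
  structure(list(angleR = put(theta),
                 parlPD = put(l1 * cos(theta)),
                 perpPD = put(l1 * sin(theta)),
                 fa = fa$data, md = md$data,
                 flagged = flag_arr, affine = eig$affine, mask = mask),
            class = "metric_maps")
}

#' Mean of a metric along a cortical profile
#'
#' Samples a voxel metric at each profile point (nearest voxel by default,
#' so each sample contributes the metric computed for that voxel; trilinear
#' optionally) and returns the arithmetic mean, skipping flagged voxels.
#' Returns NA when every sample is flagged, in which case the profile is
#' excluded from ROI summaries.
#'
#' @param metric 3D array of voxel values (NA allowed).
#' @param profile One element of [trace_profiles()]`$profiles`.
#' @param flagged Optional logical 3D array of voxels to skip.
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @return Scalar mean (NA if no usable samples).
#' @export
profile_mean <- function(metric, profile, flagged = NULL,
                         interpolation = c("nearest", "trilinear")) {
  interpolation <- match.arg(interpolation)
  pts <- profile$points
  if (nrow(pts) < 2L) return(NA_real_)
  d <- dim(metric)
  if (interpolation == "nearest") {
    lin <- nearest_voxel_index(d, pts)
    ok <- !is.na(lin)
    if (!is.null(flagged)) ok[ok] <- !flagged[lin[ok]]
    vals <- metric[lin[ok]]
  } else {
    m <- metric
    if (!is.null(flagged)) m[flagged] <- NA_real_
    vals <- trilinear(m, pts)
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Cortical ROI definition
#'
#' A region of interest inside the cortex, masked over a contiguous range of
#' slices along one axis (the acquisition convention masks ROIs over a block
#' of coronal slices). The terminal (first and last) slices of the range are
#' excluded from ROI averages to avoid partial coverage at the anterior and
#' posterior ends.
#'
#' @param mask Logical 3D array; must be non-empty and contained in the
#'   cortex label when `labels` is supplied.
#' @param region Region label, e.g. `"BA9"`, `"BA41"`, `"V1"`.
#' @param axis Slice axis (1, 2 or 3).
#' @param slice_range Optional integer range of slices; defaults to the
#'   slices actually covered by the mask.
#' @param labels Optional label volume used to validate containment.
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(mask, region, axis = 2L, slice_range = NULL,
                           labels = NULL) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  if (!is.null(labels)) {
    if (is.list(labels)) labels <- labels$labels
    if (any(mask & labels != LBL_CORTEX))
      stop("ROI mask extends outside the cortex label", call. = FALSE)
  }
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  covered <- which(apply(mask, axis, any))
  slice_range <- slice_range %||% range(covered)
  structure(list(mask = mask, region = as.character(region), axis = axis,
                 slice_range = as.integer(slice_range)),
            class = "roi_definition")
}

#' Summarise cortical metrics over an ROI
#'
#' Averages each metric first along every cortical profile ([profile_mean()])
#' and then over the profiles whose seed voxel lies inside the ROI mask,
#' excluding profiles seeded in the first or last slice of the ROI's slice
#' range. Diffusivities (MD, ParlPD, PerpPD) are reported in units of
#' 10^-3 mm^2/s; AngleR in radians.
#'
#' @param metrics A [compute_cortical_metrics()] result.
#' @param profiles A [trace_profiles()] result.
#' @param roi A [roi_definition()].
#' @param subject Subject identifier carried into the output row.
#' @param interpolation Passed to [profile_mean()].
#' @return One-row data.frame: `subject`, `region`, `angleR_rad`, `perpPD`,
#'   `parlPD`, `FA`, `MD`, `n_profiles`, `n_voxels`.
#' @export
roi_summarize <- function(metrics, profiles, roi, subject = "subject",
                          interpolation = "nearest") {
  stopifnot(inherits(metrics, "metric_maps"),
            inherits(profiles, "cortical_profiles"),
            inherits(roi, "roi_definition"))
  d <- dim(roi$mask)
  seeds <- t(vapply(profiles$profiles, `[[`, integer(3), "seed"))
  in_roi <- roi$mask[seeds]
  slice <- seeds[, roi$axis]
  terminal <- slice == roi$slice_range[1] | slice == roi$slice_range[2]
  use <- in_roi & !terminal
  if (!any(use))
    stop(sprintf("ROI '%s' has no usable profiles after terminal-slice exclusion",
                 roi$region), call. = FALSE)

  sel <- which(use)
  per_profile <- function(vol) vapply(sel, function(i)
    profile_mean(vol, profiles$profiles[[i]], metrics$flagged, interpolation),
    numeric(1))
  ang <- per_profile(metrics$angleR)
  perp <- per_profile(metrics$perpPD)
  parl <- per_profile(metrics$parlPD)
  fa <- per_profile(metrics$fa)
  md <- per_profile(metrics$md)
  ok <- is.finite(ang)
  if (!any(ok))
    stop(sprintf("ROI '%s' has no profiles with usable voxels", roi$region),
         call. = FALSE)

  # distinct unflagged voxels touched by the included profiles
  lins <- unique(unlist(lapply(sel[ok], function(i) {
    lin <- nearest_voxel_index(d, profiles$profiles[[i]]$points)
    lin[!is.na(lin)]
  })))
  lins <- lins[!metrics$flagged[lins]]

  data.frame(subject = subject, region = roi$region,
             angleR_rad = mean(ang[ok]),
             perpPD = 1e3 * mean(perp[ok], na.rm = TRUE),
             parlPD = 1e3 * mean(parl[ok], na.rm = TRUE),
             FA = mean(fa[ok], na.rm = TRUE),
             MD = 1e3 * mean(md[ok], na.rm = TRUE),
             n_profiles = sum(ok), n_voxels = length(lins),
             stringsAsFactors = FALSE)
}
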