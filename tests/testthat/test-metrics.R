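test_that("the radiality angle follows the axial angle definition", {
  expect_equal(voxel_angleR(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(voxel_angleR(c(1, 0, 0), c(0, 0, 1)), pi / 2)
  expect_equal(voxel_angleR(c(0, 0, -1), c(0, 0, 1)), 0)   # antipodal
  u <- c(1, 0, 1) / sqrt(2)
  expect_equal(voxel_angleR(u, c(0, 0, 1)), pi / 4, tolerance = 1e-12)
  expect_error(voxel_angleR(c(1, 1, 0), c(0, 0, 1)), "unit")
})

test_that("projections split lambda1 by the radiality angle", {
  expect_equal(unname(voxel_projections(1, c(0, 0, 1), c(0, 0, 1))[1, ]),
               c(1, 0))
  expect_equal(unname(voxel_projections(1, c(1, 0, 0), c(0, 0, 1))[1, ]),
               c(0, 1), tolerance = 1e-15)
  u <- c(sin(pi / 3), 0, cos(pi / 3))
  pr <- voxel_projections(0.8e-3, u, c(0, 0, 1))
  expect_equal(unname(pr[1, ]), c(0.4e-3, 0.8e-3 * sqrt(3) / 2),
               tolerance = 1e-15)
  expect_true(all(is.na(voxel_projections(-1, c(0, 0, 1), c(0, 0, 1)))))
})

test_that("parlPD^2 + perpPD^2 equals lambda1^2 voxel-wise on a phantom", {
  ph <- make_phantom(slab_spec(kappa = 4, seed = 6L))
  eig <- eigendecompose(ph$tensors)
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  met <- compute_cortical_metrics(eig, fld)
  idx <- which(met$mask & !met$flagged)
  d <- dim(met$mask)
  sub <- arrayInd(idx, d)
  l1 <- eig$values[cbind(sub, 1L)]
  expect_lt(max(abs(met$parlPD[idx]^2 + met$perpPD[idx]^2 - l1^2)), 1e-10)
  expect_true(all(met$angleR[idx] >= 0 & met$angleR[idx] <= pi / 2))
})

test_that("metric maps are bit-identical under antipodal flips", {
  ph <- make_phantom(slab_spec(kappa = 6, seed = 9L,
                               grid = c(16L, 16L, 16L), thickness = 5))
  eig <- eigendecompose(ph$tensors)
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  met0 <- compute_cortical_metrics(eig, fld)

  eig_f <- eig; eig_f$vectors[, , , , 1] <- -eig$vectors[, , , , 1]
  fld_f <- fld; fld_f$vectors <- -fld$vectors
  for (flip in list(list(eig_f, fld), list(eig, fld_f), list(eig_f, fld_f))) {
    met1 <- compute_cortical_metrics(flip[[1]], flip[[2]])
    expect_identical(met1$angleR, met0$angleR)
    expect_identical(met1$parlPD, met0$parlPD)
    expect_identical(met1$perpPD, met0$perpPD)
  }
})

test_that("PDD-degenerate voxels are excluded from the metric maps", {
  sp <- phantom_spec(grid_shape = c(12L, 12L, 14L), cortex_thickness = 4,
                     eigenvalues = c(0.5, 0.5, 0.2) * 1e-3,
                     dispersion_kappa = Inf)
  ph <- make_phantom(sp)
  eig <- eigendecompose(ph$tensors)
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  met <- compute_cortical_metrics(eig, fld)
  expect_true(all(met$flagged[met$mask]))
  expect_true(all(is.na(met$angleR[met$mask])))
})

test_that("profile means average the sampled voxels", {
  ph <- make_phantom(slab_spec())
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  prof <- trace_profiles(fld, pot, ph$truth$labels)
  const <- array(3.25, dim(ph$truth$labels))
  expect_equal(profile_mean(const, prof$profiles[[1]]), 3.25)
  # depth-fraction field averages to ~1/2 over a full-thickness profile
  m <- ph$truth$depth
  mn <- profile_mean(m, prof$profiles[[10]])
  expect_lt(abs(mn - 0.5), 0.1)
  # fully flagged profile yields NA
  allflag <- array(TRUE, dim(ph$truth$labels))
  expect_true(is.na(profile_mean(m, prof$profiles[[1]], flagged = allflag)))
})

test_that("ROI summaries exclude terminal slices and respect the mask", {
  ph <- make_phantom(slab_spec())
  eig <- eigendecompose(ph$tensors)
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  prof <- trace_profiles(fld, pot, ph$truth$labels)
  met <- compute_cortical_metrics(eig, fld)
  roi <- roi_definition(ph$tensors$mask, "cortex", axis = 2)
  base <- roi_summarize(met, prof, roi, subject = "p1")
  expect_identical(base$region, "cortex")
  expect_true(base$n_profiles >= 1)

  # corrupting the metric in the terminal slices does not change the summary
  met2 <- met
  rng <- roi$slice_range
  met2$angleR[, c(rng[1], rng[2]), ] <- pi / 2
  out <- roi_summarize(met2, prof, roi, subject = "p1")
  expect_identical(out$angleR_rad, base$angleR_rad)

  # identical per-profile values pass through unchanged
  const <- base
  met3 <- met
  met3$angleR[ph$tensors$mask] <- 0.123
  out3 <- roi_summarize(met3, prof, roi, subject = "p1")
  expect_equal(out3$angleR_rad, 0.123, tolerance = 1e-12)

  # an ROI covering only the two terminal slices errors by name
  m <- array(FALSE, dim(ph$tensors$mask))
  m[, rng[1]:(rng[1] + 1), ] <- ph$tensors$mask[, rng[1]:(rng[1] + 1), ]
  roi_term <- roi_definition(m, "edge", axis = 2)
  expect_error(roi_summarize(met, prof, roi_term), "edge")
})

test_that("zero-dispersion noiseless slab yields near-zero ROI AngleR end to end", {
  ph <- make_phantom(slab_spec(kappa = Inf, snr = Inf))
  dwi <- synthesize_dwi(ph$tensors, default_scheme(), snr = Inf)
  fit <- fit_tensor_loglinear(dwi)
  eig <- eigendecompose(fit)
  pot <- solve_cortical_potential(ph$truth$labels)
  fld <- radial_field(pot, ph$truth$labels)
  prof <- trace_profiles(fld, pot, ph$truth$labels)
  met <- compute_cortical_metrics(eig, fld)
  roi <- roi_definition(ph$tensors$mask, "cortex", axis = 2)
  out <- roi_summarize(met, prof, roi, subject = "phantom")
  expect_lt(out$angleR_rad, 0.02)
  expect_equal(out$MD, 0.4, tolerance = 1e-6)       # 10^-3 mm^2/s units
  expect_equal(out$parlPD, 0.8, tolerance = 1e-3)
})

test_that("ROI mean AngleR is monotone in the dispersion level", {
  kappas <- c(Inf, 40, 15, 5, 0)
  means <- vapply(kappas, function(k) {
    ph <- make_phantom(slab_spec(kappa = k, seed = 17L,
                                 grid = c(20L, 20L, 18L), thickness = 7))
    eig <- eigendecompose(ph$tensors)
    pot <- solve_cortical_potential(ph$truth$labels)
    fld <- radial_field(pot, ph$truth$labels)
    prof <- trace_profiles(fld, pot, ph$truth$labels)
    met <- compute_cortical_metrics(eig, fld)
    roi <- roi_definition(ph$tensors$mask, "cortex", axis = 2)
    roi_summarize(met, prof, roi)$angleR_rad
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a 90-degree grid rotation leaves ROI AngleR unchanged", {
  # rotate the slab from the z axis onto the x axis: permute array axes and
  # remap tensor components accordingly, then rerun the geometry stages
  ph <- make_phantom(slab_spec(kappa = 8, seed = 4L,
                               grid = c(16L, 16L, 16L), thickness = 6))
  summarize <- function(tensors, labels, axis) {
    eig <- eigendecompose(tensors)
    pot <- solve_cortical_potential(labels)
    fld <- radial_field(pot, labels)
    prof <- trace_profiles(fld, pot, labels)
    met <- compute_cortical_metrics(eig, fld)
    roi <- roi_definition(tensors$mask, "cortex", axis = axis)
    roi_summarize(met, prof, roi)
  }
  base <- summarize(ph$tensors, ph$truth$labels, axis = 2)

  # axis swap (x, y, z) -> (z, y, x): Dxx<->Dzz, Dxy<->Dyz, Dxz fixed
  ap <- function(a) aperm(a, c(3, 2, 1))
  Dn <- array(NA_real_, c(dim(ph$tensors$D)[c(3, 2, 1)], 6))
  Dn[, , , 1] <- ap(ph$tensors$D[, , , 6])  # Dxx' = Dzz
  Dn[, , , 2] <- ap(ph$tensors$D[, , , 5])  # Dxy' = Dzy
  Dn[, , , 3] <- ap(ph$tensors$D[, , , 3])  # Dxz' = Dzx
  Dn[, , , 4] <- ap(ph$tensors$D[, , , 4])  # Dyy' = Dyy
  Dn[, , , 5] <- ap(ph$tensors$D[, , , 2])  # Dyz' = Dyx
  Dn[, , , 6] <- ap(ph$tensors$D[, , , 1])  # Dzz' = Dxx
  tens_rot <- tensor_volume(Dn, affine = ph$tensors$affine,
                            mask = ap(ph$tensors$mask))
  rot <- summarize(tens_rot, ap(ph$truth$labels), axis = 2)
  expect_lt(abs(rot$angleR_rad - base$angleR_rad), 0.02)
  expect_equal(rot$MD, base$MD, tolerance = 1e-9)
})
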