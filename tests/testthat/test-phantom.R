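test_that("phantom specification rejects degenerate inputs", {
  expect_error(phantom_spec(cortex_thickness = 2), "at least 3 voxels")
  expect_error(phantom_spec(eigenvalues = c(0.2, 0.8, 0.2) * 1e-3),
               "non-increasing")
  expect_error(phantom_spec(eigenvalues = c(0.8, 0.2, 0) * 1e-3), "positive")
  expect_error(phantom_spec(tangential_layer = c(0.5, 0.4)), "interval")
  expect_error(phantom_spec(dispersion_kappa = -1), "non-negative")
})

test_that("zero-dispersion slab has radially aligned axes and zero AngleR", {
  ph <- make_phantom(slab_spec(kappa = Inf))
  idx <- which(ph$tensors$mask)
  ori <- pick_vec(ph$truth$orientation_field, idx)
  rad <- pick_vec(ph$truth$radial_truth, idx)
  expect_equal(ori, rad)
  expect_true(all(abs(ori[, 3]) == 1))
  expect_true(all(ph$truth$expected_angleR[idx] == 0))
})

test_that("uniform axes give mean AngleR of 1 radian", {
  # closed form: E[acos(|c|)] with |c| uniform on [0, 1] is 1 exactly;
  # Monte-Carlo check of the sampler against that and against the
  # quadrature in watson_mean_angle()
  ph <- make_phantom(phantom_spec(grid_shape = c(36L, 36L, 24L),
                                  cortex_thickness = 10,
                                  dispersion_kappa = 0, seed = 11L))
  ang <- ph$truth$expected_angleR[ph$tensors$mask]
  expect_gt(length(ang), 1e4)
  expect_lt(abs(mean(ang) - 1), 0.03)
  expect_equal(watson_mean_angle(0), 1, tolerance = 1e-8)
})

test_that("Watson sampler matches the quadrature mean angle across kappa", {
  ph <- function(k, seed) make_phantom(phantom_spec(
    grid_shape = c(32L, 32L, 20L), cortex_thickness = 10,
    dispersion_kappa = k, seed = seed))
  for (k in c(2, 10, 40)) {
    p <- ph(k, seed = 100 + k)
    mc <- mean(p$truth$expected_angleR[p$tensors$mask])
    expect_lt(abs(mc - watson_mean_angle(k)), 0.03)
  }
  # monotone: more concentration, smaller mean angle
  m <- vapply(c(0, 2, 5, 10, 40, Inf), watson_mean_angle, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("tangential layer voxels are exactly perpendicular to radial", {
  sp <- phantom_spec(grid_shape = c(20L, 20L, 24L), cortex_thickness = 10,
                     dispersion_kappa = Inf,
                     tangential_layer = c(0.45, 0.55))
  ph <- make_phantom(sp)
  idx <- which(ph$tensors$mask)
  depth <- ph$truth$depth[idx]
  in_band <- depth >= 0.45 & depth <= 0.55
  expect_true(any(in_band))
  ang <- ph$truth$expected_angleR[idx]
  expect_equal(ang[in_band], rep(pi / 2, sum(in_band)))
  expect_true(all(ang[!in_band] == 0))
})

test_that("phantom generation is deterministic in the seed", {
  a <- make_phantom(slab_spec(kappa = 5, seed = 42L))
  b <- make_phantom(slab_spec(kappa = 5, seed = 42L))
  c <- make_phantom(slab_spec(kappa = 5, seed = 43L))
  expect_identical(a$tensors$D, b$tensors$D)
  expect_false(identical(a$tensors$D, c$tensors$D))
})

test_that("DWI synthesis follows the single-tensor signal model", {
  d <- 0.3e-3
  tv <- uniform_tensor_volume(diag(rep(d, 3)))
  sch <- default_scheme()
  dwi <- synthesize_dwi(tv, sch, s0 = 1000, snr = Inf)
  idx <- which(tv$mask)
  b0 <- dwi$signal[, , , which(sch$bvals == 0)[1]]
  expect_equal(b0[idx], rep(1000, length(idx)))
  dwvols <- which(sch$bvals > 0)
  for (k in dwvols[c(1, 20, 54)])
    expect_equal(dwi$signal[, , , k][idx],
                 rep(1000 * exp(-4500 * d), length(idx)), tolerance = 1e-12)
})

test_that("prolate tensor attenuates by lambda1 along the axis and lambda3 across", {
  lam <- c(0.8, 0.2, 0.2) * 1e-3
  tv <- uniform_tensor_volume(diag(lam))
  sch <- acquisition_scheme(
    c(0, rep(4500, 7)),
    cbind(0, diag(3), normalize_mat(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1, 1, 1, 1), 3))))
  dwi <- synthesize_dwi(tv, sch, s0 = 100, snr = Inf)
  i1 <- which(tv$mask)[1]
  along <- dwi$signal[, , , 2][i1]   # gradient = x = principal axis
  across <- dwi$signal[, , , 4][i1]  # gradient = z
  expect_equal(along, 100 * exp(-4500 * lam[1]), tolerance = 1e-12)
  expect_equal(across, 100 * exp(-4500 * lam[3]), tolerance = 1e-12)
  expect_error(synthesize_dwi(tv, sch, s0 = 0), "positive")
})

test_that("Rician noise is seed-reproducible and has the requested scale", {
  tv <- uniform_tensor_volume(diag(rep(0.3e-3, 3)), grid = c(8L, 8L, 8L))
  sch <- default_scheme()
  a <- synthesize_dwi(tv, sch, s0 = 1000, snr = 50, seed = 9L)
  b <- synthesize_dwi(tv, sch, s0 = 1000, snr = 50, seed = 9L)
  c <- synthesize_dwi(tv, sch, s0 = 1000, snr = 50, seed = 10L)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
  # b = 0 magnitude noise: sd of the Rician at high SNR ~ s0/snr = 20
  b0 <- a$signal[, , , 1][tv$mask]
  expect_lt(abs(sd(b0) - 20) / 20, 0.25)
})

test_that("noise-free histology link gives a perfect Spearman correlation", {
  hm <- default_histology_model()
  for (m in names(hm)) hm[[m]]$noise_sd <- 0
  co <- make_cohort(cohort_spec(histology_model = hm, seed = 3L))
  wide <- co$table[co$table$region == "BA9" &
                     co$table$measure == "minicolumn_width", ]
  wide <- wide[match(co$subjects$subject, wide$subject), ]
  sc <- spearman_cor(co$subjects$kappa, wide$value)
  expect_equal(abs(sc$r), 1)
  expect_equal(sc$p, 0)
})

test_that("disjoint group dispersion models separate the groups", {
  co <- make_cohort(cohort_spec(
    dispersion_model = list(case = list(mean = 5, sd = 0.1),
                            control = list(mean = 30, sd = 0.1)),
    seed = 2L))
  k_case <- co$subjects$kappa[co$subjects$group == "case"]
  k_ctrl <- co$subjects$kappa[co$subjects$group == "control"]
  expect_true(max(k_case) < min(k_ctrl))
  expect_true(all(vapply(co$phantom_specs, inherits, logical(1), "phantom_spec")))
})

test_that("planted Spearman correlation is recovered from the linear link", {
  # Monte-Carlo oracle over 200 replicates of the generative model used by
  # make_cohort: y = a + b * kappa + noise, noise sd calibrated for rho 0.7
  slope <- -0.55; sd_x <- 4
  nsd <- noise_sd_for_spearman(slope, sd_x, -0.7)
  rs <- with_seed_test(77, replicate(200, {
    x <- rnorm(100, 15, sd_x)
    y <- 40 + slope * x + rnorm(100, 0, nsd)
    spearman_cor(x, y)$r
  }))
  expect_lt(abs(mean(rs) - (-0.7)), 0.15)
})
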