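# Shared fixture builders; everything is generated in code at test time.

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)

normalize_mat <- function(g) sweep(g, 2, sqrt(colSums(g^2)), `/`)

iso_affine_test <- function(dim3, voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- -voxel_size * (dim3 - 1) / 2
  a
}

slab_spec <- function(kappa = Inf, snr = Inf, seed = 1L,
                      grid = c(24L, 24L, 20L), thickness = 8) {
  phantom_spec(geometry = "flat_slab", grid_shape = grid,
               cortex_thickness = thickness, dispersion_kappa = kappa,
               snr = snr, seed = seed)
}

annulus_spec <- function(kappa = Inf, snr = Inf, seed = 1L) {
  phantom_spec(geometry = "spherical_annulus", grid_shape = c(48L, 48L, 48L),
               cortex_thickness = 10, dispersion_kappa = kappa, snr = snr,
               seed = seed)
}

# A single-tensor volume replicated over a small grid, for fit oracles.
uniform_tensor_volume <- function(D, grid = c(4L, 4L, 4L)) {
  d6 <- c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  arr <- array(rep(d6, each = prod(grid)), c(grid, 6L))
  tensor_volume(arr, affine = diag(4), mask = array(TRUE, grid))
}

random_rotation <- function(seed = NULL) {
  m <- if (is.null(seed)) matrix(rnorm(9), 3) else
    withr::with_seed(seed, matrix(rnorm(9), 3))
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random symmetric positive-definite tensor on the diffusivity scale.
random_spd_tensor <- function() {
  lam <- sort(runif(3, 0.1, 1.5), decreasing = TRUE) * 1e-3
  R <- random_rotation()
  R %*% diag(lam) %*% t(R)
}

# Cortex linear indices, voxel radii and analytic potential for the annulus.
annulus_truth <- function(ph) {
  lab <- ph$truth$labels
  d <- dim(lab)
  ctr <- (d - 1) / 2
  idx <- which(lab == tissue_labels()["cortex"])
  sub <- arrayInd(idx, d)
  r <- sqrt(rowSums(sweep(sub - 1, 2, ctr)^2))
  a <- ph$truth$annulus_radii[["inner"]]
  b <- ph$truth$annulus_radii[["outer"]]
  list(idx = idx, sub = sub, r = r, a = a, b = b,
       phi = (1 / a - 1 / r) / (1 / a - 1 / b),
       interior = r >= a + 2 & r <= b - 2)
}

pick_vec <- function(vol4, idx) {
  d <- dim(vol4)[1:3]
  plane <- prod(d)
  cbind(vol4[idx], vol4[idx + plane], vol4[idx + 2 * plane])
}

# Long cohort table with independent values for every diffusion metric and
# histology measure (null association), n subjects, 3 regions.
null_cohort_table <- function(n = 9) {
  metrics <- c("AngleR", "PerpPD", "ParlPD", "FA", "MD")
  histology <- c("minicolumn_width", "neuropil_spacing", "core_width",
                 "microsegment_number", "bundle_spacing", "bundle_width")
  cells <- expand.grid(subject = sprintf("S%02d", seq_len(n)),
                       region = c("BA9", "BA41", "V1"),
                       measure = c(metrics, histology),
                       stringsAsFactors = FALSE)
  cells$group <- "case"
  cells$value <- rnorm(nrow(cells))
  cells
}
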