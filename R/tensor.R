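#' Tensor volume container
#'
#' A per-voxel symmetric diffusion tensor field. Components are stored as a
#' 4D array whose last dimension holds the six unique elements in the fixed
#' order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), in mm^2/s. The same order is used in
#' all files written by the package.
#'
#' @param data 4D numeric array, last dimension of length 6.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param mask Logical 3D array marking voxels with valid tensors.
#' @param qc Optional integer 3D array of QC flags (0 = clean); bit 1 marks
#'   voxels whose signal was clamped before the log-linear fit, bit 2 marks
#'   non-positive-definite fitted tensors.
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(data, affine, mask, qc = NULL) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == 6L)
  mask <- array(as.logical(mask), dim(data)[1:3])
  if (is.null(qc)) qc <- array(0L, dim(data)[1:3])
  structure(list(D = data, affine = affine, mask = mask, qc = qc),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("tensor_volume: %dx%dx%d, %d voxels in mask, %d flagged\n",
              d[1], d[2], d[3], sum(x$mask), sum(x$qc != 0 & x$mask)))
  invisible(x)
}

# Extract an n x 6 component matrix at linear voxel indices.
tensor_components <- function(tv, idx) {
  plane <- prod(dim(tv$D)[1:3])
  out <- vapply(1:6, function(k) tv$D[idx + (k - 1L) * plane],
                numeric(length(idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

# Design matrix of the log-linear tensor model: per volume,
# log S = log S0 - b g' D g, linear in (log S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[1, ]^2, -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -b * g[2, ]^2, -2 * b * g[2, ] * g[3, ], -b * g[3, ]^2)
}

#' Log-linear least-squares tensor fit
#'
#' Fits the diffusion tensor per voxel by ordinary least squares on the
#' log signal: `log S = log S0 - b g' D g`, solving for the seven unknowns
#' (log S0 and the six tensor components). The fit is deterministic and
#' recovers noiseless single-tensor signals exactly.
#'
#' Non-positive or zero diffusion-weighted signals are floored at
#' `clamp_eps` times the voxel's mean b = 0 signal before taking the log;
#' affected voxels are flagged in the QC volume (bit 1) and should be
#' excluded from downstream averages. Fitted tensors that are not positive
#' definite are retained but flagged (bit 2) rather than repaired.
#'
#' @param dwi A `dwi_volume` from [synthesize_dwi()], or a 4D signal array.
#' @param scheme An [acquisition_scheme()]; defaulted from `dwi` when absent.
#' @param mask Logical 3D array of voxels to fit; defaulted from `dwi`.
#' @param affine Voxel-to-world matrix; defaulted from `dwi`.
#' @param clamp_eps Signal floor as a fraction of the voxel b = 0 signal.
#' @return A [tensor_volume()] with QC flags.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(12, 12, 12), cortex_thickness = 4))
#' dwi <- synthesize_dwi(ph$tensors, default_scheme(), snr = Inf)
#' fit <- fit_tensor_loglinear(dwi)
#' max(abs(fit$D - ph$tensors$D), na.rm = TRUE)
#' @export
fit_tensor_loglinear <- function(dwi, scheme = NULL, mask = NULL,
                                 affine = NULL, clamp_eps = 1e-6) {
  if (inherits(dwi, "dwi_volume")) {
    scheme <- scheme %||% dwi$scheme
    mask <- mask %||% dwi$mask
    affine <- affine %||% dwi$affine
    signal <- dwi$signal
  } else signal <- dwi
  stopifnot(inherits(scheme, "acquisition_scheme"), length(dim(signal)) == 4L)
  if (dim(signal)[4] != length(scheme$bvals))
    stop("signal volume count does not match the scheme", call. = FALSE)
  if (length(scheme$bvals) < 7L)
    stop("at least 7 volumes (>= 1 b = 0) are required", call. = FALSE)
  d <- dim(signal)[1:3]
  mask <- if (is.null(mask)) array(TRUE, d) else array(as.logical(mask), d)
  affine <- affine %||% iso_affine(d, 1)

  X <- tensor_design(scheme)
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("singular design matrix: the scheme's gradient directions are collinear or too few",
         call. = FALSE)

  idx <- which(mask)
  nvol <- length(scheme$bvals)
  plane <- prod(d)
  S <- vapply(seq_len(nvol), function(k) signal[idx + (k - 1L) * plane],
              numeric(length(idx)))
  s0_vox <- rowMeans(S[, scheme$bvals == 0, drop = FALSE])
  if (any(!is.finite(s0_vox)) || any(s0_vox <= 0))
    stop("non-positive b = 0 signal inside the mask", call. = FALSE)
  floor_vals <- clamp_eps * s0_vox
  clamped <- S < floor_vals
  S <- pmax(S, floor_vals)

  beta <- t(qr.coef(qrX, t(log(S))))    # nvox x 7
  tens <- array(NA_real_, c(d, 6L))
  for (k in 1:6) tens[idx + (k - 1L) * plane] <- beta[, k + 1L]

  qc <- array(0L, d)
  qc[idx[rowSums(clamped) > 0]] <- 1L
  ev <- eig3_sym(beta[, 2:7, drop = FALSE])
  nonspd <- ev$values[, 3] <= 0
  qc[idx[nonspd]] <- bitwOr(qc[idx[nonspd]], 2L)
  tensor_volume(tens, affine = affine, mask = mask, qc = qc)
}

#' Eigendecomposition of a tensor volume
#'
#' Per-voxel sorted eigensystem of the symmetric diffusion tensor. The first
#' eigenvector `e1` is the principal diffusion direction (PDD), defined only
#' up to sign; the deterministic convention makes the first component of
#' magnitude above 1e-12 non-negative. Voxels where the two leading
#' eigenvalues coincide to within a relative 1e-6 have an undefined PDD and
#' are flagged `pdd_degenerate`; voxels with a non-positive smallest
#' eigenvalue are flagged `nonspd`. Eigenvalues are never clipped.
#'
#' @param tensors A [tensor_volume()].
#' @return An object of class `eigen_volume`: `values` (4D, last dim 3,
#'   descending), `vectors` (5D, dims x 3 components x 3 eigenvectors),
#'   `mask`, `affine`, and logical flag arrays `pdd_degenerate` and `nonspd`.
#' @export
eigendecompose <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  d <- dim(tensors$D)[1:3]
  idx <- which(tensors$mask)
  d6 <- tensor_components(tensors, idx)
  bad <- !is.finite(rowSums(d6))
  if (any(bad)) {
    vox <- arrayInd(idx[which(bad)[1]], d)
    stop(sprintf("non-finite tensor inside mask at voxel (%d, %d, %d)",
                 vox[1], vox[2], vox[3]), call. = FALSE)
  }
  ev <- eig3_sym(d6)
  plane <- prod(d)
  values <- array(NA_real_, c(d, 3L))
  vectors <- array(NA_real_, c(d, 3L, 3L))
  for (k in 1:3) values[idx + (k - 1L) * plane] <- ev$values[, k]
  for (j in 1:3) for (k in 1:3)
    vectors[idx + ((k - 1L) + (j - 1L) * 3L) * plane] <- ev$vectors[, (j - 1L) * 3L + k]

  scale <- pmax(abs(ev$values[, 1]), .Machine$double.eps)
  degen <- (ev$values[, 1] - ev$values[, 2]) <= 1e-6 * scale
  nonspd <- ev$values[, 3] <= 0
  fdeg <- array(FALSE, d); fdeg[idx] <- degen
  fspd <- array(FALSE, d); fspd[idx] <- nonspd
  structure(list(values = values, vectors = vectors, mask = tensors$mask,
                 affine = tensors$affine, pdd_degenerate = fdeg, nonspd = fspd),
            class = "eigen_volume")
}

#' @export
print.eigen_volume <- function(x, ...) {
  cat(sprintf("eigen_volume: %d voxels, %d PDD-degenerate, %d non-SPD\n",
              sum(x$mask), sum(x$pdd_degenerate), sum(x$nonspd)))
  invisible(x)
}

#' Scalar maps from the eigensystem
#'
#' `fa_map()` computes fractional anisotropy,
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, defined as 0
#' for an all-zero tensor. `md_map()` computes mean diffusivity
#' `(lambda1 + lambda2 + lambda3) / 3` in mm^2/s.
#'
#' @param eig An `eigen_volume` from [eigendecompose()].
#' @return A `scalar_volume`: list of `data` (3D array, NA outside mask),
#'   `affine`, `mask`.
#' @export
fa_map <- function(eig) {
  stopifnot(inherits(eig, "eigen_volume"))
  d <- dim(eig$mask)
  lam <- lambda_arrays(eig)
  mb <- (lam[[1]] + lam[[2]] + lam[[3]]) / 3
  num <- sqrt((lam[[1]] - mb)^2 + (lam[[2]] - mb)^2 + (lam[[3]] - mb)^2)
  den <- sqrt(lam[[1]]^2 + lam[[2]]^2 + lam[[3]]^2)
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- 0
  fa[!eig$mask] <- NA_real_
  scalar_volume(array(fa, d), eig$affine, eig$mask)
}

lambda_arrays <- function(eig) {
  d <- dim(eig$mask)
  plane <- prod(d)
  lapply(1:3, function(k)
    array(eig$values[seq_len(plane) + (k - 1L) * plane], d))
}

#' @rdname fa_map
#' @export
md_map <- function(eig) {
  stopifnot(inherits(eig, "eigen_volume"))
  lam <- lambda_arrays(eig)
  md <- (lam[[1]] + lam[[2]] + lam[[3]]) / 3
  md[!eig$mask] <- NA_real_
  scalar_volume(array(md, dim(eig$mask)), eig$affine, eig$mask)
}

#' @rdname fa_map
#' @param data 3D numeric array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param mask Logical 3D array.
#' @export
scalar_volume <- function(data, affine, mask) {
  structure(list(data = data, affine = affine,
                 mask = array(as.logical(mask), dim(data))),
            class = "scalar_volume")
}
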