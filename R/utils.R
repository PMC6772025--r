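# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state. All stochastic operations in the package route through
# this, so seeds are explicit arguments rather than ambient state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) && !is.infinite(x))
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# Row-wise Euclidean normalisation of an n x 3 matrix.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}

# Deterministic orthonormal completion: for each unit row of `u` return two
# unit rows v, w with {u, v, w} orthonormal. The helper axis is the coordinate
# axis least aligned with u, which makes the completion continuous almost
# everywhere and reproducible.
orthonormal_complement <- function(u) {
  n <- nrow(u)
  pick <- max.col(-abs(u))          # least-aligned coordinate axis
  e <- matrix(0, n, 3)
  e[cbind(seq_len(n), pick)] <- 1
  v <- e - u * rowSums(e * u)
  v <- normalize_rows(v)
  w <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  list(v = v, w = w)
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates (n x 3 matrix). NA corners are dropped and the remaining corner
# weights renormalised; rows whose corners are all NA return NA.
trilinear <- function(vol, pts) {
  d <- dim(vol)
  p <- pmin(pmax(pts, 0), matrix(rep(d - 1L, each = nrow(pts)), ncol = 3))
  f <- floor(p)
  fr <- p - f
  i0 <- f + 1L                       # to 1-based
  i1 <- pmin(f + 2L, matrix(rep(d, each = nrow(pts)), ncol = 3))
  acc <- numeric(nrow(pts))
  wsum <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- if (dx == 0) i0[, 1] else i1[, 1]
    iy <- if (dy == 0) i0[, 2] else i1[, 2]
    iz <- if (dz == 0) i0[, 3] else i1[, 3]
    w <- (if (dx == 0) 1 - fr[, 1] else fr[, 1]) *
         (if (dy == 0) 1 - fr[, 2] else fr[, 2]) *
         (if (dz == 0) 1 - fr[, 3] else fr[, 3])
    v <- vol[cbind(ix, iy, iz)]
    ok <- !is.na(v) & w > 0
    acc[ok] <- acc[ok] + w[ok] * v[ok]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  out <- acc / wsum
  out[wsum == 0] <- NA_real_
  out
}

# Nearest-voxel lookup at continuous 0-based coordinates; returns NA outside
# the array.
nearest_voxel_index <- function(dim3, pts) {
  idx <- round(pts) + 1L
  ok <- idx[, 1] >= 1L & idx[, 1] <= dim3[1] &
        idx[, 2] >= 1L & idx[, 2] <= dim3[2] &
        idx[, 3] >= 1L & idx[, 3] <= dim3[3]
  lin <- rep(NA_integer_, nrow(pts))
  lin[ok] <- idx[ok, 1] + dim3[1] * (idx[ok, 2] - 1L) +
    dim3[1] * dim3[2] * (idx[ok, 3] - 1L)
  lin
}

# Default RAS-positive affine for an isotropic grid centred on the origin.
iso_affine <- function(dim3, voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- -voxel_size * (dim3 - 1) / 2
  a
}

voxel_size_from_affine <- function(affine) {
  sz <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (max(abs(sz - sz[1])) > 1e-6 * sz[1])
    stop("anisotropic voxels are not supported", call. = FALSE)
  sz[1]
}
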