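#' Solve the cortical Laplace potential
#'
#' Computes a harmonic potential on the cortex voxels with Dirichlet
#' boundary values 0 on the white-matter side and 1 on the pial side, by
#' Gauss-Seidel relaxation of the 6-connected discrete Laplacian. The
#' conditions sit on the tissue interfaces (voxel faces), folded into the
#' stencil as ghost values, so a flat slab of thickness `T` yields the exact
#' linear profile `phi(z) = z / T` with `z` measured from the white-matter
#' interface. Level sets of the potential are intermediate surfaces between
#' the two boundaries; its gradient defines the local radial direction used
#' for cortical profiles.
#'
#' @param labels 3D integer array using the [tissue_labels()] coding, or a
#'   list with elements `labels` and `affine`.
#' @param affine Optional voxel-to-world matrix (defaults to an isotropic
#'   1 mm RAS affine).
#' @param tol Convergence tolerance: iteration stops when the largest
#'   per-sweep update falls below `tol`.
#' @param max_iter Maximum number of Gauss-Seidel sweeps.
#' @return A `scalar_volume` whose `data` holds the potential on cortex
#'   voxels (NA elsewhere), with attributes `iterations`,
#'   `residual`, and `flagged` (logical array of cortex voxels with no
#'   labelled neighbour, which receive no potential).
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(16, 16, 12), cortex_thickness = 4))
#' pot <- solve_cortical_potential(ph$truth$labels)
#' range(pot$data[ph$truth$labels == tissue_labels()["cortex"]])
#' @export
solve_cortical_potential <- function(labels, affine = NULL, tol = 1e-6,
                                     max_iter = 1e4) {
  if (is.list(labels)) { affine <- affine %||% labels$affine; labels <- labels$labels }
  labels <- as_label_array(labels)
  d <- dim(labels)
  affine <- affine %||% iso_affine(d, 1)
  if (!any(labels == LBL_CORTEX))
    stop("no cortex voxels in the label volume", call. = FALSE)
  if (!any(labels == LBL_WM))
    stop("unsatisfiable boundary conditions: no white-matter voxels", call. = FALSE)
  if (!any(labels == LBL_PIAL))
    stop("unsatisfiable boundary conditions: no pial voxels", call. = FALSE)

  res <- laplace_gauss_seidel(labels, tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("Laplace solver did not converge in %d sweeps (residual %.3e)",
                 res$iterations, res$residual), call. = FALSE)
  out <- scalar_volume(res$potential, affine, labels == LBL_CORTEX)
  attr(out, "iterations") <- res$iterations
  attr(out, "residual") <- res$residual
  attr(out, "flagged") <- res$isolated
  out
}

as_label_array <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(LBL_OUTSIDE, LBL_WM, LBL_CORTEX, LBL_PIAL)))
    stop("label volume contains codes outside 0..3", call. = FALSE)
  labels
}

#' Radial direction field from the cortical potential
#'
#' Differentiates the Laplace potential by central differences and
#' normalises to unit length, oriented toward increasing potential, i.e.
#' from the white-matter boundary toward the pial surface. At voxels
#' adjacent to a tissue boundary the neighbour's value is the ghost value
#' implied by the face condition (0 on the white-matter side, 1 on the pial
#' side), matching the solver's discretisation; neighbours with no
#' condition fall back to one-sided differences. Cortex voxels whose
#' gradient norm falls below `min_grad` are flagged and carry no direction.
#' Discretisation of the boundary surfaces into voxel faces perturbs the
#' direction mainly in the one or two voxel shells next to each boundary;
#' in the interior of the ribbon the field tracks the analytic radial
#' direction to well under a degree on analytic phantoms.
#'
#' @param potential A `scalar_volume` from [solve_cortical_potential()].
#' @param labels The label volume the potential was solved on.
#' @param min_grad Gradient-norm floor below which a voxel is flagged.
#' @return An object of class `radial_field`: `vectors` (4D array, last dim
#'   3, NA where flagged or outside cortex), `flagged` (logical 3D array
#'   over cortex voxels), `affine`, `mask`.
#' @export
radial_field <- function(potential, labels, min_grad = 1e-8) {
  stopifnot(inherits(potential, "scalar_volume"))
  if (is.list(labels)) labels <- labels$labels
  labels <- as_label_array(labels)
  phi <- potential$data
  d <- dim(phi)
  vs <- voxel_size_from_affine(potential$affine)
  grad <- array(NA_real_, c(d, 3L))
  idx <- which(labels == LBL_CORTEX)
  sub <- arrayInd(idx, d)
  ctr <- phi[sub]
  neighbour_value <- function(nbsub, inside) {
    # cortex -> potential; boundary -> ghost value implied by the face
    # condition; outside grid or unlabeled -> NA
    v <- rep(NA_real_, nrow(nbsub))
    lab <- rep(LBL_OUTSIDE, nrow(nbsub))
    lab[inside] <- labels[nbsub[inside, , drop = FALSE]]
    is_cor <- inside & lab == LBL_CORTEX
    v[is_cor] <- phi[nbsub[is_cor, , drop = FALSE]]
    v[inside & lab == LBL_WM] <- -ctr[inside & lab == LBL_WM]
    v[inside & lab == LBL_PIAL] <- 2 - ctr[inside & lab == LBL_PIAL]
    v
  }
  for (ax in 1:3) {
    up <- sub; up[, ax] <- up[, ax] + 1L
    dn <- sub; dn[, ax] <- dn[, ax] - 1L
    up_in <- up[, ax] <= d[ax]
    dn_in <- dn[, ax] >= 1L
    up[!up_in, ax] <- sub[!up_in, ax]
    dn[!dn_in, ax] <- sub[!dn_in, ax]
    vu <- neighbour_value(up, up_in)
    vd <- neighbour_value(dn, dn_in)
    h <- rep(2 * vs, length(idx))
    # one-sided differences where a neighbour carries no value
    gone <- is.na(vu) & !is.na(vd)
    vu[gone] <- ctr[gone]; h[gone] <- vs
    gtwo <- is.na(vd) & !is.na(vu)
    vd[gtwo] <- ctr[gtwo]; h[gtwo] <- vs
    g <- (vu - vd) / h
    g[is.na(vu) & is.na(vd)] <- NA_real_
    grad[cbind(sub, ax)] <- g
  }
  gx <- grad[cbind(sub, 1)]; gy <- grad[cbind(sub, 2)]; gz <- grad[cbind(sub, 3)]
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  bad <- !is.finite(nrm) | nrm < min_grad
  flagged <- array(FALSE, d)
  flagged[idx[bad]] <- TRUE
  vec <- array(NA_real_, c(d, 3L))
  ok <- !bad
  if (any(ok)) {
    oksub <- sub[ok, , drop = FALSE]
    vec[cbind(oksub, rep(1L, nrow(oksub)))] <- gx[ok] / nrm[ok]
    vec[cbind(oksub, rep(2L, nrow(oksub)))] <- gy[ok] / nrm[ok]
    vec[cbind(oksub, rep(3L, nrow(oksub)))] <- gz[ok] / nrm[ok]
  }
  structure(list(vectors = vec, flagged = flagged, affine = potential$affine,
                 mask = labels == LBL_CORTEX),
            class = "radial_field")
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("radial_field: %d cortex voxels, %d flagged\n",
              sum(x$mask), sum(x$flagged)))
  invisible(x)
}

#' Trace cortical profiles along the radial field
#'
#' Seeds one profile at every unflagged cortex voxel adjacent (6-connectivity)
#' to white matter and integrates the trilinearly interpolated radial field
#' by fixed-step Euler until the path leaves the cortex, the potential stops
#' increasing, or the maximum length is reached. Profiles with fewer than two
#' samples are discarded and counted.
#'
#' @param field A [radial_field()].
#' @param potential The matching `scalar_volume` potential.
#' @param labels The label volume.
#' @param step Integration step in mm; the default is a quarter voxel.
#' @param max_length Maximum profile arc length in mm. By default four times
#'   the nominal cortical thickness, itself estimated as the median of
#'   `1 / |grad phi|` over the cortex (the potential spans 0..1 across the
#'   ribbon, so its inverse gradient is a local thickness).
#' @return An object of class `cortical_profiles`: a list with `profiles`
#'   (each a list of `points`, an m x 3 matrix of continuous 0-based voxel
#'   coordinates; `potential`, the interpolated potential at each sample;
#'   `seed`, the 1-based seed voxel index triple; `arc_length` in mm),
#'   `n_seeds`, `n_discarded`, `step`, `affine`.
#' @export
trace_profiles <- function(field, potential, labels, step = NULL,
                           max_length = NULL) {
  stopifnot(inherits(field, "radial_field"), inherits(potential, "scalar_volume"))
  if (is.list(labels)) labels <- labels$labels
  labels <- as_label_array(labels)
  d <- dim(labels)
  vs <- voxel_size_from_affine(field$affine)
  step <- step %||% (0.25 * vs)
  stopifnot_scalar(step, "step", positive = TRUE)

  if (is.null(max_length)) {
    # nominal thickness from the potential gradient (see roxygen above)
    idx <- which(field$mask & !field$flagged)
    if (length(idx) == 0L) stop("no usable radial field voxels", call. = FALSE)
    sub <- arrayInd(idx, d)
    gn <- interior_grad_norm(potential$data, labels, sub, vs)
    gn <- gn[is.finite(gn) & gn > 0]
    thick <- if (length(gn)) stats::median(1 / gn) else vs * max(d)
    max_length <- min(4 * thick, vs * max(d) * 4)
  }

  # seeds: cortex voxels with a white-matter 6-neighbour, not flagged
  cor_idx <- which(labels == LBL_CORTEX)
  sub <- arrayInd(cor_idx, d)
  adj_wm <- rep(FALSE, length(cor_idx))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- sub; nb[, ax] <- nb[, ax] + s
    inb <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    v <- rep(FALSE, length(cor_idx))
    v[inb] <- labels[nb[inb, , drop = FALSE]] == LBL_WM
    adj_wm <- adj_wm | v
  }
  seed_sub <- sub[adj_wm, , drop = FALSE]
  seed_flagged <- field$flagged[seed_sub]
  n_skipped_flagged <- sum(seed_flagged)
  seed_sub <- seed_sub[!seed_flagged, , drop = FALSE]
  n_seeds <- nrow(seed_sub)
  if (n_seeds == 0L) stop("no usable seed voxels at the white-matter boundary",
                          call. = FALSE)

  max_steps <- ceiling(max_length / step) + 1L
  step_vox <- step / vs
  fx <- field$vectors[, , , 1]; fy <- field$vectors[, , , 2]; fz <- field$vectors[, , , 3]

  pos <- seed_sub - 1          # continuous 0-based coordinates
  active <- rep(TRUE, n_seeds)
  npts <- rep(1L, n_seeds)
  path <- array(NA_real_, c(max_steps, 3L, n_seeds))
  path[1, , ] <- t(pos)
  potv <- matrix(NA_real_, max_steps, n_seeds)
  potv[1, ] <- trilinear(potential$data, pos)

  for (s in seq_len(max_steps - 1L)) {
    if (!any(active)) break
    p <- pos[active, , drop = FALSE]
    v <- cbind(trilinear(fx, p), trilinear(fy, p), trilinear(fz, p))
    nrm <- sqrt(rowSums(v^2))
    ok <- is.finite(nrm) & nrm > 0
    v[ok, ] <- v[ok, , drop = FALSE] / nrm[ok]
    pnew <- p + step_vox * v
    lin <- nearest_voxel_index(d, pnew)
    inside <- !is.na(lin) & ok
    inside[inside] <- labels[lin[inside]] == LBL_CORTEX
    phi_new <- rep(NA_real_, nrow(p))
    phi_new[inside] <- trilinear(potential$data, pnew[inside, , drop = FALSE])
    act_ids <- which(active)
    phi_old <- potv[cbind(npts[act_ids], act_ids)]
    keep <- inside & is.finite(phi_new) & phi_new > phi_old
    stopping <- act_ids[!keep]
    active[stopping] <- FALSE
    cont <- act_ids[keep]
    if (length(cont)) {
      pos[cont, ] <- pnew[keep, , drop = FALSE]
      npts[cont] <- npts[cont] + 1L
      path[cbind(rep(npts[cont], each = 3L),
                 rep(1:3, length(cont)),
                 rep(cont, each = 3L))] <- t(pnew[keep, , drop = FALSE])
      potv[cbind(npts[cont], cont)] <- phi_new[keep]
    }
  }

  keep <- npts >= 2L
  n_discarded <- sum(!keep)
  profiles <- lapply(which(keep), function(i) {
    m <- npts[i]
    list(points = matrix(path[seq_len(m), , i], ncol = 3L),
         potential = potv[seq_len(m), i],
         seed = seed_sub[i, ],
         arc_length = (m - 1L) * step)
  })
  structure(list(profiles = profiles, n_seeds = n_seeds,
                 n_discarded = n_discarded,
                 n_seeds_flagged = n_skipped_flagged,
                 step = step, max_length = max_length, affine = field$affine),
            class = "cortical_profiles")
}

# Gradient-norm estimate restricted to voxels whose neighbours along each
# axis are themselves cortex (interior of the ribbon); used only to size the
# nominal thickness 1 / |grad phi|.
interior_grad_norm <- function(phi, labels, sub, vs) {
  d <- dim(phi)
  g2 <- 0
  for (ax in 1:3) {
    up <- sub; up[, ax] <- pmin(up[, ax] + 1L, d[ax])
    dn <- sub; dn[, ax] <- pmax(dn[, ax] - 1L, 1L)
    ok <- labels[up] == LBL_CORTEX & labels[dn] == LBL_CORTEX &
      up[, ax] > dn[, ax]
    g <- rep(0, nrow(sub))
    g[ok] <- (phi[up[ok, , drop = FALSE]] - phi[dn[ok, , drop = FALSE]]) /
      ((up[ok, ax] - dn[ok, ax]) * vs)
    g[!is.finite(g)] <- 0
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

#' @export
print.cortical_profiles <- function(x, ...) {
  al <- vapply(x$profiles, `[[`, numeric(1), "arc_length")
  cat(sprintf("cortical_profiles: %d profiles (%d seeds, %d discarded, %d flagged seeds), step %g mm, mean arc length %.2f mm\n",
              length(x$profiles), x$n_seeds, x$n_discarded, x$n_seeds_flagged,
              x$step, mean(al)))
  invisible(x)
}

#' Export profiles as a data frame
#'
#' One row per profile sample: `profile_id`, `sample_index`, 0-based
#' continuous voxel coordinates `x`, `y`, `z`, and the `potential` value.
#'
#' @param profiles A [trace_profiles()] result.
#' @return A data.frame.
#' @export
profiles_to_df <- function(profiles) {
  stopifnot(inherits(profiles, "cortical_profiles"))
  do.call(rbind, lapply(seq_along(profiles$profiles), function(i) {
    p <- profiles$profiles[[i]]
    data.frame(profile_id = i, sample_index = seq_len(nrow(p$points)),
               x = p$points[, 1], y = p$points[, 2], z = p$points[, 3],
               potential = p$potential)
  }))
}
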