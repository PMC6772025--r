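#' Diffusion acquisition scheme
#'
#' Bundles b-values with unit gradient directions. The scheme must contain at
#' least one `b = 0` volume and at least six unique, non-collinear `b > 0`
#' directions, the minimum for a tensor fit.
#'
#' @param bvals Numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x n matrix of gradient directions (columns); directions for
#'   `b > 0` entries must be unit-norm. `b = 0` columns may be zero.
#' @return An object of class `acquisition_scheme` with elements `bvals` and
#'   `bvecs`.
#' @examples
#' sch <- default_scheme()
#' sch
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("'bvecs' must be a 3 x length(bvals) matrix", call. = FALSE)
  if (any(bvals < 0)) stop("b-values must be non-negative", call. = FALSE)
  dw <- bvals > 0
  if (!any(!dw)) stop("scheme must contain at least one b = 0 entry", call. = FALSE)
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("gradient directions for b > 0 must be unit-norm", call. = FALSE)
  if (count_unique_axes(bvecs[, dw, drop = FALSE]) < 6L)
    stop("scheme needs at least 6 unique non-collinear b > 0 directions",
         call. = FALSE)
  structure(list(bvals = bvals, bvecs = bvecs), class = "acquisition_scheme")
}

# Directions equal up to sign count once.
count_unique_axes <- function(g) {
  n <- ncol(g)
  if (n == 0L) return(0L)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    for (j in seq.int(i + 1L, n)) {
      if (keep[j] && abs(sum(g[, i] * g[, j])) > 1 - 1e-6) keep[j] <- FALSE
    }
  }
  sum(keep)
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("acquisition scheme: %d volumes (%d b=0, %d diffusion-weighted, max b = %g s/mm^2)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0), max(x$bvals)))
  invisible(x)
}

#' Default high-b postmortem acquisition scheme
#'
#' Deterministic scheme emulating a postmortem cortical protocol: `n_dir`
#' diffusion directions isotropically distributed over the sphere by the
#' Fibonacci (golden-angle) construction at a single shell, preceded by
#' `n_b0` unweighted volumes. The defaults are 54 directions at
#' b = 4500 s/mm^2 with six b = 0 volumes.
#'
#' @param n_dir Number of diffusion-weighted directions.
#' @param b Shell b-value in s/mm^2.
#' @param n_b0 Number of b = 0 volumes.
#' @return An [acquisition_scheme()].
#' @export
default_scheme <- function(n_dir = 54L, b = 4500, n_b0 = 6L) {
  stopifnot_scalar(b, "b", positive = TRUE)
  i <- seq_len(n_dir) - 0.5
  z <- 1 - 2 * i / n_dir
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n_dir) - 1)
  g <- rbind(r * cos(th), r * sin(th), z)
  bvals <- c(rep(0, n_b0), rep(b, n_dir))
  bvecs <- cbind(matrix(0, 3, n_b0), g)
  acquisition_scheme(bvals, bvecs)
}

#' Read and write FSL-style bval/bvec text files
#'
#' `write_scheme()` writes one whitespace-separated row of b-values and three
#' rows of gradient components; `read_scheme()` reads the same dialect.
#'
#' @param scheme An [acquisition_scheme()].
#' @param bval_path,bvec_path Paths to the two text files.
#' @return `read_scheme()` returns an [acquisition_scheme()];
#'   `write_scheme()` returns the paths invisibly.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_scheme
#' @export
read_scheme <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path, call. = FALSE)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path, call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  bvecs <- matrix(bv, nrow = 3, byrow = TRUE)
  acquisition_scheme(bvals, bvecs)
}
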