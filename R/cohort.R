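#' Specify a synthetic cohort
#'
#' Defines a two-group cohort (cases and controls) in which each subject
#' carries a single orientation-dispersion parameter (the Watson
#' concentration `kappa` of their cortical phantom) drawn from a per-group
#' normal model, and region-wise synthetic histology measures generated by a
#' linear link to `kappa` plus Gaussian noise. Cases receive a lower mean
#' `kappa` (more orientation scatter) than controls, mirroring the loss of
#' radial coherence expected with cortical pathology. Ages are normal;
#' disease duration exists for cases only and increases with age.
#'
#' The histology link slopes are negative for the width/spacing measures
#' (more dispersed cortex goes with wider minicolumns in the emulated
#' pathology) and positive for microsegment number and cell density. Noise
#' standard deviations control the planted Spearman correlation between
#' dispersion and each measure.
#'
#' @param n_per_group Named integer vector, subjects per group
#'   (default 9 cases, 6 controls).
#' @param regions Region labels.
#' @param dispersion_model Per-group list of `mean` and `sd` for `kappa`.
#' @param histology_model Per-measure list of `intercept`, `slope`,
#'   `noise_sd` linking the measure to `kappa`.
#' @param covariate_model List with `age` (mean, sd) and `duration`
#'   (intercept, slope_age, sd; cases only).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(case = 9L, control = 6L),
                        regions = c("BA9", "BA41", "V1"),
                        dispersion_model = list(case = list(mean = 8, sd = 2),
                                                control = list(mean = 20, sd = 4)),
                        histology_model = default_histology_model(),
                        covariate_model = list(age = list(mean = 72, sd = 10),
                                               duration = list(intercept = -30,
                                                               slope_age = 0.9,
                                                               sd = 6)),
                        seed = 1L) {
  if (is.null(names(n_per_group)) || any(n_per_group < 2L))
    stop("'n_per_group' must be a named vector with at least 2 subjects per group",
         call. = FALSE)
  for (g in names(n_per_group))
    if (!g %in% names(dispersion_model))
      stop(sprintf("dispersion_model lacks group '%s'", g), call. = FALSE)
  for (m in names(histology_model))
    if (histology_model[[m]]$noise_sd < 0)
      stop("histology noise sd must be non-negative", call. = FALSE)
  structure(list(n_per_group = n_per_group, regions = regions,
                 dispersion_model = dispersion_model,
                 histology_model = histology_model,
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_histology_model <- function() {
  list(minicolumn_width    = list(intercept = 44, slope = -0.55, noise_sd = 1.6),
       neuropil_spacing    = list(intercept = 18, slope = -0.14, noise_sd = 0.9),
       core_width          = list(intercept = 33, slope = -0.30, noise_sd = 1.6),
       microsegment_number = list(intercept = 150, slope = 4.5, noise_sd = 35),
       cell_density        = list(intercept = 90, slope = 2.0, noise_sd = 35),
       bundle_spacing      = list(intercept = 55, slope = -0.70, noise_sd = 2.5),
       bundle_width        = list(intercept = 11, slope = -0.13, noise_sd = 0.7))
}

#' Generate a synthetic cohort
#'
#' Realises a [cohort_spec()]: draws each subject's dispersion `kappa` from
#' their group model (truncated at a small positive floor), builds a
#' per-subject [phantom_spec()] carrying that `kappa`, and generates the
#' long-format cohort table of synthetic histology measures and covariates.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param phantom_template A [phantom_spec()] whose fields other than
#'   `dispersion_kappa` and `seed` are copied into each subject's phantom.
#' @return A list with `subjects` (data.frame: subject, group, kappa, age,
#'   disease_duration), `phantom_specs` (named list of [phantom_spec()]),
#'   and `table` (long data.frame: subject, group, age, disease_duration,
#'   region, measure, value).
#' @export
make_cohort <- function(spec, phantom_template = phantom_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    n <- length(groups)
    id <- sprintf("S%02d", seq_len(n))
    kappa <- vapply(groups, function(g) {
      m <- spec$dispersion_model[[g]]
      max(0.1, rnorm(1, m$mean, m$sd))
    }, numeric(1))
    age <- rnorm(n, spec$covariate_model$age$mean, spec$covariate_model$age$sd)
    dm <- spec$covariate_model$duration
    duration <- ifelse(groups == names(spec$n_per_group)[1],
                       pmax(1, dm$intercept + dm$slope_age * age + rnorm(n, 0, dm$sd)),
                       NA_real_)
    subjects <- data.frame(subject = id, group = groups, kappa = kappa,
                           age = age, disease_duration = duration,
                           stringsAsFactors = FALSE)

    cells <- expand.grid(i = seq_len(n), region = spec$regions,
                         measure = names(spec$histology_model),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    hm <- spec$histology_model[cells$measure]
    val <- vapply(hm, `[[`, numeric(1), "intercept") +
      vapply(hm, `[[`, numeric(1), "slope") * kappa[cells$i] +
      rnorm(nrow(cells), 0, vapply(hm, `[[`, numeric(1), "noise_sd"))
    tab <- data.frame(subject = id[cells$i], group = groups[cells$i],
                      age = age[cells$i],
                      disease_duration = duration[cells$i],
                      region = cells$region, measure = cells$measure,
                      value = val, stringsAsFactors = FALSE)
    phantoms <- lapply(seq_len(n), function(i) {
      ps <- phantom_template
      ps$dispersion_kappa <- kappa[i]
      ps$seed <- spec$seed + i
      ps
    })
    names(phantoms) <- id
    list(subjects = subjects, phantom_specs = phantoms, table = tab)
  })
}

#' Append planted diffusion metrics to a cohort table
#'
#' Generates region-wise diffusion metric rows for every subject without
#' running the imaging pipeline: AngleR is the expected Watson radiality
#' angle for the subject's dispersion ([watson_mean_angle()]) plus noise,
#' the diffusivity metrics follow from the template eigenvalues through the
#' same angle, and FA is the template's eigenvalue anisotropy plus noise.
#' This gives the correlation screen a cohort whose diffusion-histology
#' associations are known by construction.
#'
#' @param cohort A [make_cohort()] result.
#' @param eigenvalues Tensor eigenvalues (mm^2/s) defining the diffusivity
#'   scale.
#' @param noise_sd Gaussian noise added to each generated metric value (on
#'   the metric's own scale; diffusivities are in 10^-3 mm^2/s units).
#' @param seed Integer seed.
#' @return The cohort list with diffusion rows appended to `table`.
#' @export
add_planted_diffusion <- function(cohort, eigenvalues = c(0.8, 0.2, 0.2) * 1e-3,
                                  noise_sd = 0.02, seed = 1L) {
  subj <- cohort$subjects
  regions <- unique(cohort$table$region)
  lam <- eigenvalues
  fa0 <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(subj))) {
      ang0 <- watson_mean_angle(subj$kappa[i])
      for (reg in regions) {
        ang <- ang0 + rnorm(1, 0, noise_sd)
        vals <- c(AngleR = ang,
                  ParlPD = 1e3 * lam[1] * cos(ang) + rnorm(1, 0, noise_sd),
                  PerpPD = 1e3 * lam[1] * sin(ang) + rnorm(1, 0, noise_sd),
                  FA = fa0 + rnorm(1, 0, noise_sd),
                  MD = 1e3 * mean(lam) + rnorm(1, 0, noise_sd))
        for (m in names(vals)) rows[[length(rows) + 1L]] <-
          data.frame(subject = subj$subject[i], group = subj$group[i],
                     age = subj$age[i],
                     disease_duration = subj$disease_duration[i],
                     region = reg, measure = m, value = unname(vals[m]),
                     stringsAsFactors = FALSE)
      }
    }
    cohort$table <- rbind(cohort$table, do.call(rbind, rows))
  })
  cohort
}

#' Sample pairs with a planted Spearman correlation
#'
#' Draws `n` pairs from a bivariate normal whose Pearson correlation
#' `2 * sin(pi * rho / 6)` yields population Spearman correlation `rho`
#' (the Pearson--Spearman relation for Gaussian variables).
#'
#' @param n Number of pairs.
#' @param rho Target population Spearman correlation in (-1, 1).
#' @param seed Optional integer seed.
#' @return An `n` x 2 matrix.
#' @export
sample_spearman_pairs <- function(n, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("'rho' must lie in (-1, 1)", call. = FALSE)
  rp <- 2 * sin(pi * rho / 6)
  with_seed(seed, {
    x <- rnorm(n)
    y <- rp * x + sqrt(1 - rp^2) * rnorm(n)
    cbind(x, y)
  })
}

#' Noise level for a planted Spearman correlation in a linear link
#'
#' For a measure `y = intercept + slope * x + e` with `x` and `e` Gaussian,
#' returns the noise standard deviation that yields population Spearman
#' correlation `rho` between `x` and `y` given the sd of `x`.
#'
#' @param slope Link slope (non-zero).
#' @param sd_x Standard deviation of the predictor.
#' @param rho Target population Spearman correlation, matching `slope` in sign.
#' @return Noise standard deviation.
#' @export
noise_sd_for_spearman <- function(slope, sd_x, rho) {
  if (slope == 0) stop("'slope' must be non-zero", call. = FALSE)
  if (abs(rho) >= 1 || rho * slope <= 0)
    stop("'rho' must be in (-1, 1) and match the slope's sign", call. = FALSE)
  rp <- 2 * sin(pi * abs(rho) / 6)
  abs(slope) * sd_x * sqrt(1 / rp^2 - 1)
}
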