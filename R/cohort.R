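# Published per-class index means/SDs used to calibrate synthetic cohorts
# (columns: mean, sd; classes: NPS = non-parkinsonian, PS = parkinsonian)
index_calibration_table <- function() {
  data.frame(
    index = c("sbr_q", "pcr_q", "ai_q", "sbr_v", "fd_v", "ai_v"),
    nps_mean = c(2.32, 0.86, 0.03, 5.61, 2.44, 3.94),
    nps_sd   = c(0.56, 0.04, 0.02, 1.51, 0.21, 3.37),
    ps_mean  = c(1.07, 0.75, 0.09, 3.26, 4.19, 15.2),
    ps_sd    = c(0.42, 0.10, 0.06, 1.15, 1.06, 13.3),
    stringsAsFactors = FALSE
  )
}

# truncated-normal parameter bundle for one phantom parameter
ptn <- function(mean, sd, lower = -Inf, upper = Inf) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

# draw from a doubly truncated normal
rtrunc <- function(n, p) {
  a <- stats::pnorm(p$lower, p$mean, p$sd)
  b <- stats::pnorm(p$upper, p$mean, p$sd)
  stats::qnorm(a + stats::runif(n) * (b - a), p$mean, p$sd)
}

# image-cohort generative parameter distributions per class. Subject
# intensities are built as contrast = (base - 1) * uptake * exp(jitter):
# one common uptake scale per subject (driving the large between-subject
# SBR spread while keeping the putamen/caudate ratio tight) plus small
# independent per-compartment jitter. The base intensities were solved on
# the default template at 12 mm FWHM so that the cohort means of SBR-Q,
# SBR-V and PCR-Q land on the published group means.
default_phantom_params <- function() {
  list(
    NPS = list(
      base = c(caudate = 5.956, anterior_putamen = 5.148,
               posterior_putamen = 5.148),
      uptake           = ptn(1, 0.25, lower = 0.3, upper = 2.2),
      jitter_sd        = 0.04,
      shape_erosion    = ptn(0.05, 0.04, lower = 0, upper = 0.2),
      asymmetry_factor = ptn(0.97, 0.02, lower = 0.85, upper = 1),
      total_counts     = ptn(2e6, 2e5, lower = 5e5, upper = 4e6)
    ),
    PS = list(
      base = c(caudate = 4.653, anterior_putamen = 6.804,
               posterior_putamen = 6.804),
      uptake           = ptn(1, 0.33, lower = 0.25, upper = 2.2),
      jitter_sd        = 0.12,
      shape_erosion    = ptn(0.50, 0.18, lower = 0.05, upper = 0.95),
      asymmetry_factor = ptn(0.905, 0.06, lower = 0.7, upper = 1),
      total_counts     = ptn(2e6, 2e5, lower = 5e5, upper = 4e6)
    )
  )
}

#' Synthetic cohort specification
#'
#' Defines a two-class (PS / NPS) synthetic cohort: sample sizes, the
#' per-class generative parameter distributions for image phantoms, the
#' per-class index means/SDs targeted by the fast tabular generator, and an
#' optional between-index correlation for the tabular draws.
#'
#' @param n_ps,n_nps class sizes (PS = parkinsonian syndrome).
#' @param seed integer RNG seed; all cohort randomness flows from it.
#' @param calibration data frame of per-index class means/SDs; defaults to
#'   the published group statistics.
#' @param correlation 6x6 between-index correlation matrix for the tabular
#'   generator's Gaussian copula (default identity: independent marginals).
#' @param phantom_params per-class truncated-normal parameter distributions
#'   for the image phantom generator.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ps = 71, n_nps = 40, seed = 1,
                        calibration = index_calibration_table(),
                        correlation = diag(6),
                        phantom_params = default_phantom_params()) {
  n_ps <- as.integer(n_ps); n_nps <- as.integer(n_nps)
  if (is.na(n_ps) || is.na(n_nps) || n_ps <= 0L || n_nps <= 0L) {
    stop("class sizes must be positive integers", call. = FALSE)
  }
  stopifnot(is.matrix(correlation), dim(correlation) == c(6, 6))
  structure(list(n_ps = n_ps, n_nps = n_nps, seed = as.integer(seed),
                 calibration = calibration, correlation = correlation,
                 phantom_params = phantom_params),
            class = "cohort_spec")
}

#' Draw phantom specifications for a synthetic cohort
#'
#' Samples one [phantom_spec()] per subject from the per-class parameter
#' distributions. PS draws have lower compartment uptake, higher shape
#' erosion and stronger asymmetry than NPS draws. Reproducible given the
#' cohort seed.
#'
#' @param cohort a [cohort_spec()].
#' @param grid_shape,voxel_mm,psf_fwhm_mm grid and resolution for the specs.
#' @return list of elements `list(spec = phantom_spec, label = "PS"/"NPS")`,
#'   NPS subjects first.
#' @export
sample_cohort <- function(cohort, grid_shape = c(128L, 128L, 48L),
                          voxel_mm = 4.4, psf_fwhm_mm = 12) {
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(cohort$seed, {
    out <- list()
    for (cls in c("NPS", "PS")) {
      n <- if (cls == "PS") cohort$n_ps else cohort$n_nps
      pp <- cohort$phantom_params[[cls]]
      uptake <- rtrunc(n, pp$uptake)
      jit <- matrix(stats::rnorm(3 * n, sd = pp$jitter_sd), n, 3)
      erosion <- rtrunc(n, pp$shape_erosion)
      asym <- rtrunc(n, pp$asymmetry_factor)
      counts <- rtrunc(n, pp$total_counts)
      seeds <- sample.int(.Machine$integer.max, n)
      for (i in seq_len(n)) {
        k <- 1 + (pp$base - 1) * uptake[i] * exp(jit[i, ])
        spec <- phantom_spec(
          caudate = k[["caudate"]],
          anterior_putamen = k[["anterior_putamen"]],
          posterior_putamen = k[["posterior_putamen"]],
          background_intensity = 1,
          shape_erosion = erosion[i], asymmetry_factor = asym[i],
          psf_fwhm_mm = psf_fwhm_mm, total_counts = counts[i],
          seed = seeds[i], grid_shape = grid_shape, voxel_mm = voxel_mm)
        out[[length(out) + 1L]] <- list(spec = spec, label = cls)
      }
    }
    out
  })
}

#' Fast tabular cohort of six-index panels
#'
#' Draws six-index vectors directly from per-class distributions calibrated
#' to the published group means/SDs, bypassing image simulation. Marginals
#' are zero-truncated normals whose parent parameters are moment-matched so
#' the truncated mean/SD equal the calibration targets; a Gaussian copula
#' applies the requested between-index correlation (identity by default).
#'
#' @param cohort a [cohort_spec()].
#' @return data frame with columns `subject_id`, `label`, `sbr_q`, `pcr_q`,
#'   `ai_q`, `sbr_v`, `fd_v`, `ai_v` (NPS rows first).
#' @export
tabular_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  cal <- cohort$calibration
  L <- chol(cohort$correlation)
  with_seed(cohort$seed, {
    blocks <- lapply(c("NPS", "PS"), function(cls) {
      n <- if (cls == "PS") cohort$n_ps else cohort$n_nps
      pre <- if (cls == "PS") "ps" else "nps"
      z <- matrix(stats::rnorm(n * 6), n, 6) %*% L
      u <- stats::pnorm(z)
      x <- vapply(seq_len(6), function(j) {
        par <- truncnorm_match(cal[[paste0(pre, "_mean")]][j],
                               cal[[paste0(pre, "_sd")]][j], lower = 0)
        qtruncnorm_lower(u[, j], par["mu"], par["sigma"], lower = 0)
      }, numeric(n))
      x <- matrix(x, nrow = n, ncol = 6)
      df <- as.data.frame(x)
      names(df) <- cal$index
      df$label <- cls
      df
    })
    out <- do.call(rbind, blocks)
    out <- cbind(subject_id = sprintf("s%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out[, c("subject_id", "label", "sbr_q", "pcr_q", "ai_q", "sbr_v",
            "fd_v", "ai_v")]
  })
}

#' Generate image phantoms for a cohort and compute their index panels
#'
#' Runs the full image path: samples phantom specs, synthesizes each
#' volume, and computes the six-index panel under both VOI schemes.
#'
#' @param cohort a [cohort_spec()].
#' @param template a [striatal_template()].
#' @param config a [panel_config()].
#' @param grid_shape,voxel_mm,psf_fwhm_mm forwarded to [sample_cohort()].
#' @return data frame of panels (one row per subject) with a `label` column.
#' @export
image_cohort_panels <- function(cohort, template = striatal_template(),
                                config = panel_config(),
                                grid_shape = template$grid_shape,
                                voxel_mm = template$voxel_mm,
                                psf_fwhm_mm = 12) {
  subjects <- sample_cohort(cohort, grid_shape, voxel_mm, psf_fwhm_mm)
  fq <- build_fitted_vois(template, grid_shape, voxel_mm)
  pv <- build_pentagonal_vois(template, grid_shape, voxel_mm)
  rows <- lapply(seq_along(subjects), function(i) {
    ph <- make_striatal_phantom(subjects[[i]]$spec, template)
    compute_panel(ph$volume, fq, pv, config,
                  subject_id = sprintf("s%03d", i),
                  label = subjects[[i]]$label)
  })
  do.call(rbind, rows)
}
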