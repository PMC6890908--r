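#' SPECT-like volume container
#'
#' A 3D grid of non-negative counts with isotropic voxel spacing, the unit
#' of image input throughout the package. Axes are ordered x (left to
#' right), y (posterior to anterior), z (inferior to superior).
#'
#' @param data 3D numeric array, finite and non-negative.
#' @param voxel_mm isotropic voxel size in mm.
#' @return an object of class `spect_volume`.
#' @export
spect_volume <- function(data, voxel_mm = 4.4) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("volume values must be finite and non-negative", call. = FALSE)
  }
  stop_if_not_scalar_num(voxel_mm, "voxel_mm", positive = TRUE)
  structure(list(data = data, voxel_mm = voxel_mm), class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  cat(sprintf("SPECT volume %s @ %.1f mm, total counts %.4g\n",
              paste(dim(x$data), collapse = "x"), x$voxel_mm, sum(x$data)))
  invisible(x)
}

#' Phantom generation parameters
#'
#' One synthetic subject's generative parameters. Compartment intensities
#' are count concentrations in arbitrary units relative to
#' `background_intensity`. `shape_erosion` in \[0, 1\] attenuates the putamen
#' toward background, the posterior compartment faster than the anterior, so
#' that 1 leaves a caudate-only "dot"; `asymmetry_factor` multiplies the
#' left hemisphere's intensities. `total_counts` scales the volume before
#' Poisson sampling; use `Inf` for a noiseless phantom. `psf_fwhm_mm = 0`
#' disables blurring.
#'
#' @param caudate,anterior_putamen,posterior_putamen per-hemisphere
#'   compartment intensities (right hemisphere; the left is derived).
#' @param background_intensity brain background intensity.
#' @param shape_erosion erosion level in \[0, 1\].
#' @param asymmetry_factor multiplier (>= 0) applied to the left hemisphere.
#' @param psf_fwhm_mm Gaussian point-spread FWHM in mm (default 12, a
#'   typical post-reconstruction resolution for ^123^I brain SPECT).
#' @param total_counts expected total counts for the Poisson stage.
#' @param seed integer RNG seed for the noise realization.
#' @param grid_shape,voxel_mm grid geometry.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(caudate = 9, anterior_putamen = 8,
                         posterior_putamen = 8, background_intensity = 1,
                         shape_erosion = 0, asymmetry_factor = 1,
                         psf_fwhm_mm = 12, total_counts = 2e6, seed = 1,
                         grid_shape = c(128L, 128L, 48L), voxel_mm = 4.4) {
  for (nm in c("caudate", "anterior_putamen", "posterior_putamen")) {
    stop_if_not_scalar_num(get(nm), nm, positive = TRUE)
  }
  stop_if_not_scalar_num(background_intensity, "background_intensity",
                         positive = TRUE)
  stop_if_not_scalar_num(shape_erosion, "shape_erosion", nonneg = TRUE)
  if (shape_erosion > 1) stop("'shape_erosion' must be in [0, 1]",
                              call. = FALSE)
  stop_if_not_scalar_num(asymmetry_factor, "asymmetry_factor", nonneg = TRUE)
  stop_if_not_scalar_num(psf_fwhm_mm, "psf_fwhm_mm", nonneg = TRUE)
  if (!identical(total_counts, Inf)) {
    stop_if_not_scalar_num(total_counts, "total_counts", positive = TRUE)
  }
  structure(list(
    caudate = caudate, anterior_putamen = anterior_putamen,
    posterior_putamen = posterior_putamen,
    background_intensity = background_intensity,
    shape_erosion = shape_erosion, asymmetry_factor = asymmetry_factor,
    psf_fwhm_mm = psf_fwhm_mm, total_counts = total_counts,
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    voxel_mm = voxel_mm
  ), class = "phantom_spec")
}

#' Separable Gaussian blur of a 3D array
#'
#' Applies an isotropic Gaussian point-spread function by sequential 1D
#' convolutions (kernel truncated at 3.5 sigma, taps normalized to unit
#' sum, zero boundary). Conserves the voxel sum for structures away from
#' the grid edge.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is a no-op.
#' @param voxel_mm voxel size in mm.
#' @return blurred array of the same dimensions.
#' @export
gaussian_blur_3d <- function(arr, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- as.integer(ceiling(3.5 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    K <- matrix(0, n, n)
    off <- row(K) - col(K)
    sel <- abs(off) <= r
    K[sel] <- k[off[sel] + r + 1]
    p <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, p)
    m <- K %*% matrix(a, nrow = n)
    arr <- aperm(array(m, d[p]), order(p))
  }
  arr
}

# erosion weights: posterior putamen fades as (1-e)^2, anterior as (1-e),
# caudate untouched, so erosion = 1 leaves a caudate-only dot
erosion_weights <- function(e) {
  c(caudate = 1, anterior_putamen = 1 - e, posterior_putamen = (1 - e)^2)
}

# effective compartment concentrations per side, after erosion and asymmetry
effective_intensities <- function(spec) {
  w <- erosion_weights(spec$shape_erosion)
  bg <- spec$background_intensity
  right <- vapply(compartment_names, function(nm) {
    bg + w[[nm]] * (spec[[nm]] - bg)
  }, numeric(1))
  left <- spec$asymmetry_factor * right
  list(left = left, right = right)
}

# blurred unit-contrast basis images for the template compartments + brain,
# cached so cohorts of phantoms share one convolution pass
phantom_basis <- function(template, grid_shape, voxel_mm, psf_fwhm_mm) {
  key <- paste("basis", template$name, template$version,
               paste(grid_shape, collapse = "x"), voxel_mm, psf_fwhm_mm,
               sep = "|")
  cached <- !is.null(template$name)
  if (cached && !is.null(.datspect_cache[[key]])) {
    return(.datspect_cache[[key]])
  }
  masks <- template_masks(template, grid_shape, voxel_mm)
  nm <- c("brain", grep("caudate_|putamen_", names(masks), value = TRUE))
  basis <- lapply(masks[nm], function(m) {
    gaussian_blur_3d(m + 0, psf_fwhm_mm, voxel_mm)
  })
  if (cached) .datspect_cache[[key]] <- basis
  basis
}

#' Generate a synthetic striatal SPECT phantom
#'
#' Builds a brain-shaped uniform background with three ellipsoidal striatal
#' compartments per hemisphere at the spec's concentrations (erosion and
#' asymmetry applied), convolves with an isotropic Gaussian PSF, scales to
#' the requested total counts and Poisson-samples. Returns the volume
#' together with the noiseless ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param template a [striatal_template()]; geometry must fit the grid.
#' @return list with elements `volume` (a [spect_volume()]) and `truth`
#'   (class `ground_truth`: the spec plus noiseless derived quantities).
#' @export
make_striatal_phantom <- function(spec, template = striatal_template()) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- template_masks(template, spec$grid_shape, spec$voxel_mm)
  basis <- phantom_basis(template, spec$grid_shape, spec$voxel_mm,
                         spec$psf_fwhm_mm)
  bg <- spec$background_intensity
  eff <- effective_intensities(spec)
  img <- bg * basis$brain
  for (side in c("left", "right")) {
    for (nm in compartment_names) {
      contrast <- eff[[side]][[nm]] - bg
      if (contrast != 0) {
        img <- img + contrast * basis[[paste0(nm, "_", side)]]
      }
    }
  }
  img[img < 0] <- 0  # clip tiny negative ringing from edge effects
  if (is.finite(spec$total_counts)) {
    lambda <- img * (spec$total_counts / sum(img))
    counts <- with_seed(spec$seed, stats::rpois(length(lambda), lambda))
    img <- array(as.numeric(counts), dim = dim(lambda))
  }
  vx_ml <- spec$voxel_mm^3 / 1000
  vol_ml <- vapply(c("left", "right"), function(side) {
    sum(vapply(compartment_names, function(nm) {
      sum(masks[[paste0(nm, "_", side)]])
    }, numeric(1))) * vx_ml
  }, numeric(1))
  comp_vol <- vapply(c("left", "right"), function(side) {
    vapply(compartment_names, function(nm) {
      sum(masks[[paste0(nm, "_", side)]]) * vx_ml
    }, numeric(1))
  }, numeric(length(compartment_names)))
  l <- sum(eff$left); r <- sum(eff$right)
  truth <- structure(list(
    spec = spec,
    concentration_ratio = lapply(eff, function(v) v / bg),
    compartment_volume_ml = comp_vol,
    striatal_volume_ml = vol_ml,
    # anterior/posterior contrast ratio implied by the erosion weights
    ap_contrast = if (spec$shape_erosion >= 1) Inf else
      1 / (1 - spec$shape_erosion),
    true_asymmetry = 2 * abs(l - r) / (l + r)
  ), class = "ground_truth")
  list(volume = spect_volume(img, spec$voxel_mm), truth = truth)
}
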