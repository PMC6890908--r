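#' VOI set container
#'
#' Named boolean voxel masks under one of two schemes: `fitted_q` (striatal
#' sub-VOIs fitted to the template compartments, occipital reference) or
#' `pentagonal_v` (large pentagonal prisms around each striatum, whole-brain
#' reference). Striatal masks are validated to be non-empty, disjoint from
#' their reference, and disjoint between hemispheres.
#'
#' @param scheme `"fitted_q"` or `"pentagonal_v"`.
#' @param masks named list of logical arrays on a common grid.
#' @param voxel_mm isotropic voxel size in mm.
#' @return an object of class `voi_set`.
#' @export
voi_set <- function(scheme = c("fitted_q", "pentagonal_v"), masks, voxel_mm) {
  scheme <- match.arg(scheme)
  required <- if (scheme == "fitted_q") {
    c(paste0(rep(compartment_names, each = 2), "_", c("left", "right")),
      "occipital_reference")
  } else {
    c("striatal_prism_left", "striatal_prism_right", "whole_brain_reference")
  }
  missing <- setdiff(required, names(masks))
  if (length(missing)) {
    stop("missing VOI masks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  masks <- masks[required]
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("VOI masks are on different grids",
                               call. = FALSE)
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty)) stop("empty VOI masks: ", paste(empty, collapse = ", "),
                          call. = FALSE)
  ref <- grep("reference", required, value = TRUE)
  striatal <- Reduce(`|`, masks[setdiff(required, ref)])
  if (any(striatal & masks[[ref]])) {
    stop("striatal masks overlap the reference mask", call. = FALSE)
  }
  lft <- Reduce(`|`, masks[grep("_left$", required, value = TRUE)])
  rgt <- Reduce(`|`, masks[grep("_right$", required, value = TRUE)])
  if (any(lft & rgt)) stop("left and right masks overlap", call. = FALSE)
  structure(list(scheme = scheme, masks = masks, voxel_mm = voxel_mm),
            class = "voi_set")
}

#' @export
print.voi_set <- function(x, ...) {
  cat(sprintf("VOI set [%s], %d masks @ %.1f mm:\n", x$scheme,
              length(x$masks), x$voxel_mm))
  for (nm in names(x$masks)) {
    cat(sprintf("  %-24s %6d voxels\n", nm, sum(x$masks[[nm]])))
  }
  invisible(x)
}

#' Morphological dilation of a voxel mask
#'
#' Euclidean dilation by a metric radius: a voxel is set when any voxel of
#' the input mask lies within `r_mm` of its centre (computed by unioning
#' integer-offset shifts of the mask).
#'
#' @param mask logical 3D array.
#' @param r_mm dilation radius in mm.
#' @param voxel_mm voxel size in mm.
#' @return dilated logical array.
#' @export
dilate_mask <- function(mask, r_mm, voxel_mm) {
  rv <- floor(r_mm / voxel_mm)
  if (rv < 1) return(mask)
  d <- dim(mask)
  out <- mask
  offs <- expand.grid(ox = -rv:rv, oy = -rv:rv, oz = -rv:rv)
  offs <- offs[sqrt(rowSums(offs^2)) * voxel_mm <= r_mm &
                 rowSums(abs(offs)) > 0, ]
  src_rng <- function(n, o) max(1, 1 - o):min(n, n - o)
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    sx <- src_rng(d[1], o[1]); sy <- src_rng(d[2], o[2])
    sz <- src_rng(d[3], o[3])
    out[sx + o[1], sy + o[2], sz + o[3]] <-
      out[sx + o[1], sy + o[2], sz + o[3]] | mask[sx, sy, sz]
  }
  out
}

#' Fitted striatal VOIs with occipital reference
#'
#' Q-style scheme: the six striatal sub-VOIs coincide with the template's
#' anatomical compartments and the reference is a bilateral occipital zone.
#'
#' @param template a [striatal_template()].
#' @param grid_shape,voxel_mm grid; must match the volumes to be analysed.
#' @return a [voi_set()] with scheme `fitted_q`.
#' @export
build_fitted_vois <- function(template, grid_shape = template$grid_shape,
                              voxel_mm = template$voxel_mm) {
  masks <- template_masks(template, grid_shape, voxel_mm)
  voi_set("fitted_q",
          masks[c(paste0(rep(compartment_names, each = 2), "_",
                         c("left", "right")), "occipital_reference")],
          voxel_mm)
}

# pentagonal cross-section: rectangle over the dilated striatal bounding box
# with an anterior apex triangle; clamped at the midline so hemispheres stay
# disjoint
pentagon_prism_mask <- function(template, grid_shape, voxel_mm, side) {
  pg <- template$pentagon
  ext <- lapply(compartment_names, function(nm) {
    e <- template$striatum[[nm]]
    ctr <- if (side == "left") mirror_x(e$center_mm) else e$center_mm
    rbind(ctr - e$semi_axes_mm, ctr + e$semi_axes_mm)
  })
  lo <- do.call(pmin, lapply(ext, function(m) m[1, ])) - pg$dilation_mm
  hi <- do.call(pmax, lapply(ext, function(m) m[2, ])) + pg$dilation_mm
  if (side == "right") lo[1] <- max(lo[1], 0) else hi[1] <- min(hi[1], 0)
  x0 <- lo[1]; x1 <- hi[1]; y0 <- lo[2]; y1 <- hi[2]
  xm <- (x0 + x1) / 2
  ya <- y1 + pg$apex_extension_frac * (x1 - x0)
  z0 <- lo[3] - (pg$z_margin_mm - pg$dilation_mm)
  z1 <- hi[3] + (pg$z_margin_mm - pg$dilation_mm)
  xs <- axis_coords(grid_shape[1], voxel_mm)
  ys <- axis_coords(grid_shape[2], voxel_mm)
  zs <- axis_coords(grid_shape[3], voxel_mm)
  X <- matrix(xs, grid_shape[1], grid_shape[2])
  Y <- matrix(ys, grid_shape[1], grid_shape[2], byrow = TRUE)
  roof <- ifelse(X <= xm,
                 y1 + (X - x0) * (ya - y1) / (xm - x0),
                 y1 + (x1 - X) * (ya - y1) / (x1 - xm))
  sect <- X >= x0 & X <= x1 & Y >= y0 & (Y <= y1 | Y <= roof)
  if (any(sect[c(1, grid_shape[1]), ]) || any(sect[, c(1, grid_shape[2])]) ||
      z0 < zs[1] || z1 > zs[grid_shape[3]]) {
    stop(sprintf("pentagonal prism (%s) is clipped by the grid", side),
         call. = FALSE)
  }
  out <- array(FALSE, grid_shape)
  for (k in which(zs >= z0 & zs <= z1)) out[, , k] <- sect
  out
}

#' Pentagonal prism VOIs with whole-brain reference
#'
#' V-style (Southampton-type) scheme: one large pentagonal prism per
#' hemisphere, sized to the template striatum dilated by the template's
#' `dilation_mm` (apex anterior, mirrored across the midline), plus a
#' whole-brain reference excluding a zone around the basal ganglia (the
#' union of both prisms dilated by one voxel).
#'
#' @inheritParams build_fitted_vois
#' @return a [voi_set()] with scheme `pentagonal_v`.
#' @export
build_pentagonal_vois <- function(template, grid_shape = template$grid_shape,
                                  voxel_mm = template$voxel_mm) {
  masks <- template_masks(template, grid_shape, voxel_mm)
  pl <- pentagon_prism_mask(template, grid_shape, voxel_mm, "left")
  pr <- pentagon_prism_mask(template, grid_shape, voxel_mm, "right")
  excl <- dilate_mask(pl | pr, voxel_mm, voxel_mm)
  voi_set("pentagonal_v",
          list(striatal_prism_left = pl, striatal_prism_right = pr,
               whole_brain_reference = masks$brain_core & !excl),
          voxel_mm)
}

#' Count statistics of a volume within a mask
#'
#' @param volume a [spect_volume()].
#' @param mask logical array matching the volume grid, or the name of a mask
#'   when `vois` is given.
#' @return list with `mean_counts`, `total_counts`, `volume_ml` and
#'   `n_voxels`.
#' @export
voi_stats <- function(volume, mask) {
  stopifnot(inherits(volume, "spect_volume"))
  if (!identical(dim(mask), dim(volume$data))) {
    stop("mask and volume grids differ", call. = FALSE)
  }
  n <- sum(mask)
  if (n == 0) stop("mask is empty", call. = FALSE)
  vals <- volume$data[mask]
  list(mean_counts = mean(vals), total_counts = sum(vals),
       volume_ml = n * volume$voxel_mm^3 / 1000, n_voxels = n)
}

# union of one hemisphere's striatal sub-VOIs (fitted scheme)
striatal_union_mask <- function(vois, side) {
  stopifnot(vois$scheme == "fitted_q")
  Reduce(`|`, vois$masks[paste0(compartment_names, "_", side)])
}

#' Serialize a VOI set as a NIfTI label map plus JSON legend
#'
#' Masks are written as consecutive integer labels (0 = outside) with a
#' legend mapping labels to mask names and recording the scheme.
#'
#' @param vois a [voi_set()].
#' @param nii_path output NIfTI path (`.nii` or `.nii.gz`).
#' @param json_path output legend path.
#' @export
write_voi_set <- function(vois, nii_path, json_path) {
  lab <- array(0L, dim(vois$masks[[1]]))
  for (i in seq_along(vois$masks)) lab[vois$masks[[i]]] <- i
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- rep(vois$voxel_mm, 3)
  RNifti::writeNifti(img, nii_path)
  jsonlite::write_json(
    list(scheme = vois$scheme, voxel_mm = vois$voxel_mm,
         labels = stats::setNames(as.list(seq_along(vois$masks)),
                                  names(vois$masks))),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(nii_path)
}

#' @rdname write_voi_set
#' @export
read_voi_set <- function(nii_path, json_path) {
  legend <- jsonlite::fromJSON(json_path)
  lab <- as.array(RNifti::readNifti(nii_path))
  masks <- lapply(legend$labels, function(i) {
    array(lab == i, dim = dim(lab))
  })
  voi_set(legend$scheme, masks, legend$voxel_mm)
}
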