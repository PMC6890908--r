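#' Striatal phantom template geometry
#'
#' Loads the versioned template that fixes the phantom's anatomy in template
#' voxel space: a brain ellipsoid, an occipital reference zone, and three
#' ellipsoidal striatal compartments per hemisphere (caudate, anterior
#' putamen, posterior putamen; the right hemisphere is specified and the
#' left is its mirror image). All positions and semi-axes are in mm relative
#' to the grid centre; x runs left to right, y posterior to anterior,
#' z inferior to superior.
#'
#' @param path optional path to a template JSON file; defaults to the
#'   geometry shipped with the package.
#' @return an object of class `striatal_template`.
#' @export
striatal_template <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "striatal_template.json",
                        package = "datspect", mustWork = TRUE)
  }
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tpl$grid_shape <- as.integer(tpl$grid_shape)
  stopifnot(length(tpl$grid_shape) == 3L, all(tpl$grid_shape > 0L),
            tpl$voxel_mm > 0)
  structure(tpl, class = "striatal_template")
}

#' @export
print.striatal_template <- function(x, ...) {
  cat(sprintf("Striatal template '%s' v%s: %s grid @ %.1f mm\n",
              x$name, x$version, paste(x$grid_shape, collapse = "x"),
              x$voxel_mm))
  invisible(x)
}

# voxel-centre coordinates (mm) along each axis, origin at grid centre
axis_coords <- function(n, voxel_mm) {
  (seq_len(n) - 1 - (n - 1) / 2) * voxel_mm
}

# logical array marking voxel centres inside an axis-aligned ellipsoid
ellipsoid_mask <- function(grid_shape, voxel_mm, center_mm, semi_mm) {
  tx <- ((axis_coords(grid_shape[1], voxel_mm) - center_mm[1]) / semi_mm[1])^2
  ty <- ((axis_coords(grid_shape[2], voxel_mm) - center_mm[2]) / semi_mm[2])^2
  tz <- ((axis_coords(grid_shape[3], voxel_mm) - center_mm[3]) / semi_mm[3])^2
  array(outer(outer(tx, ty, "+"), tz, "+") <= 1, dim = grid_shape)
}

mirror_x <- function(center_mm) c(-center_mm[1], center_mm[2:3])

compartment_names <- c("caudate", "anterior_putamen", "posterior_putamen")

# ellipsoid must fit inside the grid; names the offender otherwise
check_clipping <- function(template, grid_shape, voxel_mm) {
  half <- (grid_shape - 1) / 2 * voxel_mm
  for (nm in compartment_names) {
    e <- template$striatum[[nm]]
    if (any(abs(e$center_mm) + e$semi_axes_mm > half)) {
      stop(sprintf("compartment '%s' is clipped by the grid boundary", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Voxelize the template's anatomical masks
#'
#' Builds logical masks for the brain, the occipital reference zone and the
#' six striatal compartments on the template grid. Overlap between adjacent
#' compartments is resolved by precedence (caudate, then anterior putamen,
#' then posterior putamen) so the returned masks are pairwise disjoint.
#'
#' @param template a [striatal_template()].
#' @param grid_shape,voxel_mm grid override; default taken from the template.
#' @return named list of logical arrays.
#' @export
template_masks <- function(template, grid_shape = template$grid_shape,
                           voxel_mm = template$voxel_mm) {
  grid_shape <- as.integer(grid_shape)
  key <- paste("masks", template$name, template$version,
               paste(grid_shape, collapse = "x"), voxel_mm, sep = "|")
  if (!is.null(template$name) && !is.null(.datspect_cache[[key]])) {
    return(.datspect_cache[[key]])
  }
  check_clipping(template, grid_shape, voxel_mm)
  em <- function(e, mirror = FALSE) {
    ctr <- if (mirror) mirror_x(e$center_mm) else e$center_mm
    ellipsoid_mask(grid_shape, voxel_mm, ctr, e$semi_axes_mm)
  }
  brain <- em(template$brain)
  # interior core used for reference sampling: keeps the reference clear of
  # brain-surface partial-volume falloff
  margin <- template$brain$reference_margin_mm %||% 0
  core <- ellipsoid_mask(grid_shape, voxel_mm, template$brain$center_mm,
                         pmax(template$brain$semi_axes_mm - margin, 1))
  masks <- list(brain = brain, brain_core = brain & core)
  for (side in c("right", "left")) {
    mir <- side == "left"
    caud <- em(template$striatum$caudate, mir) & brain
    ant  <- em(template$striatum$anterior_putamen, mir) & brain & !caud
    post <- em(template$striatum$posterior_putamen, mir) & brain &
      !caud & !ant
    masks[[paste0("caudate_", side)]] <- caud
    masks[[paste0("anterior_putamen_", side)]] <- ant
    masks[[paste0("posterior_putamen_", side)]] <- post
  }
  striatal <- Reduce(`|`, masks[grep("caudate|putamen", names(masks))])
  masks$occipital_reference <- em(template$occipital) & brain & !striatal
  if (!is.null(template$name)) .datspect_cache[[key]] <- masks
  masks
}
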