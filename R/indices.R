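#' Fractal-dimension index configuration
#'
#' Five threshold stages, expressed as fractions of the in-VOI maximum,
#' used to delineate the striatum at successively higher levels; the index
#' is the magnitude of the log-log slope of suprathreshold voxel count
#' versus threshold level.
#'
#' @param threshold_fractions exactly five strictly increasing fractions in
#'   (0, 1) of the in-VOI maximum.
#' @param counting `"3d"` counts voxels throughout the VOI (default);
#'   `"2d"` counts pixels on the single axial slice holding the in-VOI
#'   maximum.
#' @return an object of class `fd_config`.
#' @export
fd_config <- function(threshold_fractions = c(0.35, 0.40, 0.45, 0.50, 0.55),
                      counting = c("3d", "2d")) {
  counting <- match.arg(counting)
  t <- as.numeric(threshold_fractions)
  if (length(t) != 5L || any(diff(t) <= 0) || any(t <= 0) || any(t >= 1)) {
    stop("'threshold_fractions' must be 5 strictly increasing values in (0,1)",
         call. = FALSE)
  }
  structure(list(threshold_fractions = t, counting = counting),
            class = "fd_config")
}

#' Per-panel index configuration
#'
#' @param fd an [fd_config()].
#' @param v_str_ml assumed striatal volume per hemisphere (mL) for the
#'   Southampton-type SBR; default 11.2.
#' @param ai_scale_q,ai_scale_v scale applied to the asymmetry index in each
#'   scheme (fraction for Q, percent for V, matching their conventional
#'   magnitudes).
#' @param sbr_v_formula `"southampton"` (volume-corrected total-count
#'   formulation, default) or `"concentration"` (plain striatal/reference
#'   concentration ratio minus one).
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(fd = fd_config(), v_str_ml = 11.2, ai_scale_q = 1,
                         ai_scale_v = 100,
                         sbr_v_formula = c("southampton", "concentration")) {
  stopifnot(inherits(fd, "fd_config"))
  stop_if_not_scalar_num(v_str_ml, "v_str_ml", positive = TRUE)
  structure(list(fd = fd, v_str_ml = v_str_ml, ai_scale_q = ai_scale_q,
                 ai_scale_v = ai_scale_v,
                 sbr_v_formula = match.arg(sbr_v_formula)),
            class = "panel_config")
}

#' Specific binding ratio, fitted-VOI scheme
#'
#' Per hemisphere, the mean counts of the striatal VOI (union of the
#' caudate and both putamen sub-VOIs), background-subtracted, divided by
#' the mean counts of the occipital reference VOI.
#'
#' @param volume a [spect_volume()].
#' @param vois a [voi_set()] with scheme `fitted_q`.
#' @return list with `left`, `right` and `mean`.
#' @export
sbr_q <- function(volume, vois) {
  stopifnot(inherits(vois, "voi_set"))
  if (vois$scheme != "fitted_q") stop("sbr_q needs a fitted_q VOI set",
                                      call. = FALSE)
  occ <- voi_stats(volume, vois$masks$occipital_reference)$mean_counts
  if (occ <= 0) stop("occipital reference mean is not positive",
                     call. = FALSE)
  side <- vapply(c("left", "right"), function(s) {
    ms <- voi_stats(volume, striatal_union_mask(vois, s))$mean_counts
    (ms - occ) / occ
  }, numeric(1))
  list(left = unname(side["left"]), right = unname(side["right"]),
       mean = mean(side))
}

#' Specific binding ratio, pentagonal-VOI (Southampton-type) scheme
#'
#' Per hemisphere, with `C_t` the total counts of the striatal prism, `C_r`
#' the reference count concentration (counts per mL) and `V_voi` the prism
#' volume: `SBR = (C_t / C_r - V_voi) / V_str`. Because the prism captures
#' the full striatal signal, the estimate is insensitive to resolution
#' loss. `formula = "concentration"` instead returns the plain
#' striatal/reference concentration ratio minus one.
#'
#' @param volume a [spect_volume()].
#' @param vois a [voi_set()] with scheme `pentagonal_v`.
#' @param v_str_ml assumed striatal volume per hemisphere in mL.
#' @param formula `"southampton"` or `"concentration"`.
#' @return list with `left`, `right` and `mean`.
#' @export
sbr_v <- function(volume, vois, v_str_ml = 11.2,
                  formula = c("southampton", "concentration")) {
  stopifnot(inherits(vois, "voi_set"))
  formula <- match.arg(formula)
  if (vois$scheme != "pentagonal_v") {
    stop("sbr_v needs a pentagonal_v VOI set", call. = FALSE)
  }
  stop_if_not_scalar_num(v_str_ml, "v_str_ml", positive = TRUE)
  ref <- voi_stats(volume, vois$masks$whole_brain_reference)
  vox_ml <- volume$voxel_mm^3 / 1000
  c_r <- ref$mean_counts / vox_ml
  if (c_r <= 0) stop("reference count concentration is not positive",
                     call. = FALSE)
  side <- vapply(c("left", "right"), function(s) {
    st <- voi_stats(volume, vois$masks[[paste0("striatal_prism_", s)]])
    if (formula == "southampton") {
      (st$total_counts / c_r - st$volume_ml) / v_str_ml
    } else {
      st$mean_counts / ref$mean_counts - 1
    }
  }, numeric(1))
  list(left = unname(side["left"]), right = unname(side["right"]),
       mean = mean(side))
}

#' Putamen-to-caudate ratio
#'
#' Per hemisphere, the raw mean counts of the putamen VOI (anterior plus
#' posterior sub-VOIs) divided by the raw mean counts of the caudate VOI;
#' no background subtraction. Low values indicate posterior-predominant
#' uptake loss.
#'
#' @inheritParams sbr_q
#' @return list with `left`, `right` and `mean`.
#' @export
pcr <- function(volume, vois) {
  stopifnot(inherits(vois, "voi_set"))
  if (vois$scheme != "fitted_q") stop("pcr needs a fitted_q VOI set",
                                      call. = FALSE)
  side <- vapply(c("left", "right"), function(s) {
    put <- vois$masks[[paste0("anterior_putamen_", s)]] |
      vois$masks[[paste0("posterior_putamen_", s)]]
    caud <- voi_stats(volume, vois$masks[[paste0("caudate_", s)]])$mean_counts
    if (caud <= 0) stop("caudate mean is not positive", call. = FALSE)
    voi_stats(volume, put)$mean_counts / caud
  }, numeric(1))
  list(left = unname(side["left"]), right = unname(side["right"]),
       mean = mean(side))
}

#' Asymmetry index
#'
#' The absolute left-right difference divided by the mean of the two sides,
#' times `scale` (1 reports a fraction, 100 a percentage).
#'
#' @param left,right per-side values (typically SBRs).
#' @param scale output scale.
#' @return non-negative scalar.
#' @export
asymmetry_index <- function(left, right, scale = 1) {
  m <- (left + right) / 2
  if (!is.finite(m) || m <= 0) {
    stop("mean of the two sides must be positive", call. = FALSE)
  }
  abs(left - right) / m * scale
}

#' Fractal-dimension shape index
#'
#' For each of five threshold fractions `t_i` of the in-VOI maximum, counts
#' the in-VOI voxels with value `>= t_i * max`, then reports the negated
#' least-squares slope of `ln N_i` against `ln t_i`. Dot-like uptake that
#' shrinks rapidly with threshold scores high; a binary blob whose count is
#' threshold-independent scores 0. Stages with zero count are dropped with
#' a warning; fewer than three surviving stages is an error.
#'
#' @param volume a [spect_volume()].
#' @param mask logical array (typically one pentagonal prism).
#' @param config an [fd_config()].
#' @return the FD value, with the stages used as attribute `stages_used`.
#' @export
fractal_dimension <- function(volume, mask, config = fd_config()) {
  stopifnot(inherits(volume, "spect_volume"), inherits(config, "fd_config"))
  if (!identical(dim(mask), dim(volume$data))) {
    stop("mask and volume grids differ", call. = FALSE)
  }
  vals <- volume$data[mask]
  mx <- max(vals)
  if (!is.finite(mx) || mx <= 0) {
    stop("in-VOI maximum must be positive", call. = FALSE)
  }
  if (config$counting == "2d") {
    slice <- which(apply(mask, 3, function(m) any(m)) &
                     apply(volume$data * mask, 3, max) == mx)[1]
    vals <- volume$data[, , slice][mask[, , slice]]
  }
  t <- config$threshold_fractions
  n <- vapply(t, function(ti) sum(vals >= ti * mx), numeric(1))
  keep <- n > 0
  if (!all(keep)) {
    if (sum(keep) < 3L) {
      stop("fewer than 3 non-empty threshold stages; cannot fit FD",
           call. = FALSE)
    }
    warning(sprintf("%d threshold stage(s) had zero count and were dropped",
                    sum(!keep)))
  }
  lt <- log(t[keep]); ln <- log(n[keep])
  fd <- -sum((lt - mean(lt)) * (ln - mean(ln))) / sum((lt - mean(lt))^2)
  structure(fd, stages_used = which(keep))
}

#' Compute the six-index panel for one volume
#'
#' Orchestrates SBR-Q, PCR-Q, AI-Q (fitted scheme) and SBR-V, FD-V, AI-V
#' (pentagonal scheme) and returns a one-row data frame with per-side SBRs
#' retained.
#'
#' @param volume a [spect_volume()].
#' @param fitted_vois a `fitted_q` [voi_set()].
#' @param pentagonal_vois a `pentagonal_v` [voi_set()].
#' @param config a [panel_config()].
#' @param subject_id subject identifier.
#' @param label optional class label (`"PS"`/`"NPS"` or `NA`).
#' @return one-row data frame with columns `subject_id`, `label`, `sbr_q`,
#'   `pcr_q`, `ai_q`, `sbr_v`, `fd_v`, `ai_v` and the per-side SBR columns.
#' @export
compute_panel <- function(volume, fitted_vois, pentagonal_vois,
                          config = panel_config(), subject_id = "s1",
                          label = NA_character_) {
  stopifnot(inherits(config, "panel_config"))
  sq <- sbr_q(volume, fitted_vois)
  sv <- sbr_v(volume, pentagonal_vois, config$v_str_ml,
              config$sbr_v_formula)
  pc <- pcr(volume, fitted_vois)
  fd <- mean(vapply(c("left", "right"), function(s) {
    as.numeric(fractal_dimension(
      volume, pentagonal_vois$masks[[paste0("striatal_prism_", s)]],
      config$fd))
  }, numeric(1)))
  data.frame(
    subject_id = subject_id, label = label,
    sbr_q = sq$mean, pcr_q = pc$mean,
    ai_q = asymmetry_index(sq$left, sq$right, config$ai_scale_q),
    sbr_v = sv$mean, fd_v = fd,
    ai_v = asymmetry_index(sv$left, sv$right, config$ai_scale_v),
    sbr_q_left = sq$left, sbr_q_right = sq$right,
    sbr_v_left = sv$left, sbr_v_right = sv$right,
    stringsAsFactors = FALSE
  )
}
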