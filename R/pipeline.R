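panel_columns <- c("subject_id", "label", "sbr_q", "pcr_q", "ai_q",
                   "sbr_v", "fd_v", "ai_v")

#' Write / read a SPECT volume as NIfTI-1
#'
#' @param volume a [spect_volume()].
#' @param path `.nii` or `.nii.gz` path.
#' @return the path (write) or a [spect_volume()] (read).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "spect_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- rep(volume$voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  if (max(vox) - min(vox) > 1e-6) {
    stop("volume voxel spacing is not isotropic", call. = FALSE)
  }
  spect_volume(as.array(img), vox[1])
}

#' Write / read index-panel tables as CSV
#'
#' Lossless round trip at 12 significant digits; the schema (columns
#' `subject_id`, `label`, `sbr_q`, `pcr_q`, `ai_q`, `sbr_v`, `fd_v`,
#' `ai_v`) is validated with an error naming the offending column.
#'
#' @param panels panel data frame.
#' @param path CSV path (comma-separated, header, "." decimal, UTF-8).
#' @export
write_panels <- function(panels, path) {
  missing <- setdiff(panel_columns, names(panels))
  if (length(missing)) {
    stop("panel table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- panels[, panel_columns]
  for (cl in panel_columns[-(1:2)]) {
    out[[cl]] <- sprintf("%.12g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(panel_columns, names(df))
  if (length(missing)) {
    stop("panel CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), panel_columns)
  if (length(extra)) {
    stop("panel CSV has unexpected column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (cl in panel_columns[-(1:2)]) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !all(is.na(df[[cl]]))) {
      stop("non-numeric values in column: ", cl, call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: cohort definition, phantom
#' template, index configuration, split/SVM settings and the output
#' directory. Can be loaded from a YAML or JSON file via `config_file`
#' (file keys override the defaults; explicit arguments override the
#' file).
#'
#' @param cohort a [cohort_spec()].
#' @param template a [striatal_template()].
#' @param panel a [panel_config()].
#' @param mode `"tabular"` (draw index panels directly) or `"image"`
#'   (generate phantom volumes and measure them).
#' @param test_fraction,split_seed,svm_seed,c_grid,k_folds SVM stage
#'   settings.
#' @param write_volumes also save each phantom volume as NIfTI (image mode).
#' @param out_dir run output directory.
#' @param config_file optional YAML/JSON file with scalar overrides
#'   (`n_ps`, `n_nps`, `seed`, `mode`, `test_fraction`, `split_seed`,
#'   `svm_seed`, `k_folds`, `v_str_ml`, `out_dir`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            template = striatal_template(),
                            panel = panel_config(),
                            mode = c("tabular", "image"),
                            test_fraction = 0.25, split_seed = 1,
                            svm_seed = 1,
                            c_grid = c(0.01, 0.1, 1, 10, 100),
                            k_folds = 10, write_volumes = FALSE,
                            out_dir = tempfile("datspect_run_"),
                            config_file = NULL) {
  mode <- match.arg(mode)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      stop("config file not found: ", config_file, call. = FALSE)
    }
    ov <- if (grepl("\\.json$", config_file, ignore.case = TRUE)) {
      jsonlite::fromJSON(config_file)
    } else {
      yaml::read_yaml(config_file)
    }
    if (!is.null(ov$n_ps) || !is.null(ov$n_nps) || !is.null(ov$seed)) {
      cohort <- cohort_spec(
        n_ps = ov$n_ps %||% cohort$n_ps,
        n_nps = ov$n_nps %||% cohort$n_nps,
        seed = ov$seed %||% cohort$seed,
        calibration = cohort$calibration,
        correlation = cohort$correlation,
        phantom_params = cohort$phantom_params)
    }
    mode <- ov$mode %||% mode
    test_fraction <- ov$test_fraction %||% test_fraction
    split_seed <- ov$split_seed %||% split_seed
    svm_seed <- ov$svm_seed %||% svm_seed
    k_folds <- ov$k_folds %||% k_folds
    out_dir <- ov$out_dir %||% out_dir
    if (!is.null(ov$v_str_ml)) {
      panel <- panel_config(fd = panel$fd, v_str_ml = ov$v_str_ml,
                            ai_scale_q = panel$ai_scale_q,
                            ai_scale_v = panel$ai_scale_v,
                            sbr_v_formula = panel$sbr_v_formula)
    }
  }
  structure(list(cohort = cohort, template = template, panel = panel,
                 mode = mode, test_fraction = test_fraction,
                 split_seed = as.integer(split_seed),
                 svm_seed = as.integer(svm_seed), c_grid = c_grid,
                 k_folds = as.integer(k_folds),
                 write_volumes = isTRUE(write_volumes), out_dir = out_dir),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulates a cohort (tabular or image mode), trains the two SVM stages
#' (SVM-Q on SBR-Q/PCR-Q/AI-Q, SVM-V on SBR-V/FD-V/AI-V, sharing one
#' stratified split), builds the evaluation report, and writes panels CSV,
#' model JSONs, report CSV, comparisons JSON and a log to the run
#' directory. Reruns with the same configuration reproduce the same
#' outputs. A partial failure leaves a `FAILED` marker file in the run
#' directory.
#'
#' @param config a [pipeline_config()].
#' @return the run directory, invisibly; the report and panels are also
#'   returned as attributes `report` and `panels`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "FAILED")
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline did not complete", marker))
  log <- c(sprintf("datspect %s", as.character(utils::packageVersion("datspect"))),
           sprintf("R %s", R.version.string),
           sprintf("mode=%s n_ps=%d n_nps=%d cohort_seed=%d split_seed=%d svm_seed=%d",
                   config$mode, config$cohort$n_ps, config$cohort$n_nps,
                   config$cohort$seed, config$split_seed, config$svm_seed))
  panels <- if (config$mode == "tabular") {
    tabular_cohort(config$cohort)
  } else {
    if (config$write_volumes) {
      vol_dir <- file.path(config$out_dir, "volumes")
      dir.create(vol_dir, showWarnings = FALSE)
      subjects <- sample_cohort(config$cohort,
                                config$template$grid_shape,
                                config$template$voxel_mm)
      for (i in seq_along(subjects)) {
        ph <- make_striatal_phantom(subjects[[i]]$spec, config$template)
        write_volume(ph$volume,
                     file.path(vol_dir, sprintf("s%03d.nii.gz", i)))
      }
    }
    image_cohort_panels(config$cohort, config$template, config$panel)
  }
  write_panels(panels, file.path(config$out_dir, "panels.csv"))
  stages <- list(
    svm_q = svm_stage(panels, c("sbr_q", "pcr_q", "ai_q"),
                      split_seed = config$split_seed,
                      svm_seed = config$svm_seed,
                      test_fraction = config$test_fraction,
                      c_grid = config$c_grid, k_folds = config$k_folds),
    svm_v = svm_stage(panels, c("sbr_v", "fd_v", "ai_v"),
                      split_seed = config$split_seed,
                      svm_seed = config$svm_seed,
                      test_fraction = config$test_fraction,
                      c_grid = config$c_grid, k_folds = config$k_folds))
  write_svm_model(stages$svm_q$model,
                  file.path(config$out_dir, "model_svm_q.json"))
  write_svm_model(stages$svm_v$model,
                  file.path(config$out_dir, "model_svm_v.json"))
  report <- build_report(panels, stages)
  tab <- report$table
  for (cl in c("auc", "cutoff")) tab[[cl]] <- sprintf("%.12g", tab[[cl]])
  utils::write.csv(tab, file.path(config$out_dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$comparisons,
                       file.path(config$out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  writeLines(c(log, report$note), file.path(config$out_dir, "log.txt"))
  ok <- TRUE
  if (file.exists(marker)) unlink(marker)
  out <- config$out_dir
  attr(out, "report") <- report
  attr(out, "panels") <- panels
  invisible(out)
}
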