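#' Pipeline run configuration
#'
#' Collects every knob of the simulate/measure/analyze pipeline with
#' validated defaults. Configurations can also be loaded from a YAML
#' file with [load_run_config()].
#'
#' @param mask_dir Directory of vessel-mask files (measure step).
#' @param cohort_csv Path to a cohort CSV (analyze step).
#' @param out_dir Output directory.
#' @param spacing Default pixel spacing `c(row, col)` mm, used for PNG
#'   masks without a sidecar and by the simulator (default
#'   `c(0.44, 0.66)`, a typical projected in-plane grid).
#' @param min_branch Spur-pruning threshold, mm (> 0).
#' @param window Tangent-estimation half-window, points (>= 1).
#' @param frame "chord" or "image" frame for angle-based metrics.
#' @param angle_unit "degrees" or "radians" for SD_theta.
#' @param mask_format "nifti" or "png" for simulated masks.
#' @param n_subjects,seed Simulation size and seed.
#' @param id_pattern Regex with one capture group extracting the subject
#'   id from a mask file name (default: stem up to the first underscore).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mask_dir = NULL, cohort_csv = NULL, out_dir = "lsamorph_out",
                       spacing = c(0.44, 0.66), min_branch = 2,
                       window = 3L, frame = c("chord", "image"),
                       angle_unit = c("degrees", "radians"),
                       mask_format = c("nifti", "png"),
                       n_subjects = 125L, seed = 1L,
                       id_pattern = "^([^_]+)_") {
  frame <- match.arg(frame)
  angle_unit <- match.arg(angle_unit)
  mask_format <- match.arg(mask_format)
  if (any(spacing <= 0) || min_branch <= 0 || window < 1L)
    stop("numeric knobs must be positive")
  structure(list(mask_dir = mask_dir, cohort_csv = cohort_csv,
                 out_dir = out_dir, spacing = spacing,
                 min_branch = min_branch, window = as.integer(window),
                 frame = frame, angle_unit = angle_unit,
                 mask_format = mask_format,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), id_pattern = id_pattern),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(package = "lsamorph",
                     version = as.character(utils::packageVersion("lsamorph")),
                     seed = config$seed,
                     config_hash = .config_hash(config)),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write a vessel mask to disk
#'
#' NIfTI masks carry their pixel spacing in the header; PNG masks get a
#' YAML sidecar (`<file>.yaml`) with the spacing, since PNG has no
#' physical-units header.
#'
#' @param mask A [vessel_mask].
#' @param path Output path (`.nii`/`.nii.gz` or `.png`).
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.png$", path)) {
    png::writePNG(mask$raster * 1, path)
    yaml::write_yaml(list(spacing = as.numeric(mask$spacing),
                          origin = as.numeric(mask$origin)),
                     paste0(path, ".yaml"))
  } else {
    img <- RNifti::asNifti(mask$raster * 1L)
    RNifti::pixdim(img) <- c(mask$spacing[1], mask$spacing[2])
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read a vessel mask from disk
#'
#' @param path Mask file (`.nii`/`.nii.gz` or `.png`).
#' @param spacing Fallback spacing (mm) for PNGs without a sidecar.
#' @return A [vessel_mask].
#' @export
read_mask <- function(path, spacing = NULL) {
  if (grepl("\\.png$", path)) {
    ras <- png::readPNG(path)
    if (length(dim(ras)) == 3L) ras <- ras[, , 1]
    side <- paste0(path, ".yaml")
    origin <- c(0, 0)
    if (file.exists(side)) {
      sc <- yaml::read_yaml(side)
      spacing <- sc$spacing
      if (!is.null(sc$origin)) origin <- sc$origin
    }
    if (is.null(spacing)) stop("no spacing for PNG mask ", path,
                               " (no sidecar, no override)")
    vessel_mask(ras > 0.5, spacing, origin)
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    arr <- as.array(img)
    if (length(dim(arr)) > 2L) arr <- arr[, , 1]
    if (!is.null(spacing)) pd <- spacing
    vessel_mask(arr != 0, pd[1:2], c(0, 0))
  }
}

#' Simulate a study: vessel masks plus a cohort table
#'
#' Writes one rasterized curve mask per simulated vessel (a small mix of
#' arcs, sinusoids and splines), a ground-truth CSV with each curve's
#' analytic arc length, chord, distance metric and critical-point count,
#' and a simulated cohort CSV, together with a manifest recording the
#' seed and config hash.
#'
#' @param config A [run_config()].
#' @param n_curves Number of vessel masks to write (default 12).
#' @return Invisibly, a list with the output paths.
#' @export
simulate_study <- function(config = run_config(), n_curves = 12L) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  set.seed(config$seed)
  fams <- rep(c("straight", "circular_arc", "sinusoid", "spline"),
              length.out = n_curves)
  gt <- vector("list", n_curves)
  ext <- if (config$mask_format == "png") ".png" else ".nii.gz"
  for (i in seq_len(n_curves)) {
    chord <- stats::runif(1, 15, 25)
    spec <- switch(fams[i],
      straight = curve_spec("straight", chord),
      circular_arc = curve_spec("circular_arc", chord,
                                arc_angle = stats::runif(1, 0.5, 2.5)),
      sinusoid = curve_spec("sinusoid", chord,
                            amplitude = stats::runif(1, 0.5, 2.5),
                            wavelength = chord / sample(1:3, 1)),
      spline = curve_spec("spline", chord, seed = config$seed + i,
                          wiggle = chord / 12))
    gc <- generate_curve(spec)
    mask <- rasterize_curve(gc$centerline, spacing = config$spacing)
    fn <- file.path(mask_dir, sprintf("sub%03d_vessel%02d%s",
                                      (i - 1L) %/% 3L + 1L, i, ext))
    write_mask(mask, fn)
    gt[[i]] <- data.frame(file = basename(fn), family = fams[i],
                          chord_mm = gc$ground_truth$chord,
                          arc_length_mm = gc$ground_truth$arc_length,
                          dm_true = gc$ground_truth$dm_true,
                          n_critical_true = gc$ground_truth$n_critical_true)
  }
  gt <- do.call(rbind, gt)
  gt_csv <- file.path(config$out_dir, "ground_truth.csv")
  utils::write.csv(gt, gt_csv, row.names = FALSE)
  cohort <- generate_cohort(effect_config(n_subjects = config$n_subjects,
                                          seed = config$seed))
  cohort_csv <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_csv, row.names = FALSE)
  .write_manifest(config$out_dir, config,
                  list(n_curves = n_curves, n_subjects = config$n_subjects))
  invisible(list(mask_dir = mask_dir, ground_truth_csv = gt_csv,
                 cohort_csv = cohort_csv))
}

#' Measure all vessel masks in a directory
#'
#' Runs the mask-to-centerline chain and the tortuosity metrics on every
#' mask file, writing a per-vessel metrics CSV and a per-subject summary
#' CSV. Masks whose skeleton is disconnected (or otherwise fails
#' centerline extraction) are skipped with a warning; the run still
#' succeeds and the skipped files are listed in the manifest.
#'
#' @param config A [run_config()] with `mask_dir` set.
#' @return Invisibly, list with `vessels` and `subjects` data.frames.
#' @export
measure_masks <- function(config) {
  if (is.null(config$mask_dir)) stop("config$mask_dir is not set")
  files <- sort(list.files(config$mask_dir,
                           pattern = "\\.(nii|nii\\.gz|png)$",
                           full.names = TRUE))
  if (!length(files)) stop("no mask files in ", config$mask_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); skipped <- character(0)
  for (f in files) {
    res <- tryCatch({
      mask <- read_mask(f, spacing = config$spacing)
      cl <- mask_to_centerline(mask, min_branch = config$min_branch)
      m <- tortuosity_metrics(cl, window = config$window,
                              frame = config$frame, unit = config$angle_unit)
      stem <- sub("\\.(nii|nii\\.gz|png)$", "", basename(f))
      sid <- if (grepl(config$id_pattern, stem))
        sub(paste0(config$id_pattern, ".*$"), "\\1", stem) else stem
      cbind(data.frame(subject_id = sid, vessel_id = stem,
                       stringsAsFactors = FALSE), m)
    }, error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, basename(f)) else
      rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no mask produced a measurable centerline")
  vessels <- do.call(rbind, rows)
  subjects <- do.call(rbind, lapply(split(vessels, vessels$subject_id),
    function(d) cbind(data.frame(subject_id = d$subject_id[1],
                                 stringsAsFactors = FALSE),
                      summarize_subject(d))))
  rownames(subjects) <- NULL
  utils::write.csv(vessels, file.path(config$out_dir, "vessel_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(subjects, file.path(config$out_dir, "subject_summaries.csv"),
                   row.names = FALSE)
  .write_manifest(config$out_dir, config,
                  list(n_masks = length(files), n_measured = nrow(vessels),
                       skipped = as.list(skipped)))
  invisible(list(vessels = vessels, subjects = subjects))
}

#' Analyze a cohort table
#'
#' Loads the cohort CSV, runs the full comparison grid
#' ([run_full_analysis()]) and writes the results CSV plus a manifest.
#'
#' @param config A [run_config()] with `cohort_csv` set (or a cohort
#'   `data.frame` passed directly as `table`).
#' @param table Optional in-memory cohort table overriding `cohort_csv`.
#' @return Invisibly, the results data.frame.
#' @export
analyze_cohort <- function(config, table = NULL) {
  if (is.null(table)) {
    if (is.null(config$cohort_csv)) stop("config$cohort_csv is not set")
    table <- utils::read.csv(config$cohort_csv)
  }
  res <- run_full_analysis(table)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res, file.path(config$out_dir, "analysis_results.csv"),
                   row.names = FALSE)
  .write_manifest(config$out_dir, config, list(n_comparisons = nrow(res)))
  invisible(res)
}

#' Simulate, measure and analyze in one call
#'
#' @param config A [run_config()].
#' @param n_curves Vessel masks to simulate.
#' @return Invisibly, list with the three stages' outputs.
#' @export
run_full_pipeline <- function(config = run_config(), n_curves = 12L) {
  sim <- simulate_study(config, n_curves = n_curves)
  config$mask_dir <- sim$mask_dir
  config$cohort_csv <- sim$cohort_csv
  meas <- measure_masks(config)
  res <- analyze_cohort(config)
  invisible(list(simulate = sim, measure = meas, analysis = res))
}
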