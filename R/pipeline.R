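#' Pipeline configuration
#'
#' Every tunable of the stitching pipeline in one flat list. Defaults:
#'
#' * `bone_threshold_hu = 150` — standard cortical/cancellous cutoff used
#'   both for spine search scoring and for profile preprocessing.
#' * `rect_half_width = 8`, `rect_half_height = 8`, `reference_slice =
#'   "middle"` — the spine rectangle.
#' * `matcher = "varied"` — scan all overlap widths; `"fixed"` slides a
#'   spine-anchored query window and is the robust choice on noisy scans.
#' * `delta_min = 8` — smallest overlap considered by the varied matcher.
#' * `margin = 0` — columns subtracted once from each truncated edge before
#'   matching and merging (set to at least the deformed band width).
#' * `ap_window = 3`, `si_window = 2` — exhaustive search half-widths; the
#'   marker setup keeps true shifts very small.
#' * `preprocess = TRUE` — match on bone-thresholded profile copies; fusion
#'   always uses original intensities.
#' * `query_len = 32` — fixed-matcher window length.
#' * `mode = "average"`, `fill_value = -1000` — fusion settings.
#' * `keep_fraction = 0.75` — crop fraction used by [run_validate()].
#' * `manual_center_left`, `manual_center_right` — optional `(row, col)`
#'   spine overrides.
#'
#' @param ... name = value overrides of the defaults above.
#' @return A `stitch_config` list.
#' @export
stitch_config <- function(...) {
  cfg <- list(
    bone_threshold_hu = 150,
    rect_half_width = 8L, rect_half_height = 8L,
    reference_slice = "middle",
    manual_center_left = NULL, manual_center_right = NULL,
    matcher = "varied", delta_min = 8L, margin = 0L,
    ap_window = 3L, si_window = 2L,
    preprocess = TRUE, query_len = 32L,
    mode = "average", fill_value = -1000,
    keep_fraction = 0.75
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "stitch_config")
}

## accept a stitch_config or a plain partial list
stitch_config_fill <- function(config) {
  if (inherits(config, "stitch_config")) return(config)
  if (is.null(config)) return(stitch_config())
  do.call(stitch_config, as.list(config))
}

#' Read a pipeline configuration from a YAML file
#'
#' A flat `key: value` file; all keys optional, unknown keys rejected.
#' Values given in `...` override the file.
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file.
#' @return A [stitch_config()].
#' @export
read_stitch_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(list(...))] <- list(...)
  do.call(stitch_config, vals)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    report$stages[[name]] <- "failed"
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
         call. = FALSE)
  }
  report$stages[[name]] <- "succeeded"
  list(report = report, value = res)
}

locate_both_spines <- function(left, right, cfg) {
  rect <- c(cfg$rect_half_width, cfg$rect_half_height)
  list(
    left = locate_spine(left, cfg$bone_threshold_hu, rect,
                        reference_slice = cfg$reference_slice,
                        manual_center = cfg$manual_center_left),
    right = locate_spine(right, cfg$bone_threshold_hu, rect,
                         reference_slice = cfg$reference_slice,
                         manual_center = cfg$manual_center_right)
  )
}

check_compatible <- function(left, right, cfg) {
  if (!isTRUE(all.equal(left$spacing, right$spacing)))
    stop(sprintf(
      "volume compatibility check: spacings differ (%s vs %s mm); resampling is not performed",
      paste(left$spacing, collapse = "x"),
      paste(right$spacing, collapse = "x")), call. = FALSE)
  if (n_rows(left) != n_rows(right) || n_cols(left) != n_cols(right))
    stop("volume compatibility check: row/column extents differ", call. = FALSE)
  invisible(NULL)
}

stitch_volumes <- function(left, right, cfg, report) {
  st <- run_stage(report, "compatibility",
                  check_compatible(left, right, cfg))
  report <- st$report
  st <- run_stage(report, "locate_spine", locate_both_spines(left, right, cfg))
  report <- st$report; spines <- st$value
  st <- run_stage(report, "estimate_offsets",
                  estimate_offsets(left, right, spines$left, spines$right, cfg))
  report <- st$report; offsets <- st$value
  fcfg <- fusion_config(mode = cfg$mode, margin = cfg$margin,
                        fill_value = cfg$fill_value)
  st <- run_stage(report, "fuse", fuse(left, right, offsets, fcfg))
  report <- st$report
  report$spine_left <- spines$left
  report$spine_right <- spines$right
  report$offsets <- offsets
  list(report = report, fused = st$value)
}

new_report <- function(cfg, inputs = character()) {
  structure(list(inputs = inputs, config = cfg, stages = list(),
                 spine_left = NULL, spine_right = NULL, offsets = NULL),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (length(x$inputs)) cat("  inputs:", paste(x$inputs, collapse = ", "), "\n")
  for (s in names(x$stages)) cat(sprintf("  stage %-18s %s\n", s, x$stages[[s]]))
  if (!is.null(x$offsets))
    cat(sprintf("  offsets: delta_si=%d delta_ap=%d delta_rl=%d (rmse %.4g)\n",
                x$offsets$delta_si, x$offsets$delta_ap, x$offsets$delta_rl,
                x$offsets$rmse_min))
  if (!is.null(x$mismatch_count))
    cat(sprintf("  validation: %d mismatched voxel(s), mean |residual| %.4g HU\n",
                x$mismatch_count, x$mean_abs_residual))
  invisible(x)
}

#' Write a run report as plain text
#'
#' A flat `key: value` file echoing every tunable, the detected spine
#' anchors, the offset estimate and the per-stage status — together with the
#' inputs this fully determines the run.
#'
#' @param report a run report from [run_stitch()] or [run_validate()].
#' @param path output text file.
#' @export
write_report <- function(report, path) {
  cfg <- report$config
  lines <- character()
  add <- function(k, v) lines <<- c(lines, sprintf("%s: %s", k, v))
  for (i in seq_along(report$inputs))
    add(paste0("input_", names(report$inputs)[i]), report$inputs[[i]])
  for (k in names(cfg)) {
    v <- cfg[[k]]
    add(k, if (is.null(v)) "default" else paste(format(v), collapse = " "))
  }
  for (s in names(report$stages)) add(paste0("stage_", s), report$stages[[s]])
  for (nm in c("spine_left", "spine_right")) {
    sp <- report[[nm]]
    if (!is.null(sp))
      add(nm, sprintf("slice=%d row=%d col=%d", sp$slice, sp$row, sp$col))
  }
  if (!is.null(report$offsets)) {
    add("delta_si", report$offsets$delta_si)
    add("delta_ap", report$offsets$delta_ap)
    add("delta_rl", report$offsets$delta_rl)
    add("rmse_min", format(report$offsets$rmse_min, digits = 12))
    add("objective", format(report$offsets$objective, digits = 12))
  }
  if (!is.null(report$mismatch_count)) {
    add("mismatch_count", report$mismatch_count)
    add("mean_abs_residual", format(report$mean_abs_residual, digits = 12))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full stitching pipeline on two files
#'
#' read, check compatibility, locate the spine in each scan, estimate the
#' offsets, fuse, and write the fused volume plus a plain-text report next
#' to it (`<output>.report.txt`). Identical inputs and configuration always
#' produce identical outputs.
#'
#' @param left_path,right_path input volumes (NIfTI, MetaImage, or DICOM
#'   directory); left = the scan with the patient's left side complete.
#' @param out_path output volume path (`.nii`, `.nii.gz`, or `.mhd`).
#' @param config a [stitch_config()].
#' @return The run report, invisibly.
#' @export
run_stitch <- function(left_path, right_path, out_path,
                       config = stitch_config()) {
  cfg <- stitch_config_fill(config)
  report <- new_report(cfg, c(left = left_path, right = right_path))
  st <- run_stage(report, "read", list(
    left = read_volume(left_path, side = "left"),
    right = read_volume(right_path, side = "right")))
  report <- st$report
  res <- stitch_volumes(st$value$left, st$value$right, cfg, report)
  report <- res$report
  st <- run_stage(report, "write", write_volume(res$fused, out_path))
  report <- st$report
  write_report(report, paste0(out_path, ".report.txt"))
  invisible(report)
}

#' Retrospective validation on a complete volume
#'
#' The crop-and-reconstruct check: crops a complete volume into left- and
#' right-sided partial scans of `keep_fraction` width each, stitches them
#' back with the configured pipeline, and counts voxel mismatches against
#' the original (0 expected on clean data). Refuses geometries whose crop
#' overlap cannot be matched (`2*keep_fraction - 1` of the width must leave
#' at least `delta_min + 2*margin` columns).
#'
#' @param full a complete [ct_volume()], or a path readable by
#'   [read_volume()].
#' @param config a [stitch_config()].
#' @return A run report with `mismatch_count` and `mean_abs_residual`,
#'   invisibly.
#' @export
run_validate <- function(full, config = stitch_config()) {
  cfg <- stitch_config_fill(config)
  report <- new_report(cfg)
  if (!is_ct_volume(full)) {
    report$inputs <- c(full = full)
    st <- run_stage(report, "read", read_volume(full))
    report <- st$report; full <- st$value
  }
  nc <- n_cols(full)
  overlap <- 2L * round_half_up(cfg$keep_fraction * nc) - nc
  if (overlap - 2L * cfg$margin < cfg$delta_min)
    stop(sprintf(
      "keep_fraction %.3g leaves a crop overlap of %d column(s); at least delta_min + 2*margin = %d are required",
      cfg$keep_fraction, overlap, cfg$delta_min + 2L * cfg$margin),
      call. = FALSE)
  st <- run_stage(report, "crop", list(
    left = crop_volume(full, cfg$keep_fraction, "left"),
    right = crop_volume(full, cfg$keep_fraction, "right")))
  report <- st$report
  res <- stitch_volumes(st$value$left, st$value$right, cfg, report)
  report <- res$report
  fused <- res$fused
  if (!identical(dim(fused$voxels), dim(full$voxels))) {
    report$mismatch_count <- length(full$voxels)
    report$mean_abs_residual <- Inf
  } else {
    resid <- fused$voxels - full$voxels
    report$mismatch_count <- sum(resid != 0)
    report$mean_abs_residual <- mean(abs(resid))
  }
  invisible(report)
}

#' Simulate a double partial acquisition to disk
#'
#' Generates a phantom, splits it with known offsets, writes the two partial
#' volumes (and optionally the complete truth volume) plus a plain-text
#' ground-truth sidecar (`key=value`: delta_si, delta_ap, delta_rl, seed).
#'
#' @param out_dir output directory (created if missing).
#' @param phantom a [phantom_spec()].
#' @param split a [split_spec()].
#' @param format `"nifti"` or `"mhd"`.
#' @param write_full also write the complete phantom as `full.*`.
#' @return Paths of the written files, invisibly.
#' @export
simulate_acquisition <- function(out_dir, phantom = phantom_spec(),
                                 split = split_spec(overlap_cols = 48),
                                 format = c("nifti", "mhd"),
                                 write_full = FALSE) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".mhd"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  full <- generate_phantom(phantom)
  parts <- split_phantom(full, split)
  paths <- c(left = file.path(out_dir, paste0("left", ext)),
             right = file.path(out_dir, paste0("right", ext)),
             truth = file.path(out_dir, "truth.txt"))
  write_volume(parts$left, paths[["left"]], format)
  write_volume(parts$right, paths[["right"]], format)
  writeLines(c(
    sprintf("delta_si=%d", parts$truth$delta_si),
    sprintf("delta_ap=%d", parts$truth$delta_ap),
    sprintf("delta_rl=%d", parts$truth$delta_rl),
    sprintf("seed=%d", split$seed)
  ), paths[["truth"]])
  if (write_full) {
    paths <- c(paths, full = file.path(out_dir, paste0("full", ext)))
    write_volume(full, paths[["full"]], format)
  }
  invisible(paths)
}
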