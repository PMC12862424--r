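#' Generate a phantom and write volume + truth files
#'
#' Orchestration wrapper: generates the phantom of `spec`, writes the
#' label volume (with JSON sidecar) and the truth JSON into `output_dir`,
#' and returns a run report.
#'
#' @param spec A [phantom_spec()], or a list of arguments for it.
#' @param output_dir Output directory (created if missing).
#' @param format `"nii.gz"`, `"nii"` or `"nrrd"`.
#' @param basename File basename (default `"phantom"`).
#' @return Object of class `run_report`.
#' @export
run_phantom <- function(spec = phantom_spec(), output_dir,
                        format = c("nii.gz", "nii", "nrrd"),
                        basename = "phantom") {
  format <- match.arg(format)
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  ph <- generate_phantom(spec)
  vol_path <- file.path(output_dir, paste0(basename, ".", format))
  truth_path <- file.path(output_dir, paste0(basename, "_truth.json"))
  write_volume(ph$volume, vol_path)
  write_truth_json(ph$truth, truth_path)
  new_run_report(config = unclass(spec)[setdiff(names(spec), "frame")],
                 seeds = c(phantom = spec$seed),
                 stage_voxels = c(total = prod(dim(ph$volume$voxels)),
                                  tfcc = sum(ph$volume$voxels == 3L)),
                 outputs = c(volume = vol_path, truth = truth_path),
                 wall_time = c(total = proc.time()[["elapsed"]] - t0))
}

#' Extract and measure insertion footprints from a volume
#'
#' Runs [extract_footprint()] for the deep region (seeded at the fovea
#' landmark) and, when a styloid landmark is supplied, the superficial
#' region, measures each patch with [measure_patch()], and writes a JSON
#' record plus a one-row-per-region CSV table.
#'
#' @param volume A [label_volume()] or a path readable by [read_volume()].
#' @param cfg A [pipeline_config()].
#' @param frame An [anatomical_frame()].
#' @param landmarks Named list of world points; `fovea` seeds the deep
#'   region, `styloid` (optional) the superficial one.
#' @param output_dir Output directory (created if missing).
#' @param basename File basename (default `"footprint"`).
#' @return Object of class `run_report`; the measured records are attached
#'   as attribute `records`.
#' @export
run_extract_measure <- function(volume, cfg = pipeline_config(),
                                frame = anatomical_frame(),
                                landmarks = list(), output_dir,
                                basename = "footprint") {
  if (is.character(volume)) volume <- read_volume(volume)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  regions <- list(deep = landmarks$fovea)
  if (!is.null(landmarks$styloid)) regions$superficial <- landmarks$styloid
  records <- list()
  stage_voxels <- integer(0)
  for (tag in names(regions)) {
    patch <- extract_footprint(volume, cfg = cfg,
                               region_seed = regions[[tag]],
                               region_tag = tag)
    sc <- attr(patch, "stage_counts")
    names(sc) <- paste0(tag, ".", names(sc))
    stage_voxels <- c(stage_voxels, sc)
    records[[tag]] <- measure_patch(patch, frame, cfg)
  }
  tab <- do.call(rbind, lapply(records, as.data.frame))
  json_path <- file.path(output_dir, paste0(basename, "_morphometry.json"))
  csv_path <- file.path(output_dir, paste0(basename, "_morphometry.csv"))
  jsonlite::write_json(lapply(records, unclass), json_path,
                       auto_unbox = TRUE, digits = NA)
  write.csv(tab, csv_path, row.names = FALSE)
  rep <- new_run_report(config = unclass(cfg),
                        seeds = c(ransac = cfg$seed),
                        stage_voxels = stage_voxels,
                        outputs = c(json = json_path, csv = csv_path),
                        wall_time = c(total = proc.time()[["elapsed"]] - t0))
  attr(rep, "records") <- records
  rep
}

#' Run the agreement-statistics layer on measurement tables
#'
#' @param data A data.frame or CSV path. For `mode = "icc"` two numeric
#'   measurement columns; for `mode = "regress"` the response named by
#'   `response` plus predictor columns; ignored for `mode = "power"`.
#' @param mode `"icc"`, `"regress"` or `"power"`.
#' @param response Response column name for regression.
#' @param f2,n,k,alpha Parameters for `mode = "power"` (`n`/`k` default to
#'   the table's dimensions when a table is given).
#' @param output_dir Optional directory; the result is written as JSON.
#' @return The `icc_result`, `regression_result` or `power_result`.
#' @export
run_stats <- function(data = NULL, mode = c("icc", "regress", "power"),
                      response = NULL, f2 = NULL, n = NULL, k = NULL,
                      alpha = 0.05, output_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(data)) {
    data <- tryCatch(read.csv(data),
                     error = function(e) stop_fp(
                       paste0("malformed CSV: ", conditionMessage(e)),
                       "fp_error_input"))
  }
  result <- switch(mode,
    icc = {
      keep <- vapply(data, is.numeric, logical(1)) &
        !tolower(names(data)) %in% c("specimen", "id", "subject")
      if (sum(keep) < 2)
        stop_fp("need two numeric measurement columns", "fp_error_input")
      icc_two_way(data[, which(keep)[1:2]])
    },
    regress = {
      if (is.null(response) || !response %in% names(data))
        stop_fp("regression needs a 'response' column name",
                "fp_error_usage", field = "response")
      fit_multiple_regression(data[[response]],
                              data[setdiff(names(data), response)])
    },
    power = posthoc_power(f2, n, k, alpha))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(output_dir, paste0("stats_", mode, ".json"))
    jsonlite::write_json(unclass(result), out, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  result
}

new_run_report <- function(config, seeds, stage_voxels, outputs,
                           wall_time) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop_fp(paste0("reported outputs missing: ",
                   paste(missing, collapse = ", ")), "fp_error_input")
  structure(list(tool_version = as.character(packageVersion("footprintr")),
                 config = config, stage_voxels = stage_voxels,
                 seeds = seeds, outputs = outputs, wall_time = wall_time),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (footprintr", x$tool_version, ")\n")
  cat("  seeds:", paste(names(x$seeds), x$seeds, sep = "=",
                        collapse = ", "), "\n")
  for (nm in names(x$outputs)) cat("  output", nm, ":", x$outputs[nm], "\n")
  cat(sprintf("  wall time: %.2f s\n", sum(x$wall_time)))
  invisible(x)
}
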