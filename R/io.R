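# Text-format readers/writers: trace CSV + metadata JSON sidecar, diameter
# CSV, ground-truth JSON. Dialect: comma-separated, '.' decimal, UTF-8,
# header row required.

#' Write a trace matrix to CSV with a JSON metadata sidecar
#'
#' CSV layout: column 1 `time_s`, then one column per cell (`cell_001`,
#' ...). The sidecar records `fs_hz`, the genotype/condition and per-cell
#' class labels.
#'
#' @param trace A [trace_matrix()].
#' @param path Output CSV path; the sidecar goes to
#'   `sub(".csv", "_meta.json", path)` unless `meta_path` is given.
#' @param genotype Condition tag stored in the sidecar (e.g. `"wt"`).
#' @param meta_path Optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(trace, path, genotype = NA_character_,
                             meta_path = NULL) {
  stopifnot(inherits(trace, "trace_matrix"))
  df <- data.frame(time_s = trace$time_s, trace$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta_path <- meta_path %||% sub("\\.csv$", "_meta.json", path)
  meta <- list(fs_hz = trace$fs_hz, genotype = genotype,
               cell_ids = trace$cell_ids,
               cell_class = as.list(trace$labels %||%
                                      stats::setNames(
                                        rep(NA_character_,
                                            length(trace$cell_ids)),
                                        trace$cell_ids)))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace CSV (+ optional metadata sidecar)
#'
#' @param path CSV with `time_s` first column, one column per cell.
#' @param meta_path Metadata JSON path; defaults to the `_meta.json`
#'   sidecar next to `path` when it exists.
#' @param fs_hz Sampling rate; required when no sidecar provides it.
#' @return A [trace_matrix()] (with `genotype` attribute when known).
#' @export
read_traces_csv <- function(path, meta_path = NULL, fs_hz = NULL) {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stopf("first column must be time_s")
  meta_path <- meta_path %||% sub("\\.csv$", "_meta.json", path)
  labels <- NULL
  genotype <- NA_character_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    fs_hz <- fs_hz %||% meta$fs_hz
    genotype <- meta$genotype %||% NA_character_
    if (!is.null(meta$cell_class) && length(meta$cell_class))
      labels <- unlist(meta$cell_class)
  }
  if (is.null(fs_hz)) {
    dt <- stats::median(diff(df$time_s))
    fs_hz <- 1 / dt
  }
  tm <- trace_matrix(as.matrix(df[, -1, drop = FALSE]), fs_hz,
                     time_s = df$time_s, labels = labels)
  attr(tm, "genotype") <- genotype
  tm
}

#' Write / read an arteriole-diameter trace CSV
#'
#' Columns `time_s`, `diameter_um`.
#' @param diameter A [vasomotion_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [vasomotion_trace()] (read).
#' @export
write_diameter_csv <- function(diameter, path) {
  stopifnot(inherits(diameter, "vasomotion_trace"))
  utils::write.csv(data.frame(time_s = diameter$time_s,
                              diameter_um = diameter$diameter),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diameter_csv
#' @export
read_diameter_csv <- function(path) {
  if (!file.exists(path)) stopf("diameter file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "diameter_um") %in% names(df)))
    stopf("diameter CSV needs time_s and diameter_um columns")
  fs <- 1 / stats::median(diff(df$time_s))
  vasomotion_trace(df$time_s, df$diameter_um, fs)
}

#' Write the planted ground truth of a simulated recording as JSON
#'
#' @param recording A `simulated_recording`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(recording, path) {
  stopifnot(inherits(recording, "simulated_recording"))
  tr <- recording$truth
  jsonlite::write_json(
    list(cell_class = as.list(tr$cell_class),
         coupling = as.list(tr$coupling),
         spike_times_s = tr$spike_times_s,
         drive_peak_times_s = tr$drive_peak_times_s,
         vaso_lag_s = tr$vaso_lag_s),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a full simulated recording to a directory
#'
#' Emits `traces.csv` + `traces_meta.json`, `diameter.csv` and
#' `ground_truth.json`.
#'
#' @param recording A `simulated_recording`.
#' @param dir Output directory (created if missing).
#' @param genotype Condition tag for the sidecar.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, genotype = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces_csv(recording$traces, file.path(dir, "traces.csv"),
                   genotype = genotype)
  write_diameter_csv(recording$diameter, file.path(dir, "diameter.csv"))
  write_ground_truth_json(recording, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
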