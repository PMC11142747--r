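# End-to-end pipeline orchestration and group-level report tables.

default_run_config <- function() {
  list(
    input = list(traces = NULL, diameter = NULL, genotype = NA_character_),
    baseline = list(method = "percentile", q = 20, window_s = 60),
    detect = list(k_mad = 3, min_interval_s = 2, min_prominence = 0.5,
                  smooth_window_s = 1),
    connectome = list(smooth_window_s = 1, detrend = TRUE,
                      r_threshold = 0.35, hub_rule = "mean_plus_sd",
                      hub_param = 1),
    oscillation = list(expected_period_s = 100 / 3, max_lag_s = 15,
                       min_prominence = 0.5),
    seed = 1,
    out = "mdplaque_out",
    log_level = "info"
  )
}

#' Load a run configuration
#'
#' YAML with a flat `stage.param` namespace (e.g. `detect:` block holding
#' `k_mad`); unspecified values fall back to package defaults. The resolved
#' config is echoed into every output directory, so any analysis is
#' regenerable from manifest + inputs alone.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list of `stage$param` overrides applied last.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path), keep.null = TRUE)
  }
  if (!is.null(overrides))
    cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stages: read traces -> baseline/normalize -> transient detection and
#' per-cell metrics -> connectome -> whole-plaque oscillation (+ vasomotion
#' coupling when a diameter trace is available). Writes every artifact plus
#' a machine-readable `manifest.json`; the same config and inputs give
#' byte-identical non-image outputs.
#'
#' @param config A `run_config` from [read_run_config()], with
#'   `config$input$traces` set.
#' @param out Output directory (overrides `config$out`).
#' @return The output directory, invisibly; the manifest is at
#'   `file.path(out, "manifest.json")`.
#' @export
run_pipeline <- function(config, out = NULL) {
  out <- out %||% config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(out, name)
  }

  if (is.null(config$input$traces))
    stopf("pipeline stage 'read': no input trace file configured")
  raw <- pipeline_stage("read", read_traces_csv(config$input$traces))
  diameter <- NULL
  if (!is.null(config$input$diameter)) {
    if (!file.exists(config$input$diameter))
      stopf("pipeline stage 'read': diameter file not found: %s",
            config$input$diameter)
    diameter <- pipeline_stage("read",
                               read_diameter_csv(config$input$diameter))
  }

  norm <- pipeline_stage("normalize", {
    f0 <- estimate_baseline(raw, method = config$baseline$method,
                            q = config$baseline$q,
                            window_s = config$baseline$window_s)
    normalize_traces(raw, f0)
  })
  utils::write.csv(data.frame(time_s = norm$time_s, norm$values,
                              check.names = FALSE),
                   emit("normalized.csv"), row.names = FALSE)

  events <- pipeline_stage("transients", detect_transients(
    norm, k_mad = config$detect$k_mad,
    min_interval_s = config$detect$min_interval_s,
    min_prominence = config$detect$min_prominence,
    smoo_or_default(config$detect$smooth_window_s)))
  utils::write.csv(events, emit("events.csv"), row.names = FALSE)
  metrics <- pipeline_stage("transients", cell_metrics(events, norm))
  utils::write.csv(metrics, emit("cell_metrics.csv"), row.names = FALSE)

  conn <- pipeline_stage("connectome", {
    corr <- pairwise_correlation(
      norm, smooth_window_s = config$connectome$smooth_window_s,
      detrend = config$connectome$detrend)
    graph <- threshold_graph(corr, config$connectome$r_threshold)
    cls <- if (length(norm$cell_ids) >= 3)
      classify_hub_lone(graph, rule = config$connectome$hub_rule,
                        param = config$connectome$hub_param) else NULL
    list(corr = corr, graph = graph, cls = cls,
         summary = connectivity_summary(graph, corr, cls))
  })
  utils::write.csv(as.data.frame(conn$corr$r), emit("correlation.csv"),
                   row.names = TRUE)
  edges <- which(upper.tri(conn$graph$adjacency) & conn$graph$adjacency,
                 arr.ind = TRUE)
  utils::write.csv(data.frame(
    cell_i = conn$corr$cell_ids[edges[, 1]],
    cell_j = conn$corr$cell_ids[edges[, 2]],
    r = conn$corr$r[edges]), emit("edges.csv"), row.names = FALSE)
  connectome_graph(conn$graph, conn$corr, conn$cls,
                   file = emit("connectome.graphml"))
  if (plot_correlation_heatmap(conn$corr, file.path(out, "heatmap.png")))
    artifacts <- c(artifacts, "heatmap.png")

  osc <- pipeline_stage("oscillation", {
    sig <- whole_md_signal(norm)
    m <- oscillation_metrics(
      sig, expected_period_s = config$oscillation$expected_period_s,
      min_prominence = config$oscillation$min_prominence)
    coup <- if (!is.null(diameter))
      vasomotion_coupling(sig, diameter,
                          max_lag_s = config$oscillation$max_lag_s)
    else NULL
    list(signal = sig, metrics = m, coupling = coup)
  })
  jsonlite::write_json(
    list(dominant_frequency_hz = osc$metrics$dominant_frequency_hz,
         isi_cv = osc$metrics$isi_cv,
         spectral_entropy = osc$metrics$spectral_entropy,
         n_peaks = osc$metrics$n_peaks,
         coupling = if (!is.null(osc$coupling))
           list(lag_s = osc$coupling$lag_s,
                max_xcorr = osc$coupling$max_xcorr) else NULL),
    emit("oscillation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  aligned <- data.frame(time_s = osc$signal$time_s,
                        whole_md_ffo = osc$signal$value)
  if (!is.null(diameter))
    aligned$diameter_um <- stats::approx(diameter$time_s,
                                         diameter$diameter,
                                         xout = osc$signal$time_s,
                                         rule = 2)$y
  utils::write.csv(aligned, emit("whole_md_signal.csv"),
                   row.names = FALSE)

  yaml::write_yaml(unclass(config), emit("config_resolved.yaml"))
  jsonlite::write_json(
    list(package = "mdplaque",
         version = as.character(utils::packageVersion("mdplaque")),
         n_cells = length(norm$cell_ids),
         genotype = attr(raw, "genotype"),
         connectivity = conn$summary[c("connected_fraction",
                                       "mean_offdiag_r", "n_hubs",
                                       "n_lone")],
         artifacts = artifacts),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out)
}

smoo_or_default <- function(x) x %||% 1

#' Group-level descriptive report
#'
#' Mean, SD, SEM (SD / sqrt(n)) and n of each per-cell metric by group —
#' the descriptive summary behind "mean +- SEM" panels. No inferential
#' statistics are computed.
#'
#' @param metrics Per-cell metrics table ([cell_metrics()]), one row per
#'   cell, possibly concatenated across recordings.
#' @param groups Group label per row (e.g. genotype); single-member groups
#'   report `NA` SEM.
#' @param fields Metric columns to summarize.
#' @return `data.frame` with columns group, metric, mean, sd, sem, n.
#' @export
group_report <- function(metrics, groups,
                         fields = c("frequency_hz", "mean_fwhm_s",
                                    "mean_peak_fold",
                                    "cumulative_activity")) {
  if (length(groups) != nrow(metrics))
    stopf("groups length must match metrics rows")
  fields <- intersect(fields, names(metrics))
  if (!length(fields)) stopf("no requested metric columns present")
  out <- list()
  for (g in unique(groups)) {
    sub <- metrics[groups == g, , drop = FALSE]
    for (f in fields) {
      x <- sub[[f]][!is.na(sub[[f]])]
      n <- length(x)
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = f,
        mean = if (n) mean(x) else NA_real_,
        sd = if (n > 1) stats::sd(x) else NA_real_,
        sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
        n = n)
    }
  }
  do.call(rbind, out)
}
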