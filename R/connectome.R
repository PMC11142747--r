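# The MD connectome: all-pairs Pearson correlation of time-lapse Ca2+
# traces, a strict r-threshold adjacency, and hub / lone / regular cell
# classification.

#' All-pairs Pearson correlation of normalized traces
#'
#' Each trace is optionally smoothed (moving average) and linearly
#' detrended before correlation, so slow drift cannot fabricate edges. The
#' preprocessing is recorded in the result's descriptor. Zero-variance
#' traces get `NA` rows/columns (treated as non-edges downstream) and are
#' logged.
#'
#' @param norm A [normalized_trace_matrix()] with >= 2 cells and >= 30
#'   samples.
#' @param smooth_window_s Smoothing window in seconds (0 disables).
#' @param detrend Remove a per-cell linear trend before correlating.
#' @return A `correlation_matrix`: list with `cell_ids`, `r` (symmetric,
#'   unit diagonal) and `preprocessing`.
#' @export
pairwise_correlation <- function(norm, smooth_window_s = 1, detrend = TRUE) {
  stopifnot(inherits(norm, "trace_matrix"))
  v <- norm$values
  if (ncol(v) < 2) stopf("need >= 2 cells")
  if (nrow(v) < 30) stopf("need >= 30 samples")
  if (smooth_window_s > 0)
    v <- apply(v, 2, smooth_vector,
               w = smooth_window_samples(smooth_window_s, norm$fs_hz,
                                         nrow(v)),
               method = "moving_average")
  if (detrend) {
    t0 <- norm$time_s - mean(norm$time_s)
    beta <- crossprod(t0, sweep(v, 2, colMeans(v))) / sum(t0^2)
    v <- v - outer(t0, as.numeric(beta))
  }
  sds <- apply(v, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var))
    log_warn("connectome", sprintf(
      "zero-variance trace(s): %s (entries set missing)",
      paste(norm$cell_ids[zero_var], collapse = ", ")))
  r <- suppressWarnings(stats::cor(v))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- 1
  r <- (r + t(r)) / 2  # enforce exact symmetry
  dimnames(r) <- list(norm$cell_ids, norm$cell_ids)
  structure(list(cell_ids = norm$cell_ids, r = r,
                 preprocessing = sprintf(
                   "smooth_window_s=%g; detrend=%s", smooth_window_s,
                   detrend)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("<correlation_matrix> %d cells; mean off-diagonal r = %.3f (%s)\n",
              length(x$cell_ids), mean(off, na.rm = TRUE),
              x$preprocessing))
  invisible(x)
}

#' Threshold a correlation matrix into a connectivity graph
#'
#' Edge rule: cells i and j are connected iff r(i, j) > `r_threshold`
#' strictly; an exact-threshold value is not an edge. Missing correlations
#' are non-edges.
#'
#' @param corr A `correlation_matrix`.
#' @param r_threshold Pearson r cutoff, strictly inside (-1, 1);
#'   default 0.35.
#' @return A `connectivity_graph`: list with `cell_ids`, boolean
#'   `adjacency`, `degree`, `r_threshold`.
#' @export
threshold_graph <- function(corr, r_threshold = 0.35) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (r_threshold <= -1 || r_threshold >= 1)
    stopf("r_threshold must lie in (-1, 1)")
  adj <- corr$r > r_threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  structure(list(cell_ids = corr$cell_ids, adjacency = adj,
                 degree = stats::setNames(rowSums(adj), corr$cell_ids),
                 r_threshold = r_threshold),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d cells, %d edges at r > %g\n",
              length(x$cell_ids), sum(x$adjacency) / 2, x$r_threshold))
  invisible(x)
}

#' Classify cells as hub, lone or regular
#'
#' Lone cells have zero connections. Hubs are the most-connected cells:
#' under the default `"mean_plus_sd"` rule a hub has degree >=
#' mean(degree) + param * SD(degree) and degree >= 2 (no hubs when all
#' degrees are equal); under `"top_fraction"` a hub lies in the top `param`
#' fraction of degrees, ties included (still requiring degree >= 2).
#'
#' @param graph A `connectivity_graph` with >= 3 cells.
#' @param rule `"mean_plus_sd"` (default) or `"top_fraction"`.
#' @param param SD multiplier (default 1) or top fraction (e.g. 0.15).
#' @return A `cell_classification`: list with per-cell `label` in
#'   {hub, lone, regular} and the `rule` descriptor.
#' @export
classify_hub_lone <- function(graph, rule = c("mean_plus_sd",
                                              "top_fraction"),
                              param = NULL) {
  stopifnot(inherits(graph, "connectivity_graph"))
  rule <- match.arg(rule)
  deg <- graph$degree
  if (length(deg) < 3) stopf("need >= 3 cells to classify")
  label <- rep("regular", length(deg))
  label[deg == 0] <- "lone"
  if (rule == "mean_plus_sd") {
    param <- param %||% 1
    s <- stats::sd(deg)
    if (s == 0) {
      log_warn("connectome", "all degrees equal: no hubs under mean_plus_sd")
      hub <- rep(FALSE, length(deg))
    } else {
      hub <- deg >= mean(deg) + param * s & deg >= 2
    }
  } else {
    param <- param %||% 0.15
    if (param <= 0 || param > 1) stopf("top fraction must lie in (0, 1]")
    cutoff <- stats::quantile(deg, 1 - param, names = FALSE)
    hub <- deg >= cutoff & deg >= 2
  }
  label[hub] <- "hub"
  structure(list(cell_ids = graph$cell_ids,
                 label = stats::setNames(label, graph$cell_ids),
                 rule = sprintf("%s(param=%g)", rule, param)),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  tab <- table(factor(x$label, c("hub", "regular", "lone")))
  cat(sprintf("<cell_classification> %d hub, %d regular, %d lone [%s]\n",
              tab["hub"], tab["regular"], tab["lone"], x$rule))
  invisible(x)
}

#' Connectivity summary of one plaque
#'
#' @param graph A `connectivity_graph`.
#' @param corr The matching `correlation_matrix`.
#' @param classification Optional [classify_hub_lone()] result; computed
#'   with defaults when omitted and >= 3 cells.
#' @return List: `n_cells`, `connected_fraction` (edges / possible pairs),
#'   `mean_offdiag_r`, `n_hubs`, `n_lone`, `degree_histogram`.
#' @export
connectivity_summary <- function(graph, corr, classification = NULL) {
  stopifnot(inherits(graph, "connectivity_graph"),
            inherits(corr, "correlation_matrix"))
  n <- length(graph$cell_ids)
  n_pairs <- n * (n - 1) / 2
  if (is.null(classification) && n >= 3)
    classification <- classify_hub_lone(graph)
  lab <- if (!is.null(classification)) classification$label
         else rep(NA_character_, n)
  list(
    n_cells = n,
    connected_fraction = if (n_pairs > 0)
      sum(graph$adjacency[upper.tri(graph$adjacency)]) / n_pairs else 0,
    mean_offdiag_r = mean(corr$r[upper.tri(corr$r)], na.rm = TRUE),
    n_hubs = sum(lab == "hub", na.rm = TRUE),
    n_lone = sum(graph$degree == 0),
    degree_histogram = table(graph$degree)
  )
}

#' Export the connectome as an igraph / GraphML
#'
#' @param graph A `connectivity_graph`.
#' @param corr Optional `correlation_matrix` to attach edge weights.
#' @param classification Optional [classify_hub_lone()] labels.
#' @param coords Optional n x 2 matrix of cell coordinates carried as
#'   vertex attributes.
#' @param file Optional path; when given, writes GraphML there.
#' @return The `igraph` object, invisibly when `file` is given.
#' @export
connectome_graph <- function(graph, corr = NULL, classification = NULL,
                             coords = NULL, file = NULL) {
  stopifnot(inherits(graph, "connectivity_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency * 1,
                                           mode = "undirected")
  igraph::V(g)$name <- graph$cell_ids
  igraph::V(g)$degree <- as.numeric(graph$degree)
  if (!is.null(classification))
    igraph::V(g)$class <- unname(classification$label)
  if (!is.null(coords)) {
    igraph::V(g)$x <- coords[, 1]
    igraph::V(g)$y <- coords[, 2]
  }
  if (!is.null(corr)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el)) igraph::E(g)$r <- corr$r[el]
  }
  if (!is.null(file)) {
    igraph::write_graph(g, file, format = "graphml")
    return(invisible(g))
  }
  g
}

#' Write the pairwise-correlation heatmap
#'
#' Diverging two-colour gradient (blue -> white -> red over r in [-1, 1]),
#' cells in input order. Device failures (e.g. headless systems without
#' PNG support) degrade to a logged warning.
#'
#' @param corr A `correlation_matrix`.
#' @param file Output PNG path.
#' @return `TRUE` if the file was written, `FALSE` otherwise (invisibly).
#' @export
plot_correlation_heatmap <- function(corr, file) {
  stopifnot(inherits(corr, "correlation_matrix"))
  ok <- tryCatch({
    grDevices::png(file, width = 720, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    n <- length(corr$cell_ids)
    pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
    r <- corr$r
    r[is.na(r)] <- 0
    graphics::image(seq_len(n), seq_len(n), t(r[n:1, , drop = FALSE]),
                    zlim = c(-1, 1), col = pal, axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("Pairwise Pearson r (%d cells)", n))
    graphics::axis(1, seq_len(n), corr$cell_ids, las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(n), rev(corr$cell_ids), las = 2,
                   cex.axis = 0.6)
    TRUE
  }, error = function(e) {
    log_warn("connectome", sprintf("heatmap not written: %s",
                                   conditionMessage(e)))
    FALSE
  })
  invisible(ok)
}
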