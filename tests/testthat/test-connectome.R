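make_norm <- function(values, fs = 4) {
  values <- as.matrix(values)
  colnames(values) <- NULL
  tm <- trace_matrix(values, fs)
  normalized_trace_matrix(tm, rep(1, ncol(values)), "test")
}

test_that("pairwise correlation agrees with the direct two-pass oracle", {
  set.seed(42)
  v <- matrix(abs(rnorm(50 * 200, 10, 2)), 200, 50)
  norm <- make_norm(v)
  r <- pairwise_correlation(norm, smooth_window_s = 0, detrend = FALSE)$r
  # oracle: direct two-pass covariance formula on a sample of pairs
  set.seed(1)
  for (k in 1:40) {
    ij <- sample(50, 2)
    expect_equal(r[ij[1], ij[2]],
                 pearson_oracle(v[, ij[1]], v[, ij[2]]),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(r, tol = 1e-12))
  expect_equal(unname(diag(r)), rep(1, 50))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
})

test_that("identical, negated and hand-computed pairs give known r", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 5, 9)
  n <- 40
  v <- cbind(rep(x, 10), rep(y, 10),
             rep(200 - 10 * x, 10))  # negated copy of column 1 about 200
  v2 <- cbind(a = rep(x, 10) + 0.001 * seq_len(n))  # strictly varying
  norm <- make_norm(cbind(v, v2))
  r <- pairwise_correlation(norm, smooth_window_s = 0, detrend = FALSE)$r
  expect_equal(r[1, 3], -1, tolerance = 1e-12)
  expect_equal(r[1, 2], pearson_oracle(x, y), tolerance = 1e-10)
  # identical traces
  ident <- make_norm(cbind(rep(x, 10), rep(x, 10)))
  expect_equal(pairwise_correlation(ident, smooth_window_s = 0,
                                    detrend = FALSE)$r[1, 2], 1,
               tolerance = 1e-12)
})

test_that("zero-variance cells are flagged missing and become non-edges", {
  set.seed(2)
  v <- cbind(matrix(rnorm(120 * 3, 10), 120, 3), rep(5, 120))
  norm <- make_norm(v)
  expect_message(corr <- pairwise_correlation(norm, smooth_window_s = 0,
                                              detrend = FALSE),
                 "zero-variance")
  expect_true(all(is.na(corr$r[4, -4])))
  expect_equal(corr$r[4, 4], 1)
  g <- threshold_graph(corr, 0.35)
  expect_equal(unname(g$degree[4]), 0)
})

test_that("threshold rule is strict and monotone", {
  ids <- sprintf("c%02d", 1:6)
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- 0.35       # exactly at threshold: no edge
  r[1, 3] <- r[3, 1] <- 0.3500001  # just above: edge
  corr <- structure(list(cell_ids = ids,
                         r = `dimnames<-`(r, list(ids, ids)),
                         preprocessing = "none"),
                    class = "correlation_matrix")
  g <- threshold_graph(corr, 0.35)
  expect_false(g$adjacency[1, 2])
  expect_true(g$adjacency[1, 3])
  expect_error(threshold_graph(corr, 1), "r_threshold")

  # nestedness: raising the threshold never adds edges
  set.seed(7)
  m <- matrix(runif(15 * 15, -1, 1), 15)
  m <- (m + t(m)) / 2; diag(m) <- 1
  ids2 <- sprintf("c%02d", 1:15)
  corr2 <- structure(list(cell_ids = ids2,
                          r = `dimnames<-`(m, list(ids2, ids2)),
                          preprocessing = "none"),
                     class = "correlation_matrix")
  prev <- threshold_graph(corr2, -0.9)$adjacency
  for (thr in seq(-0.6, 0.9, by = 0.3)) {
    cur <- threshold_graph(corr2, thr)$adjacency
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("hub/lone classification follows the degree rules", {
  star <- diag(6) * 0
  star[1, 2:6] <- star[2:6, 1] <- 1
  ids <- sprintf("c%d", 1:6)
  g <- structure(list(cell_ids = ids,
                      adjacency = star == 1,
                      degree = stats::setNames(rowSums(star), ids),
                      r_threshold = 0.35),
                 class = "connectivity_graph")
  cls <- classify_hub_lone(g)
  expect_equal(unname(cls$label), c("hub", rep("regular", 5)))

  # all degrees zero -> all lone, no hubs
  g0 <- g; g0$adjacency[] <- FALSE; g0$degree[] <- 0
  expect_true(all(classify_hub_lone(g0)$label == "lone"))

  # all degrees equal (complete graph) -> no hubs, logged
  gc <- g; gc$adjacency[] <- TRUE; diag(gc$adjacency) <- FALSE
  gc$degree[] <- 5
  expect_message(cl2 <- classify_hub_lone(gc), "no hubs")
  expect_true(all(cl2$label == "regular"))

  # top_fraction includes ties and respects degree >= 2
  cls3 <- classify_hub_lone(g, rule = "top_fraction", param = 0.2)
  expect_equal(sum(cls3$label == "hub"), 1)
})

test_that("planted lone cell is recovered as lone in >= 90% of seeds", {
  hits <- sapply(1:20, function(s) {
    rec <- simulate_plaque(preset("wt", seed = s))
    norm <- normalize_traces(rec$traces)
    g <- threshold_graph(pairwise_correlation(norm), 0.35)
    cls <- classify_hub_lone(g)
    lone_id <- names(which(rec$truth$cell_class == "lone"))
    cls$label[lone_id] == "lone"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("planted coupling hierarchy shows in degrees (high > low)", {
  diffs <- sapply(1:20, function(s) {
    rec <- simulate_plaque(preset("wt", seed = 100 + s))
    norm <- normalize_traces(rec$traces)
    g <- threshold_graph(pairwise_correlation(norm), 0.35)
    cl <- rec$truth$cell_class
    mean(g$degree[cl == "follower_high"]) -
      mean(g$degree[cl == "follower_low"])
  })
  expect_gt(mean(diffs), 0)
})

test_that("time-shuffled cell loses its edges (null degree < 0.5)", {
  rec <- simulate_plaque(preset("wt", seed = 3))
  norm <- normalize_traces(rec$traces)
  set.seed(33)
  degs <- sapply(1:20, function(k) {
    shuf <- norm
    shuf$values[, 5] <- sample(shuf$values[, 5])
    g <- threshold_graph(pairwise_correlation(shuf), 0.35)
    unname(g$degree[5])
  })
  expect_lt(mean(degs), 0.5)
})

test_that("relabeling cells permutes matrix and labels consistently", {
  rec <- simulate_plaque(preset("wt", seed = 6, duration_s = 200))
  norm <- normalize_traces(rec$traces)
  r1 <- pairwise_correlation(norm)
  set.seed(9)
  perm <- sample(length(norm$cell_ids))
  norm2 <- norm
  norm2$values <- norm$values[, perm]
  norm2$cell_ids <- norm$cell_ids[perm]
  norm2$f0 <- norm$f0[perm]
  colnames(norm2$values) <- norm2$cell_ids
  r2 <- pairwise_correlation(norm2)
  expect_equal(r2$r, r1$r[perm, perm], tolerance = 1e-12)
  g1 <- threshold_graph(r1); g2 <- threshold_graph(r2)
  expect_equal(unname(g2$degree), unname(g1$degree[perm]))
})

test_that("connectivity summary and WT > KO connectivity", {
  rec <- simulate_plaque(preset("wt", seed = 7))
  norm <- normalize_traces(rec$traces)
  corr <- pairwise_correlation(norm)
  g <- threshold_graph(corr)
  s <- connectivity_summary(g, corr)
  expect_equal(s$n_cells, 25)
  expect_equal(s$n_lone, sum(g$degree == 0))
  # complete / empty graphs
  gc <- g; gc$adjacency[] <- TRUE; diag(gc$adjacency) <- FALSE
  gc$degree <- stats::setNames(rowSums(gc$adjacency), g$cell_ids)
  expect_equal(connectivity_summary(gc, corr)$connected_fraction, 1.0)
  g0 <- g; g0$adjacency[] <- FALSE; g0$degree[] <- 0
  s0 <- connectivity_summary(g0, corr)
  expect_equal(s0$connected_fraction, 0.0)
  expect_equal(s0$n_lone, 25)

  ko <- simulate_plaque(preset("ngfr_ko", seed = 7))
  ko_s <- connectivity_summary(
    threshold_graph(pairwise_correlation(normalize_traces(ko$traces))),
    pairwise_correlation(normalize_traces(ko$traces)))
  expect_gt(s$connected_fraction, ko_s$connected_fraction)
})

test_that("graph export carries degree/class attributes", {
  rec <- simulate_plaque(preset("wt", seed = 2, duration_s = 200))
  norm <- normalize_traces(rec$traces)
  corr <- pairwise_correlation(norm)
  g <- threshold_graph(corr)
  cls <- classify_hub_lone(g)
  ig <- connectome_graph(g, corr, cls)
  expect_equal(igraph::vcount(ig), 25)
  expect_equal(igraph::V(ig)$degree, unname(g$degree))
  expect_equal(igraph::V(ig)$class, unname(cls$label))
  f <- tempfile(fileext = ".graphml")
  connectome_graph(g, corr, cls, file = f)
  expect_silent_file(f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(ig))
})
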