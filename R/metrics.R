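# Accept either a thresholded_graph or a bare symmetric weight matrix and
# return the pieces the metric kernels need. A bare matrix is treated as
# weighted unless every nonzero entry equals 1.
graph_parts <- function(graph) {
  if (inherits(graph, "thresholded_graph")) {
    w <- graph$adjacency
    weighted <- identical(graph$flavor, "weighted")
    labels <- graph$node_labels
  } else {
    w <- unclass(as.matrix(graph))
    if (any(w < 0)) stop("negative weights are not supported")
    diag(w) <- 0
    weighted <- any(w > 0 & w != 1)
    labels <- rownames(w)
    if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(w)))
  }
  list(w = w, weighted = weighted, labels = labels)
}

# Edge-length matrix for shortest-path metrics: 1 for every binary edge,
# 1/weight for weighted edges (stronger correlation = shorter path).
length_matrix <- function(w, weighted) {
  len <- matrix(0, nrow(w), ncol(w))
  pos <- w > 0
  len[pos] <- if (weighted) 1 / w[pos] else 1
  len
}

#' Clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient. For binary graphs
#' this is `2 * triangles_i / (k_i (k_i - 1))`; nodes of degree < 2
#' contribute 0. Weighted graphs use the geometric-mean-of-triangle-weights
#' form: weights are rescaled by the maximum weight and each triangle
#' contributes the cube root of its weight product, which reduces exactly to
#' the binary definition when all kept weights are 1.
#'
#' @param graph a [threshold_graph()] result or a bare symmetric nonnegative
#'   matrix.
#' @return scalar clustering coefficient (Cp).
#' @export
clustering_coefficient <- function(graph) {
  g <- graph_parts(graph)
  w <- g$w
  k <- rowSums(w > 0)
  s <- if (g$weighted) (w / max(w))^(1 / 3) else (w > 0) * 1
  d3 <- diag(s %*% s %*% s)
  ci <- ifelse(k >= 2, d3 / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all pairs of distinct nodes with a finite
#' distance; disconnected pairs are excluded from the average rather than
#' assigned an arbitrary length, so all thresholds of a sweep remain
#' computable. Weighted graphs use edge length `1/weight`.
#'
#' @inheritParams clustering_coefficient
#' @return scalar characteristic path length (Lp).
#' @export
characteristic_path_length <- function(graph) {
  g <- graph_parts(graph)
  d <- cpp_shortest_paths(length_matrix(g$w, g$weighted))
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("graph has no edges: path length is undefined")
  mean(vals)
}

#' Global, nodal and local efficiency
#'
#' `global_efficiency` is the mean over unordered node pairs of the inverse
#' shortest-path length, with disconnected pairs contributing 0.
#' `nodal_efficiency` returns, for each node, the mean inverse distance to
#' every other node. `local_efficiency` is the mean over nodes of the global
#' efficiency of the subgraph induced by each node's neighbours (0 for nodes
#' of degree < 2). All three lie in `[0, 1]` for binary graphs.
#'
#' @inheritParams clustering_coefficient
#' @return `global_efficiency` and `local_efficiency` return a scalar;
#'   `nodal_efficiency` a named vector over nodes.
#' @export
global_efficiency <- function(graph) {
  g <- graph_parts(graph)
  n <- nrow(g$w)
  if (n < 2) return(0)
  d <- cpp_shortest_paths(length_matrix(g$w, g$weighted))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv[upper.tri(inv)]) / (n * (n - 1) / 2)
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(graph) {
  g <- graph_parts(graph)
  n <- nrow(g$w)
  d <- cpp_shortest_paths(length_matrix(g$w, g$weighted))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  e <- rowSums(inv) / (n - 1)
  names(e) <- g$labels
  e
}

#' @rdname global_efficiency
#' @export
local_efficiency <- function(graph) {
  g <- graph_parts(graph)
  mean(cpp_local_efficiency(length_matrix(g$w, g$weighted)))
}

#' Null-model configuration for small-world normalization
#'
#' Controls the ensemble of degree-preserving rewired random networks used
#' to normalize the clustering coefficient and characteristic path length.
#' 100 nulls with 10 swap attempts per edge are conventional
#' connectome-toolbox settings; both are exposed because the stochastic
#' acceptance simulations run with smaller ensembles.
#'
#' @param n_random number of null networks (>= 1).
#' @param n_swaps_per_edge rewiring intensity: swap attempts per edge.
#' @param seed RNG seed governing the rewiring draws.
#' @return a `null_model_config` list.
#' @export
null_model_config <- function(n_random = 100, n_swaps_per_edge = 10, seed = 1) {
  if (n_random < 1) stop("n_random must be >= 1")
  if (n_swaps_per_edge < 0) stop("n_swaps_per_edge must be >= 0")
  structure(list(n_random = as.integer(n_random),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewired null networks
#'
#' Generates random networks matched to the input on node count, edge count
#' and the exact degree sequence via Maslov-Sneppen double-edge swaps; each
#' proposed swap is rejected if it would create a self-loop or multi-edge.
#' For weighted graphs the topology is rewired and each edge's weight
#' travels with it. Graphs admitting no legal swap (e.g. complete graphs)
#' come back unchanged, with a notice.
#'
#' @inheritParams clustering_coefficient
#' @param config a [null_model_config()].
#' @return list of `n_random` graphs of the same class/flavor as the input.
#' @export
rewire_null <- function(graph, config = null_model_config()) {
  g <- graph_parts(graph)
  w <- g$w
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  weights <- w[ut]
  nswap <- config$n_swaps_per_edge * m
  make_graph <- function(edges, wt) {
    adj <- matrix(0, n, n, dimnames = list(g$labels, g$labels))
    adj[edges] <- wt
    adj[edges[, c(2, 1), drop = FALSE]] <- wt
    if (inherits(graph, "thresholded_graph")) {
      out <- graph
      out$adjacency <- adj
      out
    } else adj
  }
  complete <- m == n * (n - 1) / 2
  if (m < 2 || nswap == 0 || complete) {
    if (complete && config$n_swaps_per_edge > 0)
      message("rewire_null: no legal swap exists (complete graph); ",
              "returning input copies")
    return(replicate(config$n_random, make_graph(ut, weights),
                     simplify = FALSE))
  }
  with_seed(config$seed, {
    lapply(seq_len(config$n_random), function(i) {
      e <- cpp_rewire_edges(ut, n, nswap)
      make_graph(e, weights)
    })
  })
}

# All distance-based metrics from a single shortest-path solve, plus Cp and
# E_loc. Lp is NA for an edgeless graph (no finite pair distances).
graph_metric_bundle <- function(graph) {
  g <- graph_parts(graph)
  len <- length_matrix(g$w, g$weighted)
  d <- cpp_shortest_paths(len)
  n <- nrow(d)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  list(Cp = clustering_coefficient(graph),
       Lp = if (length(vals) > 0) mean(vals) else NA_real_,
       E_glob = if (n >= 2) sum(inv[upper.tri(inv)]) / (n * (n - 1) / 2) else 0,
       E_nodal = stats::setNames(rowSums(inv) / (n - 1), g$labels),
       E_loc = mean(cpp_local_efficiency(len)))
}

# Cp and Lp of a null network (the only two quantities normalization needs).
null_cp_lp <- function(graph) {
  g <- graph_parts(graph)
  d <- cpp_shortest_paths(length_matrix(g$w, g$weighted))
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  c(cp = clustering_coefficient(graph),
    lp = if (length(vals) > 0) mean(vals) else NA_real_)
}

sw_from_bundle <- function(bundle, graph, config) {
  nulls <- rewire_null(graph, config)
  nm <- vapply(nulls, null_cp_lp, numeric(2))
  cp_rand <- mean(nm["cp", ])
  lp_rand <- mean(nm["lp", ])
  if (is.na(cp_rand) || cp_rand == 0)
    stop("mean null clustering coefficient is zero")
  if (is.na(lp_rand) || lp_rand == 0) stop("mean null path length is zero")
  gamma <- bundle$Cp / cp_rand
  lambda <- bundle$Lp / lp_rand
  structure(list(Cp = bundle$Cp, Lp = bundle$Lp, gamma = gamma,
                 lambda = lambda, sigma = gamma / lambda,
                 E_glob = bundle$E_glob, E_loc = bundle$E_loc),
            class = "global_metrics")
}

#' Small-world parameters with null-model normalization
#'
#' Computes the raw clustering coefficient Cp and characteristic path length
#' Lp, normalizes each by its mean over degree-preserving rewired null
#' networks (gamma = Cp / Cp_rand, lambda = Lp / Lp_rand), and forms the
#' small-worldness index sigma = gamma / lambda. Global and local efficiency
#' are carried along unnormalized. sigma > 1 indicates small-world
#' organization: more clustered than random at comparable path length.
#'
#' @inheritParams rewire_null
#' @return a `global_metrics` list with elements `Cp`, `Lp`, `gamma`,
#'   `lambda`, `sigma`, `E_glob`, `E_loc`.
#' @export
small_world_params <- function(graph, config = null_model_config()) {
  bundle <- graph_metric_bundle(graph)
  if (is.na(bundle$Lp))
    stop("graph has no edges: path length is undefined")
  sw_from_bundle(bundle, graph, config)
}

#' Metric curves across a sparsity sweep
#'
#' Evaluates the five global parameters (gamma, lambda, sigma, E_glob,
#' E_loc, plus the raw Cp and Lp underlying the normalization) and the
#' nodal-efficiency vector at every threshold of a sweep. The null-model
#' seed at threshold `t` is derived from the base seed and the threshold
#' index, so curves are reproducible threshold-by-threshold.
#'
#' @param graphs output of [sweep_graphs()].
#' @param config a [null_model_config()]; its `seed` acts as the base seed.
#' @return an object of class `metric_curves`: list with `grid`, `flavor`,
#'   `global` (thresholds x 7 matrix) and `nodal` (thresholds x N matrix).
#' @export
metric_curves <- function(graphs, config = null_model_config()) {
  grid <- attr(graphs, "grid")
  if (is.null(grid)) grid <- vapply(graphs, `[[`, numeric(1), "sparsity")
  if (length(graphs) == 0) stop("empty sweep")
  labels <- graphs[[1]]$node_labels
  gl <- matrix(NA_real_, length(graphs), 7,
               dimnames = list(NULL, c("Cp", "Lp", "gamma", "lambda",
                                       "sigma", "E_glob", "E_loc")))
  nodal <- matrix(NA_real_, length(graphs), length(labels),
                  dimnames = list(NULL, labels))
  for (t in seq_along(graphs)) {
    bundle <- graph_metric_bundle(graphs[[t]])
    if (is.na(bundle$Lp)) {
      # edgeless threshold: efficiencies and Cp are zero, the normalized
      # parameters are undefined
      gl[t, ] <- c(0, NA, NA, NA, NA, 0, 0)
      nodal[t, ] <- 0
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "threshold", t)
    sw <- tryCatch(sw_from_bundle(bundle, graphs[[t]], cfg),
                   error = function(e)
                     stop("threshold ", as.numeric(grid)[t], ": ",
                          conditionMessage(e), call. = FALSE))
    gl[t, ] <- c(sw$Cp, sw$Lp, sw$gamma, sw$lambda, sw$sigma,
                 sw$E_glob, sw$E_loc)
    nodal[t, ] <- bundle$E_nodal
  }
  structure(list(grid = as.numeric(grid),
                 flavor = attr(graphs, "flavor"),
                 global = gl, nodal = nodal),
            class = "metric_curves")
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of metric values over the sparsity grid, the
#' threshold-free scalar used for all subject-level statistics. For a curve
#' constant at `c` over a grid of width `w` the AUC is `c * w`.
#'
#' @param values numeric metric values, one per threshold.
#' @param grid matching sparsity thresholds (>= 2, strictly increasing).
#' @return scalar AUC.
#' @export
curve_auc <- function(values, grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("AUC needs at least 2 grid points")
  if (length(values) != length(grid)) stop("values and grid lengths differ")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' AUC summary of a subject's metric curves
#'
#' @param curves a [metric_curves()] object.
#' @return named numeric vector: `gamma_auc`, `lambda_auc`, `sigma_auc`,
#'   `Eglob_auc`, `Eloc_auc`, then `Enodal_auc_<label>` for every node.
#' @export
auc_summary <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  g <- curves$global
  out <- c(gamma_auc = curve_auc(g[, "gamma"], curves$grid),
           lambda_auc = curve_auc(g[, "lambda"], curves$grid),
           sigma_auc = curve_auc(g[, "sigma"], curves$grid),
           Eglob_auc = curve_auc(g[, "E_glob"], curves$grid),
           Eloc_auc = curve_auc(g[, "E_loc"], curves$grid))
  nodal <- apply(curves$nodal, 2, curve_auc, grid = curves$grid)
  names(nodal) <- paste0("Enodal_auc_", colnames(curves$nodal))
  c(out, nodal)
}

#' @export
plot.metric_curves <- function(x, metrics = c("gamma", "lambda", "sigma"),
                               ...) {
  old <- graphics::par(mfrow = c(1, length(metrics)))
  on.exit(graphics::par(old))
  for (m in metrics)
    graphics::plot(x$grid, x$global[, m], type = "b", xlab = "sparsity",
                   ylab = m, main = paste(x$flavor, m), ...)
  invisible(x)
}

#' Per-subject AUC metric row
#'
#' Convenience wrapper: connectivity -> sparsity sweep -> metric curves ->
#' AUC summary, returned as a one-row data frame.
#'
#' @param conn a [connectivity_matrix()].
#' @param grid a [sparsity_grid()].
#' @param flavor `"binary"` or `"weighted"`.
#' @param config a [null_model_config()].
#' @param subject_id subject identifier for the row.
#' @return one-row `data.frame` with `subject_id`, `flavor` and all AUC
#'   columns.
#' @export
subject_metrics <- function(conn, grid = sparsity_grid(),
                            flavor = c("binary", "weighted"),
                            config = null_model_config(),
                            subject_id = "subject") {
  flavor <- match.arg(flavor)
  curves <- metric_curves(sweep_graphs(conn, grid, flavor), config)
  aucs <- auc_summary(curves)
  cbind(data.frame(subject_id = subject_id, flavor = flavor,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(aucs), check.names = FALSE))
}

#' Subject-by-metric AUC table for a set of connectivity matrices
#'
#' Applies [subject_metrics()] to every subject. Each subject's null-model
#' seed is derived from the base seed, the subject id and the flavor, so
#' adding or removing subjects never perturbs the others' null ensembles.
#'
#' @param conns named list of [connectivity_matrix()] objects (names are
#'   subject ids).
#' @inheritParams subject_metrics
#' @param base_seed integer base seed for null-model derivation.
#' @param verbose log per-subject progress via `message()`.
#' @return `data.frame` with one row per subject (class
#'   `subject_metrics_table`).
#' @export
cohort_metrics <- function(conns, grid = sparsity_grid(),
                           flavor = c("binary", "weighted"),
                           config = null_model_config(),
                           base_seed = config$seed, verbose = FALSE) {
  flavor <- match.arg(flavor)
  if (is.null(names(conns)) || anyDuplicated(names(conns)))
    stop("conns must be a named list with unique subject ids")
  rows <- lapply(names(conns), function(id) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, id, flavor)
    if (verbose) message("metrics [", flavor, "]: ", id)
    subject_metrics(conns[[id]], grid, flavor, cfg, subject_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subject_metrics_table", "data.frame")
  out
}

#' Write / read a subject metrics table
#'
#' CSV with one row per subject: `subject_id`, `flavor`, the five global
#' AUCs and one `Enodal_auc_<label>` column per node.
#'
#' @param tbl a table from [cohort_metrics()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_metrics <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_metrics
#' @export
read_subject_metrics <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  class(out) <- c("subject_metrics_table", "data.frame")
  out
}
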