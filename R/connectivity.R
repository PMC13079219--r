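#' ROI time-series panel
#'
#' Container for one subject's parcellated resting-state signal: a numeric
#' matrix with one row per region of interest (ROI) and one column per time
#' point, plus unique ROI labels. This is the entry point of the pipeline;
#' everything upstream of it (realignment, nuisance regression, filtering,
#' parcellation averaging) is assumed done.
#'
#' @param data numeric matrix, `n_rois x n_timepoints`.
#' @param node_labels character vector of unique ROI names; defaults to the
#'   rownames of `data` or `ROI1..ROIn`.
#' @param subject_id subject identifier.
#' @param allow_constant permit zero-variance rows (correlation with such a
#'   row is undefined, so downstream connectivity will refuse them anyway
#'   unless they are dealt with).
#' @return an object of class `timeseries_panel`.
#' @export
timeseries_panel <- function(data, node_labels = NULL, subject_id = "subject",
                             allow_constant = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("time series contains non-finite values")
  if (is.null(node_labels)) {
    node_labels <- rownames(data)
    if (is.null(node_labels)) node_labels <- paste0("ROI", seq_len(nrow(data)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != nrow(data))
    stop("node_labels length does not match the number of rows")
  if (anyDuplicated(node_labels)) stop("node_labels must be unique")
  if (!allow_constant) {
    v <- apply(data, 1, stats::var)
    if (any(v == 0))
      stop("zero-variance ROI(s): ",
           paste(node_labels[v == 0], collapse = ", "))
  }
  structure(list(subject_id = subject_id, data = data,
                 node_labels = node_labels),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat("<timeseries_panel> subject:", x$subject_id, "-",
      nrow(x$data), "ROIs x", ncol(x$data), "time points\n")
  invisible(x)
}

#' Read one subject's ROI time series from CSV
#'
#' Expects the dialect written by [write_cohort()]: a header row of ROI
#' labels and one row per time point (so the matrix on disk is the transpose
#' of the in-memory ROI-by-time layout).
#'
#' @param path CSV file path.
#' @param subject_id subject identifier; defaults to the file name stem.
#' @inheritParams timeseries_panel
#' @return a [timeseries_panel()].
#' @export
read_timeseries_csv <- function(path, subject_id = NULL, allow_constant = FALSE) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  timeseries_panel(t(as.matrix(df)), node_labels = colnames(df),
                   subject_id = subject_id, allow_constant = allow_constant)
}

#' Symmetric nonnegative connectivity matrix
#'
#' Validates and wraps an edge-weight matrix: symmetric, zero diagonal,
#' entries in `[0, 1]`. This is the form produced by
#' [pearson_connectivity()] after negative-correlation exclusion.
#'
#' @param weights numeric `N x N` matrix.
#' @param node_labels character labels, one per node.
#' @return an object of class `connectivity_matrix` (the matrix itself, with
#'   `dimnames` set and a class attribute).
#' @export
connectivity_matrix <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be exactly zero")
  if (any(weights < 0)) stop("negative entries are not allowed")
  if (any(weights > 1 + 1e-12)) stop("entries must lie in [0, 1]")
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- paste0("ROI", seq_len(n))
  }
  if (length(node_labels) != n || anyDuplicated(node_labels))
    stop("node_labels must be unique and match the matrix dimension")
  dimnames(weights) <- list(node_labels, node_labels)
  class(weights) <- c("connectivity_matrix", "matrix")
  weights
}

#' Pearson connectivity with negative-edge exclusion
#'
#' Computes pairwise Pearson correlations between all ROI time series and
#' sets negative correlations to zero (they are excluded from the network,
#' not analysed as negative edges). The diagonal is forced to zero: a region
#' is not its own neighbour.
#'
#' @param panel a [timeseries_panel()] (or a bare ROI-by-time matrix).
#' @return a [connectivity_matrix()].
#' @export
pearson_connectivity <- function(panel) {
  if (!inherits(panel, "timeseries_panel"))
    panel <- timeseries_panel(panel)
  x <- panel$data
  if (ncol(x) < 3) stop("need at least 3 time points")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI(s): ",
         paste(panel$node_labels[v == 0], collapse = ", "))
  r <- stats::cor(t(x))
  r[r < 0] <- 0
  diag(r) <- 0
  r <- (r + t(r)) / 2   # exact symmetry against floating-point asymmetry
  connectivity_matrix(pmin(r, 1), panel$node_labels)
}

#' Read a precomputed connectivity matrix from CSV
#'
#' For workflows where the `N x N` correlation matrix was computed elsewhere.
#' Negative entries are clipped to zero and the diagonal discarded, mirroring
#' [pearson_connectivity()].
#'
#' @param path CSV with a header row of node labels and `N` numeric rows.
#' @return a [connectivity_matrix()].
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  m[m < 0] <- 0
  diag(m) <- 0
  m <- (m + t(m)) / 2
  connectivity_matrix(m, colnames(df))
}

#' Extract mean ROI time series from a NIfTI image and a labelled parcellation
#'
#' Optional convenience reader: averages the 4D signal over the voxels of
#' each integer label of a parcellation image, yielding the same
#' [timeseries_panel()] contract as the CSV reader. Requires the `RNifti`
#' package.
#'
#' @param image_path path to a 4D NIfTI time series.
#' @param parcellation_path path to a 3D integer-labelled NIfTI in the same
#'   space and grid.
#' @param subject_id subject identifier.
#' @param label_names optional named character vector mapping label integers
#'   to ROI names.
#' @return a [timeseries_panel()].
#' @export
nifti_roi_timeseries <- function(image_path, parcellation_path,
                                 subject_id = "subject", label_names = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("nifti_roi_timeseries requires the RNifti package")
  img <- RNifti::readNifti(image_path)
  parc <- RNifti::readNifti(parcellation_path)
  if (!identical(dim(img)[1:3], dim(parc)[1:3]))
    stop("image and parcellation grids differ")
  nt <- if (length(dim(img)) == 4) dim(img)[4] else 1
  vox <- matrix(as.numeric(img), ncol = nt)
  lab <- as.integer(round(as.numeric(parc)))
  keep <- lab > 0
  labels <- sort(unique(lab[keep]))
  ts <- t(vapply(labels, function(l) colMeans(vox[lab == l, , drop = FALSE]),
                 numeric(nt)))
  nm <- if (!is.null(label_names)) unname(label_names[as.character(labels)])
        else paste0("ROI", labels)
  timeseries_panel(ts, node_labels = nm, subject_id = subject_id)
}

#' Sparsity grid for the threshold sweep
#'
#' The default grid is 0.10 to 0.40 in steps of 0.01 (31 thresholds), the
#' range over which thresholded functional connectomes are commonly both
#' estimable and non-random. Endpoints are inclusive.
#'
#' @param start,stop,step sweep limits and increment, all in (0, 1).
#' @return numeric vector of thresholds with class `sparsity_grid`.
#' @export
sparsity_grid <- function(start = 0.1, stop = 0.4, step = 0.01) {
  if (start <= 0 || stop >= 1 || stop < start)
    stop("require 0 < start <= stop < 1")
  if (step <= 0) stop("step must be positive")
  k <- round((stop - start) / step)
  values <- start + step * seq(0, k)
  if (abs(values[length(values)] - stop) > step / 2)
    values <- c(values, stop)
  values <- round(values, 10)
  structure(values, class = "sparsity_grid", start = start, stop = stop,
            step = step)
}

# Rank the strictly positive upper-triangle edges of a weight matrix:
# decreasing weight, ties broken lexicographically on (i, j) so that
# thresholding is reproducible across platforms.
ranked_edges <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0)
    return(list(i = integer(0), j = integer(0), w = numeric(0)))
  wt <- w[ut]
  o <- order(-wt, ut[, 1], ut[, 2])
  list(i = ut[o, 1], j = ut[o, 2], w = wt[o])
}

#' Sparsity-threshold a connectivity matrix
#'
#' Keeps the `K = round(sparsity * N(N-1)/2)` largest-weight edges among the
#' strictly positive entries (`round` is R's round-half-to-even). The binary
#' flavor sets kept edges to 1; the weighted flavor retains their correlation
#' weights. If fewer than `K` positive edges exist, all are kept and the
#' shortfall recorded.
#'
#' @param conn a [connectivity_matrix()] (or bare symmetric nonnegative
#'   matrix).
#' @param sparsity target edge fraction in (0, 1).
#' @param flavor `"binary"` or `"weighted"`.
#' @return an object of class `thresholded_graph`: a list with `adjacency`,
#'   `sparsity`, `flavor`, `achieved_edges`, `shortfall`, `node_labels`.
#' @export
threshold_graph <- function(conn, sparsity, flavor = c("binary", "weighted")) {
  flavor <- match.arg(flavor)
  if (!(sparsity > 0 && sparsity < 1)) stop("sparsity must lie in (0, 1)")
  w <- unclass(conn)
  n <- nrow(w)
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(n))
  k_target <- round(sparsity * n * (n - 1) / 2)
  re <- ranked_edges(w)
  k <- min(k_target, length(re$w))
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  if (k > 0) {
    sel <- seq_len(k)
    val <- if (flavor == "binary") rep(1, k) else re$w[sel]
    adj[cbind(re$i[sel], re$j[sel])] <- val
    adj[cbind(re$j[sel], re$i[sel])] <- val
  }
  structure(list(adjacency = adj, sparsity = sparsity, flavor = flavor,
                 achieved_edges = k, shortfall = k_target - k,
                 node_labels = labels),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat("<thresholded_graph>", x$flavor, "- N =", length(x$node_labels),
      "- sparsity", x$sparsity, "-", x$achieved_edges, "edges",
      if (x$shortfall > 0) paste0("(shortfall ", x$shortfall, ")") else "",
      "\n")
  invisible(x)
}

#' Threshold a connectivity matrix over a whole sparsity grid
#'
#' @inheritParams threshold_graph
#' @param grid a [sparsity_grid()].
#' @return list of [threshold_graph()] results, ascending in sparsity, with
#'   the grid attached as an attribute.
#' @export
sweep_graphs <- function(conn, grid = sparsity_grid(),
                         flavor = c("binary", "weighted")) {
  flavor <- match.arg(flavor)
  graphs <- lapply(as.numeric(grid), function(s)
    threshold_graph(conn, s, flavor))
  attr(graphs, "grid") <- grid
  attr(graphs, "flavor") <- flavor
  graphs
}
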