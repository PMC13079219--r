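test_that("closed-form graphs reproduce textbook metric values", {
  expect_equal(clustering_coefficient(complete_graph(3)), 1)
  expect_equal(clustering_coefficient(star4()), 0)
  expect_equal(characteristic_path_length(path3()), 4 / 3)
  expect_equal(characteristic_path_length(complete_graph(7)), 1)

  # two disjoint edges: only finite pair distances are the two edges
  disjoint <- sym_graph(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(characteristic_path_length(disjoint), 1)

  expect_equal(global_efficiency(star4()), 0.75)
  expect_equal(unname(nodal_efficiency(star4())), c(1, 2/3, 2/3, 2/3))
  expect_equal(local_efficiency(star4()), 0)
  expect_equal(global_efficiency(complete_graph(4)), 1)
  expect_equal(local_efficiency(complete_graph(4)), 1)
  expect_equal(unname(nodal_efficiency(complete_graph(4))), rep(1, 4))

  # isolated node has zero nodal efficiency
  iso <- sym_graph(4, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(unname(nodal_efficiency(iso))[4], 0)
})

test_that("cycle-with-chord clustering matches exhaustive triangle counting", {
  g <- sym_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
  # node 1 and 3 sit in both triangles (123, 134): local values 2/3, 1, 2/3, 1
  expect_equal(clustering_coefficient(g), 5 / 6)
  expect_equal(oracle_clustering(g), 5 / 6)
  ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected")
  expect_equal(mean(igraph::transitivity(ig, type = "localundirected",
                                         isolates = "zero")), 5 / 6)
})

test_that("metrics agree with brute-force and igraph oracles on random graphs", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    weighted <- rep %% 4 == 0
    w <- random_graph(n, runif(1, 0.2, 0.7), weighted)
    expect_equal(clustering_coefficient(w), oracle_clustering(w, weighted),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(w), oracle_global_eff(w, weighted),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(w)), oracle_nodal_eff(w, weighted),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(w), oracle_local_eff(w, weighted),
                 tolerance = 1e-12)
    if (sum(w) > 0)
      expect_equal(characteristic_path_length(w), oracle_path_length(w, weighted),
                   tolerance = 1e-12)
    # independent library cross-check on the distance structure
    ig <- igraph::graph_from_adjacency_matrix(
      w, mode = "undirected", weighted = if (weighted) TRUE else NULL)
    dig <- igraph::distances(
      ig, weights = if (weighted) 1 / igraph::E(ig)$weight else NULL)
    fin <- is.finite(dig) & dig > 0
    expect_equal(sum(1 / dig[fin]) / (n * (n - 1)), global_efficiency(w),
                 tolerance = 1e-12)
  }
})

test_that("metrics are permutation equivariant", {
  set.seed(9)
  w <- random_graph(10, 0.4)
  rownames(w) <- colnames(w) <- paste0("R", 1:10)
  p <- sample(10)
  wp <- w[p, p]
  expect_equal(clustering_coefficient(w), clustering_coefficient(wp))
  expect_equal(global_efficiency(w), global_efficiency(wp))
  expect_equal(nodal_efficiency(w)[rownames(w)[p]], nodal_efficiency(wp))
})

test_that("weighted metrics reduce to binary when all weights are 1", {
  set.seed(13)
  conn <- random_connectivity(20)
  b <- threshold_graph(conn, 0.25, "binary")
  w <- b
  w$flavor <- "weighted"   # same 0/1 adjacency, weighted formulas
  expect_equal(clustering_coefficient(w), clustering_coefficient(b))
  expect_equal(characteristic_path_length(w), characteristic_path_length(b))
  expect_equal(global_efficiency(w), global_efficiency(b))
  expect_equal(local_efficiency(w), local_efficiency(b))
})

test_that("trapezoid AUC matches closed forms and is linear", {
  grid <- sparsity_grid()
  expect_equal(curve_auc(rep(1, 31), grid), 0.3)
  lin <- seq(0, 1, length.out = 31)
  expect_equal(curve_auc(lin, grid), 0.15)   # triangle: 0.5 * 0.3 * 1
  set.seed(2)
  f <- runif(31); g <- runif(31)
  expect_equal(curve_auc(2 * f + 3 * g, grid),
               2 * curve_auc(f, grid) + 3 * curve_auc(g, grid),
               tolerance = 1e-12)
  expect_error(curve_auc(1, sparsity_grid(0.2, 0.2, 0.1)), "at least 2")
})

test_that("metric curves span the grid and handle edgeless thresholds", {
  set.seed(21)
  conn <- random_connectivity(25)
  curves <- metric_curves(sweep_graphs(conn, sparsity_grid(), "binary"),
                          null_model_config(3, 5, 1))
  expect_equal(nrow(curves$global), 31)
  expect_equal(ncol(curves$nodal), 25)
  expect_true(all(is.finite(curves$global)))
  # binary E_glob non-decreasing in sparsity for nested sweeps
  expect_true(all(diff(curves$global[, "E_glob"]) >= -1e-12))
  expect_true(all(apply(curves$nodal, 2, function(v) all(diff(v) >= -1e-12))))

  empty <- matrix(0, 6, 6)
  g0 <- list(threshold_graph(connectivity_matrix(empty), 0.2),
             threshold_graph(connectivity_matrix(empty), 0.3))
  attr(g0, "grid") <- c(0.2, 0.3)
  c0 <- metric_curves(g0, null_model_config(2, 2, 1))
  expect_equal(unname(c0$global[, "E_glob"]), c(0, 0))
  expect_equal(unname(c0$global[, "E_loc"]), c(0, 0))
  expect_true(all(c0$nodal == 0))
})

test_that("subject metric rows carry the expected AUC columns", {
  set.seed(33)
  conn <- random_connectivity(15)
  row <- subject_metrics(conn, sparsity_grid(0.2, 0.4, 0.1), "binary",
                         null_model_config(3, 5, 2), subject_id = "s1")
  expect_equal(row$subject_id, "s1")
  expect_true(all(c("gamma_auc", "lambda_auc", "sigma_auc", "Eglob_auc",
                    "Eloc_auc", "Enodal_auc_ROI1") %in% colnames(row)))
  expect_equal(row$sigma_auc > 0, TRUE)
})
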