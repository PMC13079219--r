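# Brute-force oracles, independent of the package's compiled kernels.

# Floyd-Warshall in plain R on a length matrix (0 = no edge).
oracle_distances <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  edge <- len > 0 & is.finite(len)
  d[edge] <- len[edge]
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

oracle_length_matrix <- function(w, weighted) {
  len <- matrix(0, nrow(w), ncol(w))
  len[w > 0] <- if (weighted) 1 / w[w > 0] else 1
  diag(len) <- 0
  len
}

# Exhaustive triangle enumeration clustering (Onnela form for weighted).
oracle_clustering <- function(w, weighted = FALSE) {
  n <- nrow(w)
  s <- if (weighted) (w / max(w))^(1 / 3) else (w > 0) * 1
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a == b) next
      j <- nb[a]; h <- nb[b]
      tot <- tot + s[i, j] * s[i, h] * s[j, h]
    }
    ci[i] <- tot / (k * (k - 1))
  }
  mean(ci)
}

oracle_path_length <- function(w, weighted = FALSE) {
  d <- oracle_distances(oracle_length_matrix(w, weighted))
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  mean(v)
}

oracle_global_eff <- function(w, weighted = FALSE) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- oracle_distances(oracle_length_matrix(w, weighted))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv[upper.tri(inv)]) / (n * (n - 1) / 2)
}

oracle_nodal_eff <- function(w, weighted = FALSE) {
  n <- nrow(w)
  d <- oracle_distances(oracle_length_matrix(w, weighted))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  rowSums(inv) / (n - 1)
}

oracle_local_eff <- function(w, weighted = FALSE) {
  n <- nrow(w)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- oracle_global_eff(w[nb, nb, drop = FALSE], weighted)
  }
  mean(e)
}

# Fixture builders -----------------------------------------------------------

sym_graph <- function(n, edges, weights = 1) {
  w <- matrix(0, n, n)
  weights <- rep_len(weights, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    w[edges[i, 1], edges[i, 2]] <- weights[i]
    w[edges[i, 2], edges[i, 1]] <- weights[i]
  }
  w
}

star4 <- function() sym_graph(4, cbind(1, 2:4))
path3 <- function() sym_graph(3, rbind(c(1, 2), c(2, 3)))
complete_graph <- function(n) {
  w <- matrix(1, n, n); diag(w) <- 0; w
}

ring_lattice <- function(n, k) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i + s - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  w
}

random_graph <- function(n, p, weighted = FALSE) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p]
  w[on] <- if (weighted) stats::runif(length(on), 0.1, 1) else 1
  w + t(w)
}

# A positive random "connectivity-like" matrix with all-distinct weights.
random_connectivity <- function(n) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[ut] <- sample(seq_along(ut)) / (length(ut) + 1)
  w <- w + t(w)
  connectivity_matrix(w, paste0("ROI", seq_len(n)))
}
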