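#include <Rcpp.h>
using namespace Rcpp;

// Floyd-Warshall on a dense length matrix. len(i,j) > 0 and finite means an
// edge of that length; anything else means no direct edge. Undirectedness is
// the caller's responsibility (the R layer only ever passes symmetric
// matrices). Connectome graphs here are small (<= a few hundred nodes), so
// O(n^3) on a dense matrix beats repeated heap-based searches once R call
// overhead is counted.
static void floyd_warshall(std::vector<double>& d, int n) {
    for (int k = 0; k < n; ++k) {
        const double* dk = &d[(size_t)k * n];
        for (int i = 0; i < n; ++i) {
            double dik = d[(size_t)i * n + k];
            if (!R_FINITE(dik)) continue;
            double* di = &d[(size_t)i * n];
            for (int j = 0; j < n; ++j) {
                double alt = dik + dk[j];
                if (alt < di[j]) di[j] = alt;
            }
        }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(NumericMatrix len) {
    int n = len.nrow();
    std::vector<double> d((size_t)n * n, R_PosInf);
    for (int i = 0; i < n; ++i) d[(size_t)i * n + i] = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            double l = len(i, j);
            if (l > 0 && R_FINITE(l) && l < d[(size_t)i * n + j])
                d[(size_t)i * n + j] = l;
        }
    floyd_warshall(d, n);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) out(i, j) = d[(size_t)i * n + j];
    return out;
}

// Local efficiency: for each node, the global efficiency of the subgraph
// induced by its neighbours (edge lengths taken from `len`), 0 when the node
// has fewer than two neighbours. Doing the per-node subgraph sweep in one
// call keeps the sparsity sweep tractable.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix len) {
    int n = len.nrow();
    NumericVector eloc(n);
    std::vector<int> nb;
    std::vector<double> d;
    for (int v = 0; v < n; ++v) {
        nb.clear();
        for (int j = 0; j < n; ++j) {
            double l = len(v, j);
            if (j != v && l > 0 && R_FINITE(l)) nb.push_back(j);
        }
        int m = (int)nb.size();
        if (m < 2) { eloc[v] = 0.0; continue; }
        d.assign((size_t)m * m, R_PosInf);
        for (int a = 0; a < m; ++a) {
            d[(size_t)a * m + a] = 0.0;
            for (int b = 0; b < m; ++b) {
                if (a == b) continue;
                double l = len(nb[a], nb[b]);
                if (l > 0 && R_FINITE(l)) d[(size_t)a * m + b] = l;
            }
        }
        floyd_warshall(d, m);
        double s = 0.0;
        for (int a = 0; a < m; ++a)
            for (int b = a + 1; b < m; ++b) {
                double dd = d[(size_t)a * m + b];
                if (R_FINITE(dd) && dd > 0) s += 1.0 / dd;
            }
        eloc[v] = 2.0 * s / ((double)m * (m - 1));
    }
    return eloc;
}

// Degree-preserving double-edge swaps (Maslov-Sneppen). `edges` is an m x 2
// 1-based endpoint matrix of a simple undirected graph; `nswap` swap
// attempts are made, each rejected if it would create a self-loop or a
// multi-edge. Uses R's RNG so set.seed() governs the draw. Edge identity is
// preserved row-wise, so weights attached to rows travel with their edge.
// [[Rcpp::export]]
IntegerMatrix cpp_rewire_edges(IntegerMatrix edges, int n_nodes, int nswap) {
    int m = edges.nrow();
    IntegerMatrix out = clone(edges);
    if (m < 2) return out;
    std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
    for (int e = 0; e < m; ++e) {
        int a = out(e, 0) - 1, b = out(e, 1) - 1;
        adj[(size_t)a * n_nodes + b] = 1;
        adj[(size_t)b * n_nodes + a] = 1;
    }
    for (int s = 0; s < nswap; ++s) {
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 >= m) e1 = m - 1;
        if (e2 >= m) e2 = m - 1;
        if (e1 == e2) continue;
        int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
        int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
        if (unif_rand() < 0.5) std::swap(c, d);
        // propose (a,d) and (c,b)
        if (a == d || c == b) continue;
        if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b]) continue;
        adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
        adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
        adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
        adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
        out(e1, 0) = a + 1; out(e1, 1) = d + 1;
        out(e2, 0) = c + 1; out(e2, 1) = b + 1;
    }
    return out;
}
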