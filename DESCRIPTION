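Package: swtopo
Title: Small-World Topology of Functional Connectomes Across Sparsity Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretical analysis of resting-state functional
    connectomes built from ROI time series. Constructs Pearson correlation
    networks with negative-edge exclusion, sweeps sparsity thresholds to
    obtain binary or weighted graphs, computes small-world parameters
    (clustering coefficient, characteristic path length, gamma, lambda,
    sigma) normalized against degree-preserving rewired null networks,
    global/local/nodal efficiency, and area-under-the-curve summaries across
    the sparsity sweep. Includes a two-group statistical layer
    (normality-gated t / Mann-Whitney comparisons with false-discovery-rate
    correction and covariate-adjusted partial Pearson correlations with
    serum cytokine panels and clinical scores) and a synthetic cohort
    generator with modular correlated time series for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    nortest,
    RNifti
Config/testthat/edition: 3
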