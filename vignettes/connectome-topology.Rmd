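---
title: "Small-world topology of functional connectomes: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world topology of functional connectomes: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`swtopo` implements a graph-theoretical pipeline for resting-state
functional connectomes. Each subject contributes a parcellated ROI-by-time
signal matrix; pairwise Pearson correlations between regional time series
define edge weights; negative correlations are excluded (set to zero)
because their interpretation after global-signal-style preprocessing is
ambiguous. Because correlation networks have no natural edge cutoff, the
network is thresholded at a *sweep* of sparsity values — by default 0.10 to
0.40 in steps of 0.01, keeping the top `round(s * N(N-1)/2)` edges at each
sparsity `s` — and every topological metric is computed at every threshold,
then summarized by the trapezoidal area under its metric-versus-sparsity
curve (AUC). The metrics are the clustering coefficient `Cp` and
characteristic path length `Lp`, their null-normalized forms `gamma =
Cp/Cp_rand` and `lambda = Lp/Lp_rand` (means over degree-preserving rewired
random networks), small-worldness `sigma = gamma/lambda`, and global, local
and nodal efficiency. A statistics layer compares patient and control AUCs
with a normality-gated t / Mann–Whitney test and Benjamini–Hochberg FDR
correction, and relates significant metrics to log10 serum cytokine levels
and clinical scores through partial Pearson correlations controlling for
age, sex and education.

## Graph construction

**Pearson, not partial, correlation.** The construction computes pairwise
Pearson correlations between each pair of ROI time series. Sparse inverse /
partial-correlation connectivity is a different estimator with different
small-sample behaviour and is out of scope here; the negative-edge
exclusion and thresholding conventions below are defined for the pairwise
Pearson matrix.

**Negative-edge exclusion.** Negative correlations are set to zero *before*
thresholding, so they can never be ranked into the retained edge set. The
diagonal never participates.

**Thresholding contract.** At sparsity `s` the pipeline keeps the
`K = round(s * N(N-1)/2)` largest-weight edges among strictly positive
entries (`round` is R's round-half-to-even, a stated and testable
convention). Ties at the K-th rank are broken lexicographically on the
`(i, j)` node indices so results are identical across platforms and runs;
real-valued correlations essentially never tie, but synthetic fixtures can.
If fewer than `K` positive edges exist, all are kept and the shortfall is
recorded rather than padded. Binary graphs set retained edges to 1;
weighted graphs retain the correlation weights on the same support, which
makes the two flavors directly comparable edge-set-by-edge-set. Because the
retained set is a top-K selection, sweeps are nested: every edge present at
sparsity `s` is present at `s' > s`, which in turn guarantees that binary
global and nodal efficiency are non-decreasing along the grid — a property
the tests exploit.

## Metric definitions and degenerate cases

All metrics are defined on undirected graphs with no self-loops.

- **Clustering coefficient.** Binary: mean over nodes of
  `2 * triangles_i / (k_i (k_i - 1))`, zero for degree < 2. Weighted: the
  geometric-mean-of-triangle-weights (Onnela) form on weights rescaled by
  the maximum; it reduces exactly to the binary definition when all kept
  weights are 1.
- **Path length and efficiency.** Weighted edges are converted to lengths
  `1/weight` (stronger correlation = shorter path). `Lp` averages shortest
  path lengths over *finite* pairs only; efficiencies count disconnected
  pairs as zero contribution. These conventions keep every threshold of the
  sweep computable even when low-sparsity graphs fragment, which is routine
  for thresholded connectomes. An edgeless graph has no defined `Lp`
  (explicit error from the scalar function; inside a sweep the efficiency
  curves are zero and the normalized parameters are undefined).
- **Local efficiency** of a node is the global efficiency of the subgraph
  induced by its neighbours (zero for degree < 2); **nodal efficiency** of
  a node is its mean inverse distance to all others.
- The distance kernels (Floyd–Warshall all-pairs, and the per-node
  neighbour-subgraph sweep for local efficiency) are implemented in C++
  because a single cohort analysis evaluates them on tens of thousands of
  graphs; the test suite checks them to 1e-12 against brute-force R oracles
  and igraph on hundreds of random graphs.

## Null-model normalization

`gamma` and `lambda` divide `Cp` and `Lp` by their means over an ensemble
of random networks matched on node count, edge count and the *exact* degree
sequence, generated by Maslov–Sneppen double-edge swaps. Each proposed swap
is rejected if it would create a self-loop or multi-edge. Defaults are 100
null networks with 10 swap attempts per edge — conventional
connectome-toolbox settings; both knobs and the seed are exposed in
`null_model_config()` because the simulation studies use smaller
ensembles. For weighted graphs the topology is rewired and each edge's
weight travels with its edge, so the weight multiset and degree sequence
are both preserved. Graphs admitting no legal swap (complete graphs) are
returned unchanged with a notice, which correctly yields
`gamma = lambda = sigma = 1`.

`sigma` is computed per threshold as `gamma/lambda` and then summarized by
AUC, matching the per-threshold definition of the other metrics; computing
AUCs of `gamma` and `lambda` first and taking their ratio afterwards is a
different (non-equivalent) summary that this package deliberately does not
use.

Null-model seeds are derived per subject and per threshold from the base
seed with a stable string hash (`derive_seed()`), so adding a subject to a
cohort never perturbs any other subject's null ensembles, and reruns are
bit-identical.

## The statistics layer

The gate applies a one-sample Kolmogorov–Smirnov test against a normal
with moment-estimated parameters to each group; if neither group rejects
at 0.05, an equal-variance independent-sample t-test is used, otherwise a
Mann–Whitney U test reported through its tie-corrected normal-approximation
z statistic (no continuity correction by default; both a continuity flag
and an exact-p option exist). The KS-with-estimated-parameters gate is
anticonservative as a normality test — it under-rejects, and therefore
leans toward the t branch; a Lilliefors-corrected gate is available behind
`lilliefors = TRUE`. This is documented rather than silently "fixed"
because the uncorrected gate is what the field's toolboxes conventionally
apply.

FDR correction is Benjamini–Hochberg, applied within three separate
families mirroring how such results are tabulated: the 5 global AUC
metrics, the N nodal efficiency AUCs, and the 17 cytokines. Cytokine
concentrations are base-10 log-transformed before testing; the generator
guarantees positivity so the transform is always defined.

Partial correlations are computed on AUC scalars (not per-threshold
values), restricted to the patient group, between FDR-significant metrics
and FDR-significant cytokines, and between FDR-significant metrics and the
clinical variables (HDRS, YMRS, onset age, number of episodes, illness
duration). The implementation regresses both variables on an intercept
plus covariates (age, sex coded 0 = male / 1 = female, education) and
correlates the residuals; p-values use `n - 2 - k` degrees of freedom.
Correlation p-values are reported uncorrected — the convention in this
literature, where such correlations are exploratory — with a flag marking
which would survive FDR within their family.

## The synthetic cohort generator

No subject-level data are distributed with analyses of this kind, so the
package ships a generator whose draws have the statistical structure the
pipeline assumes, making every stage testable end to end.

- **Time series** are multivariate normal over ROIs with a block
  compound-symmetry correlation: `within_module_r` inside modules (default
  0.3), `between_module_r` between them (default 0.05), 4 modules by
  default; modules absorb remainder nodes front-first when the count does
  not divide the ROI count. Draws are temporally white by default — Pearson
  connectivity depends only on the spatial covariance — with an optional
  variance-preserving AR(1) switch (`ar1_phi`) for workflows that care
  about temporal autocorrelation. Band-pass-filtered hemodynamics, scanner
  noise, motion artefacts and assay detection limits are *not* emulated;
  passing tests demonstrate correctness of the pipeline's statistics, not
  robustness to those real-data features.
- **Patient degradation.** Each patient gets a personal factor
  `d >= 0` (truncated normal, mean `patient_segregation_delta` = 0.15, SD
  0.05) that lowers within-module correlation by `d` and raises
  between-module correlation by `d/3`. The truncation bound keeps
  within ≥ between, which is also the positive-definiteness boundary of
  the block compound-symmetry family; every subject covariance is
  re-checked by Cholesky factorization, and failures name the offending
  parameters. Per-subject variation (rather than one fixed patient
  covariance) is what makes the IL-8 coupling estimable.
- **Cytokines.** Seventeen analytes with fixed baseline log10 means and a
  common log10 SD of 0.25; IL-8, IL-10, G-CSF, MCP-1 and MIP-1beta get a
  +0.2 log10 shift in patients. The default cohort sizes (65/50, cytokine
  subsample 34/30) and the clinical inclusion pattern (HDRS > 20,
  YMRS < 7 in patients) mirror the study design this pipeline targets.
- **IL-8–topology coupling.** `il8_topology_coupling` is a designed
  *correlation* in [-1, 1] between log10 IL-8 and topology integrity
  (default -0.5): the patient's standardized degradation factor enters the
  IL-8 draw with weight `|c|` and the independent noise with weight
  `sqrt(1 - c^2)`, so the IL-8 marginal SD stays at `cytokine_log_sd` and
  the group mean shift is untouched. Standardization uses the realized
  moments of the truncated degradation factors, so truncation cannot leak
  into the IL-8 group difference. The degradation factor lowers `gamma`,
  so a negative coupling yields the designed negative IL-8-versus-`gamma`
  partial correlation.
- **Effect sizes are design choices.** The source literature reports test
  statistics on private data, not effect sizes usable for calibration; the
  defaults above were chosen once as plausible values for a clearly
  detectable deficit at cohort scale and are not estimates of any study's
  true effects.

### What segregation-only degradation can and cannot reproduce

Lowering within-module and raising between-module correlation moves the
patient's thresholded graph *toward a random graph*. That reproduces the
clinical pattern for segregation-type metrics — lower `gamma`, `sigma` and
local efficiency — and for the IL-8 correlation. But a more random graph
has *shorter* paths at fixed edge count, so this mechanism raises global
efficiency and pushes `lambda` toward its random-graph value of 1, leaving
the sign of the `lambda` group difference small and unstable across cohort
conditions, whereas patient cohorts are typically reported with higher
`lambda` and lower global efficiency (a pattern usually attributed to
fragmented or weakened long-range hub connections, a mechanism this
generator does not model). The validation suite therefore asserts recovery
of the `gamma`/`sigma`/`E_loc` deficits and the negative IL-8 coupling,
and does not assert the `lambda`/`E_glob` signs.

## Validation studies and problem sizes

Three seeded simulation studies back the test suite, all desk-scale by
design (200 time points throughout; 7-point sparsity grid 0.10–0.40 in
steps of 0.05 for speed, against the 31-point default used for real
analyses):

1. **Calibration:** 200 null cohorts (no designed effects; 20/20 subjects,
   30 ROIs, 6 nulls per graph). The fraction of cohorts with any
   FDR-significant global metric must sit near the nominal 5%.
2. **Recovery:** 50 effect-bearing cohorts (40/40 subjects, 60 ROIs, 8
   nulls per graph). The `gamma` AUC deficit must be FDR-detected with the
   correct sign in at least 80% of cohorts, and the patient-group partial
   IL-8–`gamma` correlation negative in at least 90%.
3. **Concordance:** 15 effect-bearing cohorts (20/20 subjects, 40 ROIs)
   analysed with both flavors; the sign of the `gamma` and `sigma` group
   statistics must agree between binary and weighted graphs in the large
   majority of cohorts, mirroring the usual binary-versus-weighted
   robustness check.

Unit tests additionally pin every metric to closed-form values on
canonical graphs and to brute-force oracles on hundreds of random graphs,
verify the exact-degree-sequence invariant of every rewired null, and
check the statistics layer against closed forms (step-up FDR, exact
Mann–Whitney enumeration, matrix-inversion partial correlations).

## Known limitations

- The pipeline starts at ROI time series; preprocessing quality (motion,
  nuisance regression, filtering) is assumed and only a motion-exclusion
  helper (`qc_motion_flags()`) is provided as metadata QC.
- Metrics beyond the small-world/efficiency family (modularity, rich-club,
  betweenness, network-based statistics) are out of scope.
- The Mann–Whitney z statistic uses the large-sample normal approximation;
  for very small groups use `exact = TRUE`.
- Null-model ensembles are finite: `gamma`/`lambda` carry Monte-Carlo
  noise of order `1/sqrt(n_random)`; the default of 100 makes this
  negligible relative to between-subject variation, but scaled-down
  ensembles (as in the simulation studies) trade precision for speed.
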