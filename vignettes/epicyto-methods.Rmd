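---
title: "Models and methods behind epicyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epicyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

epicyto analyses single-cell mass-cytometry (CyTOF) profiles of histone
modifications, of the kind produced when an antibody panel targets core
histones (H3, H3.3, H4), a set of histone marks (H3K27me2/3, H3K27ac,
H3K9me2/3, ...) and a few transcription factors (e.g., BCL6) in lymphoma
cell lines or patient-derived samples. This vignette explains the models
the package implements, the assumptions they rest on, the tunable
parameters and their defaults, and the limitations a user should keep in
mind. It states no empirical result beyond what the package's own test
suite and `scripts/acceptance.R` compute.

## Preprocessing model

Per-cell ion counts confound biological signal with the amount of
chromatin captured per cell: a cell with more nucleosomes yields more of
*every* histone-derived ion. The pipeline therefore runs, in order:

1. **Core-histone gate.** Only cells whose every core-histone channel has a
   raw value of at least `min_raw = 5` (inclusive) pass. The bound is read
   as an attainable minimum; the boundary convention is tested explicitly.
2. **arcsinh transform**, `asinh(x / cofactor)` with `cofactor = 5`, the
   standard variance-stabilising transform for cytometry.
3. **Core-histone normalization.** Every column is divided row-wise by
   `1 + alpha*H3.3 + beta*H4 + gamma*H3`, `gamma = 1 - alpha - beta`, where
   the coefficients minimise the sum of the variances of the (transformed)
   core histones themselves. The rationale: core histones are invariant per
   nucleosome, so after removing the per-cell abundance factor their
   variance should be as small as possible; whatever division achieves that
   also removes the same multiplicative factor from the modification
   channels. The denominator uses the arcsinh-transformed core values (the
   division step follows the transform in the pipeline ordering).
4. **Batch-wise z-standardization** of the modification/factor columns
   (mean 0, sd 1 within each acquisition batch); core-histone and other
   non-analyte channels are dropped at this point.

**Feasible set and optimiser.** Only `gamma = 1 - alpha - beta` is forced
by the model; whether negative coefficients should be allowed is not
decidable from the formula alone. We restrict `(alpha, beta)` to the
simplex `alpha >= 0, beta >= 0, alpha + beta <= 1`, which makes all three
weights non-negative mixing coefficients and guarantees a positive
denominator for non-negative arcsinh values. The optimiser is plain
Nelder–Mead from the fixed start `(1/3, 1/3)` with infeasible candidates
rejected by penalty — the objective is a smooth 2-D surface and the fit is
validated against a 50x50 grid-search oracle to 1e-3 in the tests. When
all three core columns are constant the objective is identically zero and
the fit returns the start point. Coefficients are fitted per batch by
default (`pooled = TRUE` fits one global set); whether the original
analysis fitted per batch or globally is not stated anywhere we could
check, so both modes exist and the batch-wise one is the default, matching
the batch-wise scaling convention.

## Synthetic data: what it emulates and what it does not

`default_synthetic_spec()` defines the study conditions used throughout
the tests: a two-genotype design (a WT-like reference and an
EZH2-gain-of-function-like mutant) with

* a per-cell log-normal core-histone factor (`histone_factor_sd = 0.4`)
  multiplying every channel — the systematic effect normalization must
  remove;
* log-scale marker values with a planted 3-edge acyclic dependency graph
  (H3K27me2 -> H3K27me3, H3K9me2 -> H3K27me2, H3K9ac -> H3K27ac, weights
  0.45–0.6) — ground truth for the network module. Dependency effects act
  on centred parent values so planted edges change covariance, not means;
* a mutant with doubled dispersion (`dispersion_scale = 2`), mean shifts
  (H3K27me3 up, H3K27me2 and H3K9me2 down) and a bimodal H3K27me3 with a
  20% minor mode sitting back at the reference level — the 'WT-like'
  subpopulation structure;
* a bell-shaped H3K27me3–BCL6 relationship: the factor's log-value gains
  `curvature * (mark - centre)^2` with `curvature = -0.3`, so binned means
  of BCL6 against H3K27me3 rise then fall;
* fixed per-channel detection efficiencies (0.8–1.2 for the cores),
  mimicking antibody/metal sensitivity differences without free
  parameters.

Marker base means (2.4–3.4 log units against core means 4.2–4.8) and base
sd 0.35 give arcsinh-scale values in the range typical of CyTOF data.
Base values were chosen once as a realistic regime and are not tuned.

The generator does **not** simulate doublets, bead events, barcode
channels, acquisition drift, or zero-inflation. Passing tests on this
generator therefore demonstrate correctness of the algorithms under the
stated statistical structure, not robustness to every artifact of real
acquisitions.

The bell-shaped relationship is planted underneath the shared
histone-abundance factor, so it only becomes visible after normalization —
the tests read it out on preprocessed data, which is also how the analysis
is meant to be run on real data.

## Heterogeneity measures

Populations are compared after a joint 2-D UMAP embedding (via uwot) of
all modification/factor markers, by default across the parameter grid
`n_neighbors in {15, 30, 50, 100} x min_dist in {0.1, 0.3, 0.5}` with a
fixed seed per setting. The exact ranges swept in the original analyses
are not published; the grid is configurable. Populations are subsampled to
equal size before embedding (flag, default on) because embedding density
artifacts would otherwise confound the area measures. Four measures are
computed per population and setting:

* **global area** — area of the convex hull of all the population's
  points, no outlier trimming (a trimming flag exists for sensitivity
  analysis only);
* **global distance** — the 0.95 quantile of all pairwise distances,
  exact up to 5000 points and estimated from 2e6 seeded random pairs
  above that (the estimator is validated against the exact oracle to <2%);
* **local area** — occupied-cell area of a 100x100 grid spanning the joint
  bounding box with `min_count = 1`; grid resolution and count threshold
  are reported with results. For heavy-tailed (e.g., Gaussian) point
  clouds the occupied area of the tails keeps growing slowly with n, so
  ratios between equal-sized populations are meaningful but absolute
  areas are resolution- and n-dependent;
* **NND** — each point's distance to its nearest same-population
  neighbour (kd-tree, validated against the O(n^2) oracle), summarised
  between populations by the ratio of empirical CDFs on a grid; grid
  points where the denominator CDF is zero are reported as undefined
  rather than 0 or infinity. Ratios below 1 mean the test population's
  NNDs are stochastically larger, i.e. it is more dispersed.

All four are invariant to rigid motions of the embedding; areas scale as
c^2 and distances as c under uniform scaling — these invariances are
property-tested. Per-marker Gini coefficients (computed on values shifted
to non-negative, by the sorted-form identity of the mean-absolute-
difference definition) measure single-marker inequality independently of
the embedding. Whether NND/areas should also be computed in the full
marker space is left open by the source material; embedding space is the
default and a full-space variant can be had by passing coordinates
directly.

The transcriptional analogue samples `n_sub = 300` cells per sample
`reps = 200` times, records the mean pairwise Euclidean distance on the
expression matrix each time, and compares two samples with Welch's
unequal-variance t test.

## Network reconstruction

Three complementary models turn cell-to-cell covariation of marks into a
directed or undirected influence matrix (rows = source, columns = target;
factor and cell-cycle channels are excluded by default):

1. **Gradient boosting + Shapley attributions.** Each marker is regressed
   on all others with an xgboost tree ensemble (squared-error loss; depth
   4, 100 trees, learning rate 0.1 — conventional defaults, recorded in
   the output metadata since the original settings are unpublished), on a
   seeded subsample of cells per iteration; TreeSHAP attributions are
   averaged as mean absolute value per feature (a signed mode exists
   behind a flag; magnitudes cannot cancel, which is what an influence
   score needs). The default 500 iterations (subsample 1000) is a
   desk-scale stand-in for the full-scale >10,000; entries are ensemble
   means, so their standard error shrinks as 1/sqrt(iterations).
2. **Link probability.** Each feature is discretized into 20 uniform bins
   over its full range; per iteration a DAG is learned on a subsample by
   hill climbing (add/delete/reverse moves, parent cap 3) with a BIC
   score for multinomial nodes, and the adjacency entry is the fraction
   of iterations containing that directed edge. With 20 bins the BIC
   penalty for acquiring a first parent is `0.5 * log(n) * 19^2 * ...`,
   so subsamples of ~1000 cells admit only very strong edges; the
   subsample size is a config knob and analyses aiming at moderate
   dependencies should use 2000–2500. Edge *direction* from observational
   data is identifiable only up to the DAG equivalence class — tests
   therefore score the symmetrized adjacency.
3. **Partial correlations**, computed from the precision matrix (equal to
   residual-correlation by definition; the equivalence is tested to
   1e-8), with an optional ridge term for singular covariances.

`compare_networks()` reports the Spearman rank correlation of symmetrized
edge scores and top-k edge overlap between any two models.

## Markov model of H3K27 dynamics

States are `unmodified, me1, me2, me3, ac` with the minimal chemically
sensible moves: stepwise methylation `unmodified <-> me1 <-> me2 <-> me3`,
acetylation `unmodified <-> ac`, methylation and acetylation mutually
exclusive; all other transitions are exactly zero. The true state set and
transition values of the original simulation are not published; the matrix
is fully user-editable and this default is a documented reconstruction,
not a claim of equivalence.

Each cell holds a pool of nucleosomes (defaults: 5000 cells x 3e7
nucleosomes, 1000 steps) evolved independently, so one step is exactly a
multinomial redistribution of the per-state counts; we draw it as a chain
of conditional binomials, which is vectorised over cells and conserves
counts exactly. Initial fractions are uniform on the simplex
(Dirichlet(1,...,1)) — the flat choice absent any stated law.

**Calibration.** The allowed-move graph is a tree, so every stationary
chain on it is reversible and detailed balance holds edge by edge:
`pi_i P_ij = pi_j P_ji`. `calibrate_transition()` exploits this: forward
(methylation/acetylation) moves get `base_move = 0.2` and each reverse
move gets `base_move * pi_from / pi_to`, making the target distribution
exactly stationary — no search needed. A corollary fixes the model's
logic: demethylation < methylation on every edge *if and only if* the
stationary fractions increase along the methylation chain. Targets that
violate this (or that push a reverse rate beyond the row budget) are
rejected as infeasible. The default target
(`unmodified 0.10, me1 0.15, me2 0.25, me3 0.40, ac 0.10`) is a
writer-dominant steady state chosen once on that constraint.

**Attribution asymmetry.** At stationarity each cell's state-count vector
is multinomial, and for a multinomial the regression slope of state j on
state i scales differently than the reverse when `pi_j != pi_i`; under
writer dominance (`pi_me3 > pi_me2`) this predicts a stronger
me2 -> me3 attribution than the reverse. `asymmetry_analysis()` runs the
simulate-then-attribute cycle repeatedly: the unmodified state is excluded
from the features (it is not measurable by CyTOF, and including every
state would make each target an exact linear function of the others
through the sum-to-one constraint); the last 10 recorded stationary
snapshots are pooled (each is an equally valid draw of the population, so
pooling reduces estimator noise without changing the expectation); and the
attribution is ensemble-averaged over random subsamples, the same device
the full-scale analysis uses for robustness. A symmetric random walk
(equal up/down rates, uniform stationary distribution) makes the pooled
features exchangeable, so the attribution difference is centred at zero —
the tests check both directions. Steady state is declared when the mean
state fractions change by less than `1e-4` plus the multinomial noise
floor `10 / sqrt(nucleosomes * n_cells)` over the last 10 recorded steps;
the floor matters only for scaled-down runs.

## Subpopulation analyses

* **'WT-like' fraction.** "Overlap with the reference distribution" is
  operationalised as membership in the central `coverage = 0.99` quantile
  interval of the reference marker (a raw min–max overlap rule would be
  outlier-fragile; coverage is a config key reported with results). Note
  an identifiability limit: a central-99% interval reaches 2.58 sd, so
  when the 'extreme' mode sits closer than ~4–5 sd to the reference the
  recovered fraction is biased upward by mode leakage regardless of
  sample size. The fraction is monotone non-decreasing in coverage, which
  is property-tested. Whether the original gate was the 1-D marker
  overlap or joint-embedding cluster membership is ambiguous in the
  source; the 1-D overlap is the default and the cluster route can be
  assembled from the heterogeneity module.
* **Contrast tables.** Per-marker mean differences (extreme - WT-like,
  and each versus a reference population) with bootstrap standard errors
  (1000 resamples, percentile convention, seeded).
* **Binned mean curves.** Equal-width bins over the x-marker
  (default 20 bins), per-bin mean/SEM/count of the y-marker, bins under
  `min_count = 50` masked. The bell-shaped H3K27me3–BCL6 readout is
  "exactly one sign change in the first differences of unmasked bin
  means".
* **Mean-difference tables** for group pairs, antisymmetric by
  construction, with the same bootstrap convention.

## Scaling choices in tests and acceptance runs

All tests run on generated data. Problem sizes were chosen as the
smallest at which each property is comfortably identifiable rather than at
the full scale of a real acquisition: heterogeneity recovery embeds 2 x
5000 cells over the 12-setting grid; network recovery uses 5000 cells
with 20 shap iterations / 200 link-probability iterations (entries are
ensemble proportions, so precision follows binomial scaling); the Markov
asymmetry runs 500 cells x 1e5 nucleosomes x 300 steps with 50 repeats;
fraction-recovery and bell-curve checks use 5000–20,000 cells. The
acceptance script reruns the same designs from scratch at these sizes.

## Known limitations

* FCS support covers list-mode float/integer FCS 3.0/3.1 with one data
  segment — the common CyTOF export shape — not the full standard; events
  are assumed de-barcoded and bead-gated upstream.
* The link-probability model inherits the coarse 20-bin discretization;
  weak dependencies need large subsamples to clear the BIC penalty.
* Occupied-grid "local area" is resolution-dependent; compare only equal-n
  populations on a shared grid (the report does this by construction).
* The Markov state set and transition values are a reconstruction; only
  the writer-dominance constraint and the population/step counts are
  anchored.
* Directionality in the two directed network models reflects ensemble
  frequency, not causal identification.
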