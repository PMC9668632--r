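---
title: "Dynamic connectivity states: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfcstates)
```

## The analysis in one paragraph

`dfcstates` implements a time-resolved functional-connectivity (FC) analysis
of resting-state component time-courses. Pairwise Pearson correlations are
computed in sliding windows (22 TR, slide 1 TR at TR = 2.25 s), Fisher-Z
transformed, and vectorized as the lower triangle of the component-pair
matrix (1081 pairs for 47 components). Windowed FC vectors from all
participants are pooled and clustered with city-block (L1) k-means into
recurrent whole-brain connectivity states; the state count is chosen by
convergence of an elbow criterion with Dunn's cluster-validity index, and
state identities are re-coded by descending total occupancy. Per
participant, temporal metrics (fraction time, mean dwell time, stickiness,
transition counts), state-wise average connectivity and signed Louvain
modularity, and across-state overall connectivity (ASOC: grand,
intra-network, inter-network) are derived. Clinical heterogeneity is
summarised as seven impairment-coded domain z-scores, patients are split by
EDSS percentiles, and inference uses permutation T-tests, age-residualised
Kruskal-Wallis tests with Dunn's post-hoc comparisons, and age-controlled
Spearman partial correlations — each with Benjamini-Hochberg correction
inside explicitly declared families.

## Sliding-window FC

Window `m` (0-based) covers TRs `[m*s, m*s + w)`. Within a window the
pairwise Pearson correlation matrix is computed (optionally weighted by a
rectangular window convolved with a Gaussian of sigma = 3 TR — the taper is
a switch because common practice varies), clipped to `|r| <= 1 - 1e-7`, and
arctanh-transformed. The clipping bound keeps perfectly correlated pairs
finite (about ±8.4) while preserving the ordering of all correlations.
Pair order is the column-major lower triangle, fixed once and used by every
module: `(2,1), (3,1), ..., (n,1), (3,2), ...`.

## State clustering

K-means uses the city-block distance with **coordinate-wise median** centroid
updates — the true L1 minimiser, keeping the assignment and update steps
internally consistent. Empty clusters are re-seeded at the point farthest
from its current centroid. The best of `n_init = 20` k-means++-style
restarts (by total within-cluster L1 cost) is kept; everything is
deterministic under the seed.

Two practical choices matter at cohort scale:

* **Exemplar windows.** With a slide of 1 TR, adjacent windows share 21 of
  22 TRs. Near-duplicate windows astride a state boundary collapse the
  minimum between-cluster distance in Dunn's index for every k and slow the
  scan. The k scan therefore runs on non-overlapping exemplar windows
  (window stride = window length), mirroring the two-stage
  exemplar-then-full procedure standard in the sliding-window dFC
  literature. The final clustering at the chosen k refits the full pooled
  window set, initialised from the exemplar-stage centroids.
* **Elbow operationalisation.** The elbow is defined in two parts. If the
  per-k cost drop from the single-cluster solution down to the smallest
  candidate k is more than three times the next marginal drop, the smallest
  candidate is the elbow (a chord criterion cannot select the boundary of
  its own scan range). Otherwise the elbow is the k whose normalised cost
  lies farthest below the chord joining the endpoints of the scanned curve
  (the L-method). A raw second difference of the cost curve was rejected
  during design: with unequal state occupancies the second difference is
  dominated by how much mass each split relocates and systematically picks
  too-small k, whereas the chord distance finds the steep-to-flat
  transition.

Dunn's index is the minimum between-cluster point distance divided by the
maximum within-cluster diameter (city-block metric, min/max linkage). It is
computed once per scan from the exemplar pairwise distances. When the
elbow and Dunn candidates agree, that k is returned; otherwise the elbow k
is returned with a divergence flag. On windowed FC data the min-linkage
numerator is intrinsically noisy, so occasional divergence flags at the
true k are expected and documented behaviour.

## Temporal metrics and ASOC

For a per-window label sequence: fraction time is the share of windows per
state; mean dwell time is the mean maximal run length; stickiness counts
adjacent same-state window pairs; transition counts tally ordered switches
(with unordered pair totals, which the group tests use). The identities
`sum(stickiness) + sum(transitions) = n_windows - 1` and
`fraction_time = (stickiness + n_runs) / n_windows` are enforced by
property tests.

ASOC averages a participant's windowed Fisher-Z values over **all** windows
irrespective of state: one grand mean over all pairs, one intra-network
mean per network with at least two components (7 under the default
assignment, whose basal-ganglia network has a single component), and one
inter-network mean per network (pairs with exactly one member in the
network — the network's overall connectivity with the rest of the brain),
plus pairwise network-to-network means used to decompose inter-network
effects. Grand ASOC equals the occupancy-weighted mean of per-state average
connectivities, which is exactly why time spent in a high-connectivity
state drives overall connectivity.

Modularity is computed per participant per state on the median per-state FC
matrix with a community Louvain algorithm written for signed weighted
graphs: positive and negative subnetworks enter the quality function with
weights `1/v+` and `1/(v+ + v-)` (the asymmetric signed treatment;
absolute-value and zero-clip rules are selectable). The implementation adds
two robustness devices to plain greedy Louvain — single-node moves may open
a fresh singleton community, and half of the seeded restarts begin from a
random coarse partition — which in tests makes the attained Q match the
exhaustive-partition optimum on all small-graph fixtures.

## Clinical domains and the EDSS split

Each raw test is z-scored across patients (n−1 SD); domain composites are
available-case means of their tests; vision, cognition, and brain-volume
composites are multiplied by −1 so every domain is an impairment index
(higher = worse). Patients are split at the nearest-rank 30th/70th EDSS
percentiles; patients whose EDSS equals the sample median are excluded from
the two-group comparison (on the reference cohort structure this reproduces
the realised cut of EDSS ≤ 1 vs ≥ 2 with median-tied 1.5 excluded). EDSS is
validated to the 0–10 grid in 0.5 steps.

## Statistical framework

* **Permutation T-tests**: Welch statistic (robust to unequal variances; the
  permutation framework is valid either way) with uniformly permuted group
  labels and the add-one p-value `(1 + #{|T*| >= |T|}) / (1 + n_perm)`,
  which can never return 0. Mass-univariate FC tests share one set of label
  permutations across the 1081 pairs.
* **Families**: BH correction is applied independently within declared
  families — per group pair for static FC (1081 tests), per group pair and
  state for dynamic FC, per state and domain for FC-clinical correlations
  (35 families of 1081 = 37,835 tests on the default fixture), per
  state-metric for the three pairwise Dunn tests, and over the seven domain
  comparisons.
* **Age control** follows two distinct paths, as the group tests and the
  correlation analyses require: metrics/ASOC are residualised on age and
  the residuals enter Kruskal-Wallis + Dunn's post-hoc tests (tie-corrected,
  BH over the three pairs; the omnibus gate is a policy flag, with all
  pairwise tests computed by default); FC-clinical associations use
  rank-then-partial Spearman correlations controlling for age, with p from
  the t approximation at n − 3 df and pairwise deletion of missing data.

## The synthetic cohort generator

No deposited data exist for this design, so the generator is a first-class
module emulating the statistical structure the analysis assumes:

* **State process**: a TR-resolution Markov chain over k = 5 states with
  self-transition probabilities 0.985, 0.980, 0.975, 0.970, 0.960 (mean
  dwell ~67 down to ~25 TR), giving a stationary occupancy that decreases
  with state index — state 1 the most frequent, state 5 the least. Window
  ground truth is the majority state over each window's TRs (ties go to the
  state appearing first in the window), because the analysis clusters
  windows, not TRs.
* **State centroids**: network-block correlation matrices over the default
  8-network assignment (DMN 10, VIS 8, SMN 8, FPN 7, dATT 6, vATT 4, CB 3,
  BG 1 components). State 1 is globally hypo-connected, state 5 globally
  hyper-connected, and states 2–4 carry disjoint network signatures
  (sensory, default-mode/frontoparietal, attention) of similar total
  weight. The signature strengths are chosen so that the states are
  approximately equidistant in L1 and separable at window length 22 —
  within-window estimation noise is ~0.23 per Fisher-Z pair, so weaker
  signatures make the generative k structurally unrecoverable and the
  model-selection problem ill-posed. The design goal is testability of the
  recovery machinery, not biological realism of effect sizes. Matrices are
  repaired to positive semidefiniteness by eigenvalue clipping at zero and
  re-normalisation to unit diagonal; sampling uses an eigen square-root
  factor, valid for semidefinite matrices.
* **Group effect**: the mild-disability group's transition diagonal for
  state 5 is raised (default +0.02), increasing its state-5 dwell and
  fraction time; the power analysis (`kw_dunn_power`) uses +0.04 as a
  large shift.
* **Clinical tables**: per-domain standardised mean differences between the
  EDSS subgroups (defaults on the order of 0.5–1.5, largest for fatigue,
  matching the magnitude ordering of the reference cohort), EDSS drawn on
  the 0.5 grid with a distribution that reproduces the three-group
  percentile split including median-tied (1.5) and unrated patients, age
  older in the higher-EDSS subgroup, and per-test missingness (default
  8%).
* **Seeding**: one master seed fans out to per-participant seeds by a fixed
  offset, so cohorts are reproducible while participants stay independent.

What the generator does **not** emulate: hemodynamic autocorrelation (TR
samples are conditionally independent given the state), scanner drift and
motion artefacts, ICA mixing errors, spatial structure of components, and
between-participant variability in the state centroids themselves. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct under its own assumptions, not that the pipeline is robust to real
acquisition artefacts — the nuisance-prep module exists for real data but
is off by default for synthetic input.

## Numerical choices and degenerate inputs

* Correlations are clipped at `1 - 1e-7` before arctanh.
* Despiking winsorizes beyond 4 robust SDs (1.4826·MAD) of the component
  median; constant series (MAD = 0) pass through unchanged.
* Band-pass is a zero-phase order-4 Butterworth applied forward-backward
  with one-window reflection padding; series are demeaned first, since DC
  lies below the pass band.
* Rank-deficient confound matrices are reduced by dropping dependent
  columns with a warning.
* Occupancy re-coding breaks ties by ascending original cluster id; even-
  count medians use the mean-of-middle rule; unvisited states propagate as
  missing (never zero) and the affected participant drops out of that
  state's tests, so per-test Ns vary.
* Zero-variance inputs raise errors that name the offending component or
  test; two all-constant groups give T = 0, p = 1 in the permutation test.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run entirely on generated data at
desk scale, chosen as the smallest sizes at which each property is
informative: 40 participants × 234 windows for state-count recovery; 27
patients for the correlation-stage enumeration (the 37,835-test count is a
property of the family structure, not of n); 1000 null simulations at 999
permutations for type-I calibration; 200 patients per subgroup (3
replicates) for effect-size recovery; and 50 replicates at 60 participants
per group for the fraction-time power analysis.

## Known limitations

* Sliding-window FC with k-means is one of several state estimators; HMMs,
  eigenvector-centrality dynamics, and whole-brain models are out of scope.
* Dunn's index with min/max linkage is noisy on overlapping window clouds;
  it is used as a convergence check, not as the sole selector.
* Greedy Louvain does not guarantee the global modularity optimum on
  arbitrary graphs; the restart and refinement scheme makes it exact on the
  small-graph fixture battery, and 47-node FC graphs are well within its
  reliable regime.
* The FC estimator is the plain windowed Pearson correlation; no shrinkage
  or penalised-precision variants are provided.
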