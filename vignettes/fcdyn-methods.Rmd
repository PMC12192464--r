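---
title: "fcdyn: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fcdyn: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `fcdyn`, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic validation does and does not establish about real
recordings.

# The estimation problem

Intracranial (SEEG-type) recordings sample tens of channels at 1000 Hz.
Within a short window the signals are approximated as jointly stationary,
and *directed functional connectivity* asks how well each channel's past
predicts each other channel's present. No single statistic answers this
robustly: correlation is blind to direction, lagged prediction is blind
to spectral structure, and parametric spectral measures depend on a model
fit. `fcdyn` therefore computes four complementary measures per window
and fuses them, an ensemble strategy in which the fusion parameters are
learned on simulations with known ground truth.

## Window preprocessing

Every window is linearly detrended and z-scored per channel before any
measure. Slow drifts inflate correlations, and the two spectral measures
are only scale-equivariant after standardization; with it, multiplying
any channel by a positive constant leaves all four measures unchanged
(PDC and COH1 up to refit tolerance). A consequence is that MVAR
coefficients are estimated in standardized coordinates; `mvarCoeffs(model,
units = "original")` maps them back through the stored channel scales
(A\_k = D B\_k D^-1), which is the form that recovers a generator's printed
coefficients exactly.

## The four measures

* **BCorrU**: |Pearson r| per channel pair. Symmetric; zero diagonal.
* **BCorrD**: for each ordered pair, the maximum absolute lagged
  correlation over lags 1..`maxLag` in the direction past(i) to
  present(j); the direction with the larger value wins and the loser is
  set to zero. The source description is a comparison rule, not a
  formula, so the winner-take-all operationalization is this package's
  choice; `maxLag` defaults to 100 ms of samples, generous for
  monosynaptic-scale lags at 1000 Hz.
* **COH1**: coherence from the MVAR cross-spectral density
  S(f) = H Σ H\*; bounded in [0, 1], symmetric.
* **PDC**: column-normalized |Ā(f)|; the normalization over targets makes
  the columns unit vectors (Σ_i π² = 1), so a source's influence is
  ranked relative to everything it sends.

Matrix orientation is **source row → target column** everywhere; PDC's
textbook (i, j) indexing is transposed at the boundary so that no stage
can silently flip direction.

**MVAR estimation** is multichannel least squares. With `order = "auto"`
the order minimizing BIC over 1..`maxOrder` (default 10) is chosen; BIC is
consistent for VAR order selection, and all candidate orders are fit on
the common sample support of the largest order so their likelihoods are
comparable (one Gram matrix is computed and sub-blocks solved per order).
A near-singular Gram matrix triggers a small ridge with a logged
strength. Spectral measures default to the 1–45 Hz band, 64 equispaced
frequencies, aggregated by the mean: the broadest conventional band of
task-related activity and the least-assumption reduction of a spectrum
to one number per edge; band and grid are exposed as parameters.

## Fuzzy fusion and the genetic algorithm

The fused edge weight is a convex combination of logistic memberships,
fused(i,j) = Σ_m α_m σ(k_m (m(i,j) − θ_m)). This realizes
"membership functions + learned fusion weights" in a concrete, monotone,
tunable form: increasing any measure can never decrease the fused score,
undirected measures contribute symmetrically to both directions, and the
12 parameters are a small, well-conditioned search space for the GA.
The GA uses tournament selection (size 3), uniform crossover (rate 0.7),
Gaussian mutation (sd 0.1, rate 0.2), one elite (so the running best
fitness is non-decreasing) and defaults of 50 genomes for 40
generations. Fitness is the mean **AUC** of fused scores against the
ground-truth adjacency across training networks — threshold-free, so no
decision cutoff has to be fixed during tuning. Measure matrices for the
training networks are computed once; the GA only re-fuses them, which is
why tuning costs seconds beyond the simulations themselves.

# The synthetic-session generator

Ground-truth networks draw exactly `round(density · n(n−1))` directed
edges with weights uniform in `weightRange`. The adjacency maps to MVAR
coefficients by placing each edge weight at lag 1 (split evenly across
lags when a higher order is requested) plus a self-decay of 0.5 on the
diagonal — the simplest structure recoverable by all four measures.
Innovations are i.i.d. Gaussian with identity covariance times
`noiseScale²`, so instantaneous correlation never masquerades as a
directed edge. Coefficients are uniformly shrunk until the companion
matrix's spectral radius is ≤ 0.95, guaranteeing stationarity with
margin; 1000 samples of burn-in are discarded per block. Task sessions
concatenate blocks generated from per-task networks, with half-open,
0-based annotations in seconds.

Defaults the study conditions do not pin down were fixed once: density
0.2, weights in [0.3, 0.8], unit noise scale, generator order 1, and
fs = 1000 Hz. An optional 1/f-shaped additive observation noise exists
for realism experiments but is off by default so oracles stay exact.

What the generator does *not* emulate: epileptiform transients and
artifacts, volume conduction / common reference leakage, nonstationarity
within a task block, and band-limited oscillatory structure. Passing
tests therefore demonstrate correctness of the estimation machinery and
recoverability under the stated model — not robustness to every
pathology of clinical recordings.

# Dynamics, task states, classification

Windows are 5 s with 50% overlap (hop 2.5 s), anchored at the session
start. A window fully covered by one annotation takes its task label;
windows straddling a boundary are labelled `"mixed"`, stay in the FCD
matrix (their dynamics are real) but are excluded from clustering
evaluation and supervised learning, since their true label is undefined.
The FCD matrix correlates the **raw fused weights** of the off-diagonal
entries (the diagonal is information-free); binarizing first would
discard the weight information for no testable benefit.

Spectral clustering uses a Gaussian kernel with the median pairwise
distance as bandwidth (a standard self-tuning heuristic), the symmetric
normalized Laplacian, and seed-controlled k-means with 10 restarts on the
leading eigenvectors. BIRCH is implemented as a single-level
clustering-feature tree — points are absorbed into the nearest
subcluster while the merged radius stays under a threshold (a distance
quantile, relaxed until at least k subclusters survive) — followed by
Ward agglomeration of the CF centroids; this preserves BIRCH's
absorb-then-agglomerate architecture at the problem sizes involved
(tens to hundreds of windows). t-SNE is the exact O(W²) algorithm with
perplexity-calibrated bandwidths; the learning rate (25) is sized for
the small window counts embedded here, and a fixed seed makes the layout
reproducible.

Classification uses a 500-tree random forest or an RBF SVM (C = 1,
features z-scored on the training fold only — no leakage). Folds are
stratified by task **and** contiguous in time per class: each class's
windows are cut into K contiguous segments, and training windows whose
time span overlaps a test window are dropped, so overlapping windows
never appear on both sides of a split. Where time-contiguity and
stratification could conflict for interleaved tasks, the
contiguous-segment-per-class rule above is this package's documented
choice. Metrics are computed on predictions concatenated across folds
(per-fold values are also reported; on balanced synthetic data the two
agree closely, which a test asserts).

Two metric conventions deserve a note. The printed balanced-accuracy
formula in the source describes precision-like terms with an undefined
symbol; `fcdyn` implements the standard balanced accuracy
(macro-averaged recall), matching the scikit-learn metric the formula
names. And because "accuracy" of an unsupervised clustering requires
aligning cluster ids to classes, `fcdyn` reports both the pair-counting
Rand index and the Hungarian-matched accuracy (the optimal one-to-one
matching is found by exhaustive permutation, exact for the ≤ 8 states
considered). MAE on categorical labels uses the integer encoding in
annotation order and is flagged as encoding-dependent in the output.

# Region profiles and comparisons

Channel FC maps to regions by the **maximum** link weight between region
pairs — the strongest electrode pair defines the inter-region link, and
the mapping is idempotent under channel duplication. Centrality profiles
use seven metrics, all in [0, 1] by construction: weighted in/out degree
normalized by (R−1) (weighted strength rather than binarized link
counts, preserving information; a binarization threshold exists but is
off by default), in/out closeness and betweenness on shortest paths with
lengths 1/weight (stronger link = shorter path, the standard conversion
for weights in (0, 1]), and in/out Katz centrality with α = 0.9/λ_max
and β = 1, the vector rescaled to maximum 1. The printed constraint
"α < (λmax − 1)" in the source is read as α < 1/λ_max — the actual
convergence condition of the Katz series. Closeness on disconnected
graphs counts only reachable counterparts scaled by the reachable
fraction (r/Σd), keeping values in [0, 1]; an unreachable node scores 0.
Where the source lists six metrics with "eigencentrality" in one place
and seven with Katz-in/out in another, the seven-metric set is canonical
here.

Between-task link classification uses the 1-D Wasserstein distance
between per-window weight distributions (area between empirical CDFs).
"Strong" means median ≥ 0.5 and "different" means distance ≥ 0.2 —
declared defaults aligned with the median conventions of the degree
highlights, not recovered constants, and both are exposed as arguments.
Degree highlighting follows the rule table exactly: excluded if both
medians < 0.5; else significant for a task if the one-sided Mann–Whitney
test passes at α = 0.001 (raw p-values by default, matching the stated
procedure; a Bonferroni flag exists); else shared-very-high if both
medians > 0.8, else shared-high. The Mann–Whitney implementation is
exact for m + n ≤ 12 without ties and a tie-corrected normal
approximation otherwise. Group-level pooling concatenates per-window
region metrics across sessions sharing a region label — pooling, not a
mixed-effects model.

# Validation design and problem sizes

Validation is oracle-first: every estimator is checked against an
independent computation — closed-form Ā(f) evaluation for PDC, Welch
cross-spectra for COH1, exhaustive lagged-correlation scans for BCorrD,
brute-force simple-path enumeration for betweenness/closeness, Neumann
series and dense solves for Katz, exhaustive pair enumeration for the
agreement metrics, and the sorted-sample closed form for the Wasserstein
distance. The test suite uses 2–10 node networks at 5–20 k samples;
session-level properties use three-task sessions (10 nodes, 60 s blocks
at 1000 Hz, 5 seeds) and GA tuning uses 10-node (5 train / 5 held-out,
20 k samples) and 30-node (10 k samples) network sets with a reduced GA
population — sizes chosen so the full suite runs on a laptop-class
single core in a couple of minutes while leaving the statistical
assertions comfortably powered.

# Known limitations

* The MVAR family captures linear, stationary interactions; cross-
  frequency coupling and nonlinear dependencies are out of scope.
* The fuzzy rule realized here is a monotone weighted-membership sum;
  richer rule bases (conjunctive rules, per-edge priors) are not
  reproduced.
* The simulator's recoverability results transfer to real SEEG only to
  the extent the stationary-block model holds; electrode coverage,
  reference effects and artifacts are not modelled.
* Group pooling treats windows from different sessions as exchangeable
  within a region; hierarchical modelling is deliberately not attempted.
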