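---
title: "Comparing causality networks in the sensor and source space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing causality networks in the sensor and source space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalspace)
```

## The question the package addresses

Multichannel EEG is recorded at scalp electrodes (the *sensor space*), but
much of modern connectivity analysis is performed on reconstructed cortical
current densities (the *source space*) obtained through a linear inverse
operator such as a standardized minimum-norm estimate. `causalspace`
implements a controlled experiment asking how much of the *network-level*
information in multichannel signals survives that inverse mapping: coupled
dynamical systems with a known directed coupling graph are simulated "in
the sensor space", mapped through a synthetic standardized inverse to
ROI-averaged source signals, and directed causality networks are estimated
in both spaces. Five graph metrics of the binarized networks then quantify
how well the three canonical coupling topologies — random (RAND),
small-world (SW) and hub-dominated scale-free (SCF) — can be discriminated
in each space, with the folded AUROC as the separation index. A companion
workflow applies the same windowed network profiling to synthetic
multichannel epochs containing an epileptiform-discharge-like (ED) segment.

Why a linear mixing should degrade network structure at all is made
explicit by the VAR argument implemented in `transformVar()`: if
$x_t = A x_{t-1} + e_t$ and $y_t = H x_t$ with invertible $H$, then
$y_t = H A H^{-1} y_{t-1} + H e_t$. The mixed process is again VAR(1) and
its lag-connectivity matrix $B = H A H^{-1}$ can have essentially arbitrary
structure — only the eigenvalues of $A$ are invariant. Choosing
$H = Q_A^{-1}$ (the inverse eigenvector matrix) even yields a *diagonal*
$B$: a fully connected system can be mixed into one with no lagged
cross-dependencies at all.

## Ground-truth networks

`generateNetwork()` draws an undirected skeleton of the requested class and
orients every edge in one uniformly random direction (a fair coin;
`bidirectional = TRUE` keeps both). Self-loops are never generated; the
simulators own their self-term conventions.

The class parameters are repository conventions (the defaults of
`defaultNetworkParams()`), chosen once so that the five metrics of the
*true* networks at $K = 20$ separate the three classes at the near-perfect
level the study design is built around, while keeping the mean
in-degree low enough (about two drivers per node) that the couplings
remain individually resolvable by the causality estimators:

* **RAND**: Erdős–Rényi with wiring probability $p = 0.35$;
* **SW**: Watts–Strogatz ring of degree 4 with rewiring probability 0.02
  (strongly clustered, long characteristic path);
* **SCF**: preferential attachment with one edge per new node and
  attachment exponent 3 (a hub-dominated, near-star topology with zero
  clustering).

With these defaults the class-averaged separations are: SWi, mean degree
and degree-SD essentially 1, characteristic path length about 0.99, and
assortativity about 0.88 for the true networks. Denser "equal-expected-degree" variants were rejected during
design: they push the mean in-degree beyond 3, where the mean-field
normalization of the coupled-map system dilutes each individual driver
below what any conditional estimator can resolve, and they collapse the
mean-degree separation between classes. All parameters remain configurable
per call.

## The three simulated systems

* `simulateCHM()` — coupled Hénon maps: node $j$ evolves as
  $x_{j,t} = 1.4 - \big[\tfrac{\sum_i C_{ij} x_{i,t-1}}{\sum_i \Theta(C_{ij})}
  + (1 - \tfrac{\sum_i C_{ij}}{\sum_i \Theta(C_{ij})}) x_{j,t-1}\big]^2 +
  0.3\,x_{j,t-2}$, with coupling strength $C = 0.2$ by convention. A node
  with no drivers is the standard Hénon map (the 0/0 coupling ratio is
  taken as 0). Trajectories beyond $|x| > 10^6$ raise an instability error
  naming the node.
* `simulateCMG()` — coupled Mackey–Glass delay equations
  $\dot x_j = -0.1 x_j + \sum_i C_{ij}\, x_i(t-\Delta)/(1 + x_i(t-\Delta)^{10})$
  with $\Delta = 100$ time units, inter-node coupling $C = 0.1$, sampled
  every 4 time units. Each node carries a self-coupling of 0.2 (the classic
  Mackey–Glass production coefficient), so an uncoupled unit is the
  high-dimensional chaotic Mackey–Glass system; without the self term the
  printed equations would make an isolated node a pure exponential decay.
  The integrator is a fixed-step classical Runge–Kutta (h = 0.1, i.e. 1000
  steps per delay) with the delayed state interpolated by cubic Hermite
  polynomials on the stored grid (method of steps). Accuracy is verified by
  step-halving (RMS change below $10^{-4}$) and against an adaptive DDE
  solver. The initial history is constant per node, drawn from
  $U(0.5, 1.5)$ under the seed.
* `stabilizeVar()` / `simulateVar()` — a VAR(1) whose non-zero
  coefficients start at 0.9 on the (transposed) coupling support and are
  multiplied by 0.95 until the spectral radius drops below 0.95 (margin
  0.05); innovations are i.i.d. standard normal. The shrink factor and
  margin are repository conventions for the "iteratively reduced until
  stationary" rule.

Transients (1000 map iterations, 1000 time units, 500 steps respectively)
are discarded; all simulators are bit-reproducible under their seed.

## The synthetic head model and the standardized inverse

No deposited lead field is available, so `synthesizeHeadModel()` builds an
analytic stand-in: electrodes on the unit sphere at synthetic 10-10
coordinates, voxels on a cubic lattice pruned to a concentric sphere of
radius 0.85, and gains from the truncated Legendre-series solution of a
current dipole in a homogeneous conducting sphere (80 terms; the worst-case
geometric ratio 0.85 leaves a truncation error of order $10^{-6}$). This
model is deliberately simple — a single homogeneous shell, not a
three-layer realistic head — which is the reason the package treats
source-space numbers as *directional* results (sensor vs. source) rather
than as reproductions of any anatomically exact values.

`buildTransform()` solves the weighted minimum-norm problem
$\min_d \|L W d\|$ s.t. $m = G d$, with $W$ the diagonal matrix of
lead-field column norms (depth weighting), giving
$T = M^{-1} G^\top (G M^{-1} G^\top)^{+}$ with $M = W L^\top L W$. Each
voxel estimate is standardized by the 3×3 diagonal block of the model
covariance of $d^* = Tm$ under the prior matched to the weighted norm,
$d \sim N(0, M^{-1})$, i.e. $S = T (G M^{-1} G^\top) T^\top$; the reported
source scalar is the quadratic form $d_i^{*\top} S_{ii}^{-1} d_i^*$, a
non-negative standardized power.

Two design points deserve emphasis:

* **Smoothing operator.** With the default `smoothing = "none"` ($L = I$)
  the weighting matrix is diagonal and cancels exactly in the standardized
  quadratic form; one can show (a Schur-complement argument on the PSD
  matrix $G^\top (G M^{-1} G^\top)^{+} G$) that the power argmax for a
  noiseless single dipole is then *exactly* the true voxel — the defining
  zero-localization-error property of the standardized inverse, verified in
  the tests over random dipoles. With `smoothing = "laplacian"` (the
  6-neighbour lattice operator $I - \mathrm{Adj}/6$ per component, the
  smoothness-seeking low-resolution variant) the weighting no longer
  cancels and exact localization provably fails; that variant is validated
  against a Lagrange-multiplier (KKT) oracle instead and kept as an option.
  The default is the variant that has the property the standardized method
  is named for.
* **Standardization covariance.** Using the norm-matched prior covariance
  (rather than an identity-prior covariance $T G G^\top T^\top$, or the
  asymmetric resolution matrix $TG$) is what makes $S$ symmetric positive
  definite, the powers non-negative, and the localization exact. The 3×3
  blocks are ridge-regularized by $10^{-12}$ of their trace before
  inversion.

`partitionRois()` assigns each voxel to its nearest electrode ("all
nearest voxels"; ties to the lowest electrode index) and
`toSourceSpace()` averages the standardized power over each ROI per time
point, yielding one source channel per electrode with unchanged length.
The source series are non-negative spiky power profiles — visibly less
oscillatory than the sensor series, as expected for a quadratic transform.

## Causality measures

**RCGCI** (`rcgci()`): a restricted conditional Granger causality index on
a sparse VAR. Terms are selected per target by `mbtsSelect()`: candidates
are all lagged channels up to `pmax` (default 5), ordered backward in time
(lag 1 of every channel first); at each round the candidate whose inclusion
lowers the BIC most is added, until no candidate lowers it. For each driver
X with selected lags, the index is $\log(s_R^2 / s_U^2)$ with the
restricted model refitted without X's lags; residual variances are
maximum-likelihood (RSS/n), so nesting makes the index non-negative, and it
is exactly zero when the U-model contains no lag of X.

**PMIME** (`pmime()`): the partial mutual information from mixed
embedding. Per target, `mixedEmbedding()` greedily selects lagged variables
(candidate lags 1..`Lmax`, default 5, for the maps and the VAR; for the
subsampled Mackey–Glass the candidate set is {1, 2, 3, 24, 25, 26}, since
the coupling delay of 100 time units is 25 sampling steps and candidates
that stop short of the delay cannot see the couplings at all) by maximal
MI / conditional MI with the target's next value,
estimated by the Kraskov–Stögbauer–Grassberger k-nearest-neighbour
estimator (k = 5, maximum norm) on rank-uniformized data. The measure for
driver X is $I(y_{t+1}; w^x \mid w^y, w^z) / I(y_{t+1}; \mathbf w)$,
clipped to $[0, 1]$, zero exactly when no lag of X was selected.

Termination of the embedding search:

* the first term must beat a *family-wise* time-shift randomization test:
  the observed statistic is a maximum over all candidates, so each
  surrogate draw is the maximum MI over the identically time-shifted
  candidates. With the default 19 surrogates this is an exact rank test at
  level 1/20 = 0.05 — an independent target yields an empty embedding with
  probability about 0.95. The gate (its statistic and all null draws) runs
  on a 96-point subsample: the test keeps its exact level, its
  any-dependence decision needs little data, and the full max-statistic
  null would otherwise dominate the runtime;
* each later term (default `stopping = "surrogate"`) must beat 19
  per-candidate time-shift surrogates of its conditional MI, again an
  exact level-0.05 rank test with sequential early stopping;
* `stopping = "ratio"` instead accepts a term while its conditional gain
  exceeds $(1/A - 1)$ times the accumulated information, $A = 0.97$. The
  accumulated total is the chain-rule sum of accepted gains rather than a
  direct joint estimate, because the direct KSG estimate saturates (and
  even decreases) with dimension, which would terminate embeddings
  spuriously early.

Three numerical conventions keep the estimator affordable at study scale
without touching its definition: term-*selection* scans run on a
systematic thinning of at most 256 time points (which also decorrelates
consecutive samples); the final measure (numerator and denominator of the
ratio) is evaluated on up to 512 points; and the surrogate count is 19
rather than a larger round number because the "observed exceeds all n
surrogates" rank test already has exactly the intended 5% level. All three
are arguments (`selectionPoints`, `measurePoints`, `nSurrogates`) for
full-scale runs. Negative MI/CMI estimates are floored at zero;
embeddings are capped at 10 terms.

## Graph metrics and evaluation

`binarize()` accepts every strictly positive value as an edge (both
measures carry their own significance decision). `computeMetrics()`
symmetrizes (edge iff either direction present) and reports: mean and SD of
the degree distribution; characteristic path length λ as the mean
shortest-path length over *connected* ordered pairs (flagged when less
than half the pairs connect); small-worldness
$SWi = (C/C_{rand}) / (\lambda/\lambda_{rand})$ with C the mean local
clustering coefficient and the reference terms averaged over 20 seeded
random graphs with matched node and edge counts; and degree assortativity
(undefined — NaN, never zero — for regular graphs). Empty graphs yield NaN
metrics, and NaN values are excluded from downstream AUROCs.

`auroc()` is the normalized Mann–Whitney statistic with half-ties, folded
to $\max(A, 1-A)$, so 0.5 means full distributional overlap whichever
group lies higher. `averagePairwiseAuroc()` averages
the three pairwise tasks (RAND/SW, RAND/SCF, SW/SCF). One-way fixed-effects
ANOVA, Welch t-tests of pre-ED vs ED windows, and the Pearson correlation
of true vs estimated metrics complete the evaluation layer.

## The synthetic ED epochs

`generateEdEpoch()` emulates the *statistical* structure of an epoch
containing a spontaneous epileptiform discharge, not its clinical
morphology: 10 s of background from a sparse stationary VAR on a random
coupling graph (wiring probability 0.05), an ED segment of 2–6 s from a
denser (0.15), more strongly coupled graph (stationarity margin 0.02) with
a superposed high-amplitude 3 Hz oscillation (amplitude 4 background SDs,
random per-channel gains), 10 s of background again, cross-faded over
0.1 s. The 3 Hz rate and the amplitude are generator conventions chosen to
mimic a spike-wave-like dominance of the discharge over background; the
generator reproduces the qualitative signatures the windowed analysis
relies on (variance jump, connectivity increase and rising causal degree
during the discharge) but none of the waveform details, artifacts or
patient variability of real recordings — so passing tests certify the
pipeline's behaviour, not clinical validity. `preprocessTS()` provides the
matching preprocessing chain for external recordings (zero-phase
Butterworth band-pass with the low-pass applied before decimation and the
very low high-pass edge applied at the output rate where its biquad is
well conditioned; the whole chain is linear), and `makeWindows()` the 2 s /
0.5 s sliding windows, labelled by majority overlap with ties to the later
period. External multichannel data enter via `readTimeSeries()` (CSV with a
JSON sidecar); channel rejection and reference-free re-referencing of
clinical EEG are out of scope.

## Orchestration, seeds and problem sizes

`runSimulationStudy()` runs one system end to end (network → simulation →
source mapping → causality in both spaces → metrics → AUROC table), with
per-(type, realization) sub-seeds derived order-independently from the
master seed, so cached or resumed runs (`cacheDir`) reproduce the same
numbers byte for byte. `runEpochStudy()` does the windowed variant and
reports per-task AUROCs averaged over epochs plus the t-test listing.

Two presets document the problem sizes used throughout:
`studyPreset("full")` — 50 realizations per type, $N = 2048$, about 1000
voxels — and `studyPreset("desk")` — 10 realizations, $N = 1024$, about
500 voxels. The package's own test suite exercises the desk scale; the
reproduction script runs the linear-system study at the full scale and the
initial-network discrimination at 50 realizations per type.

## Known limitations

* The head model is a homogeneous single sphere with synthetic 10-10
  geometry; source-space results are directional comparisons, not
  anatomical reconstructions.
* PMIME inherits the KSG estimator's dimensionality limits; with dense
  coupling (mean in-degree beyond ~3) individual mean-field-diluted
  drivers fall below its resolution at any realistic series length.
* The characteristic path length of disconnected graphs is averaged over
  connected pairs only; heavily disconnected estimates are flagged rather
  than dropped.
* The ED generator makes no attempt at clinical realism (morphology,
  artifacts, inter-subject variability); real-data conclusions require
  real data.
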