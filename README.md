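# causalspace

Directed causality networks estimated from multichannel time series look
different in the *sensor space* (the recorded channels) and in the *source
space* reached through a linear inverse operator — and the difference is
not cosmetic: a linear mixing `y = Hx` of a VAR(1) process `x_t = A x_{t-1}
+ e_t` is again a VAR(1) with coefficient matrix `B = H A H^{-1}`, so only
the eigenvalues of the connectivity survive, and a suitable `H` can erase
every lagged cross-dependency. `causalspace` turns that observation into a
tested simulation pipeline for the question neuroscientists actually care
about: **how much of the network-level discriminative information in
multichannel EEG-like signals survives a standardized minimum-norm
(sLORETA-style) inverse?**

The package is aimed at methods researchers in network neuroscience and
nonlinear time-series analysis. It provides:

* ground-truth directed coupling networks of three classes — random (RAND),
  small-world (SW) and hub-dominated scale-free (SCF) — at `K = 20` nodes;
* three simulators on those networks: coupled Hénon maps (C = 0.2), coupled
  Mackey–Glass delay systems (Δ = 100, C = 0.1, sampled every 4 time
  units; fixed-step RK4 with Hermite interpolation of the delayed state)
  and a stabilized VAR(1) (coefficients shrunk from 0.9 until the spectral
  radius is below 0.95);
* a synthetic spherical head model (analytic single-shell dipole gains,
  10-10 electrode geometry) with the standardized weighted minimum-norm
  inverse `T = M^{-1} G' (G M^{-1} G')^+`, per-voxel standardized power
  `d_i' S_ii^{-1} d_i` (exactly localizing for noiseless point sources),
  and nearest-electrode ROI averaging back to `K` source channels;
* two directed causality measures with built-in dimension reduction:
  **RCGCI**, the restricted conditional Granger index `log(s_R^2/s_U^2)`
  on a sparse VAR selected by backward-in-time BIC search, and **PMIME**,
  the partial mutual information from mixed embedding,
  `I(y_{t+1}; w^x | w^y, w^z) / I(y_{t+1}; w)`, with
  Kraskov-type k-nearest-neighbour estimates and time-shift surrogate
  termination;
* the five graph metrics of the binarized networks (mean degree, degree
  SD, characteristic path length λ, small-worldness SWi, assortativity r)
  and the folded-AUROC evaluation layer (pairwise network-type
  discrimination, ANOVA, Welch t-tests, true-vs-estimated correlation);
* a synthetic epileptiform-discharge (ED) epoch generator plus the
  windowed (2 s / 0.5 s) network-profiling study for pre-ED / ED / post-ED
  discrimination.

See the methods vignette (`vignettes/causality-sensor-source.Rmd`) for the
model details, parameter conventions and design decisions.

## Worked example

Run a reduced coupled-Hénon study end to end: for each of the three
network classes, 5 realizations are generated, simulated at N = 1024,
mapped through the synthetic standardized inverse (500 voxels), and the
causality networks are estimated with PMIME in both spaces; the table
reports the average pairwise network-type AUROC of each graph metric:

```r
library(causalspace)

st <- runSimulationStudy("CHM", nRealizations = 5, N = 1024,
                         nVoxels = 500, masterSeed = 42)
print(st$auroc, digits = 3)
```

```
    space   SWi degMean degSD lambda     r
1 initial 1.000   1.000 1.000  1.000 0.933
2  sensor 0.987   0.947 0.973  0.867 0.760
3  source 0.708   0.733 0.607  0.628 0.810
```

Reading the table: the three coupling topologies are perfectly separable
from the true networks (`initial` row, AUROC ~1). The networks estimated
from the simulated sensor-space signals retain almost all of that
discriminative information (SWi 0.99, degree SD 0.97). After the
standardized inverse and ROI averaging, the same estimator on the
source-space signals separates the classes far less well (SWi 0.71,
degree SD 0.61): the linear inverse mapping preserves the signals but
rewires the estimated causality network enough to blur the topology
classes — the package's headline, reproducible observation. Per-realization
metric rows are in `st$metrics`.

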