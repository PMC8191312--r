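---
title: "Markov state model analysis of translocation dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state model analysis of translocation dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmhelix)
```

# Scope and model

`msmhelix` implements the analysis stack used to characterize slow
conformational transitions — here motivated by template-base translocation
across the RNA polymerase II bridge helix — as a discrete-time Markov state
model (MSM), together with the structural observables that interpret the
model's states: helix kinking and hydrogen bonding.

The central object is a row-stochastic transition matrix $T(\tau)$ on $k$
microstates, estimated from trajectories discretized at lag $\tau$. Its
assumptions are the usual MSM ones: the discretized dynamics are
approximately Markovian at the chosen lag; the trajectories sample a
stationary, time-reversible process; and the microstate partition resolves
the slow degrees of freedom. The package surfaces each assumption as a
testable diagnostic: implied-timescale flatness across lags, GMRQ
cross-validation for partition quality, and the residence-probability test
for Markovianity at the working lag.

## Stages

1. **Features and tICA.** Input trajectories are real-valued feature
   matrices (for molecular data, atom-pair distances via
   `computePairDistances()`). `fitTICA()` estimates the mean, the
   instantaneous covariance $C_0$ and the symmetrized time-lagged
   covariance $C_\tau$, then solves $C_\tau v = \lambda (C_0 + \epsilon I)
   v$. The symmetrized (reversible) estimator is used so eigenvalues are
   real and bounded by 1; the paper-scale protocol fits tICA on the
   modified-template dataset alone and projects other datasets onto it,
   which `projectTICA()` supports directly. Feature pruning by loading
   magnitude (`pruneFeaturesByLoading()`) keeps the union of the top
   $n_1/n_2/n_3$ features per tIC; ties at the selection rank are all
   retained so the result is order-independent. The manual
   "visually connected projection" judgment used in the original protocol
   is replaced by a numeric diagnostic (`projectionConnectivity()`), not
   an automatic pruner.
2. **Microstates.** `kCenters()` is the greedy farthest-point traversal
   (first center = caller-chosen seed frame, default frame 1), giving the
   classic factor-2 bound on the covering radius and full determinism.
   Assignment ties go to the lowest center index.
3. **MSM.** `countTransitions()` uses sliding-window counting;
   `trimToConnected()` restricts to the largest strongly connected
   component (via igraph) and optionally applies a per-state
   off-diagonal count floor (`minCounts`) — the standard ergodic-trimming
   guard: farthest-point clustering deliberately places centers on
   outlier frames, and a state visited once for a handful of frames
   otherwise masquerades as a slow process. `estimateMarkovModel()`
   defaults to the reversible estimator (symmetrize counts, row-normalize),
   which guarantees a real spectrum, exact detailed balance and
   $\pi \propto$ symmetrized row sums; the non-reversible row-normalized
   estimator is available by flag and reports complex eigenvalue pairs
   with a warning.
4. **Validation.** `gmrqCrossValidate()` splits whole trajectories 1:1
   five times; per split it fits the discretization and MSM on the
   training half and scores
   $\mathrm{tr}[(V^\top C_0 V)^{-1}(V^\top C_\tau V)]$ of the training
   eigenvectors on the test correlation matrices ($m = 5$ eigenvalues by
   default; the protocol source does not state $m$). Test sets missing
   training states are scored on the intersection and flagged.
   `residenceProbabilityTest()` compares $(T^k)_{ii}$ for the 12 most
   populated states at lag multiples $0,1,2$ with the trajectory estimate
   among window-smoothed starts spaced at least one tenth of the lag
   apart (the published 4.5 ns spacing at a 45 ns lag).
5. **Coarse-graining and kinetics.** `macrostateCountByGap()` maximizes
   $\lambda_k/\lambda_{k+1}$; `spectralLump()` embeds microstates in the
   top right eigenvectors and clusters with k-means (fixed seed, 10
   restarts, one retry on an empty cluster). Transition-path theory
   (`committor()`, `reactiveFlux()`, `decomposePathways()`) follows the
   standard formulas with the committor solved linearly and pathways
   extracted by widest-path bottleneck subtraction until 95% of the
   reactive flux is covered. TPT runs at the microstate level and is
   aggregated to macrostates (`aggregateFlux()`); the aggregate-after-micro
   order is the default because the kinetic network is defined on sampled
   structures. MFPTs are reported both ways: the linear solve is the
   ground truth, and the MCMC protocol (10 chains of $10^5$ steps, 20%
   burn-in, chain starts drawn from $\pi$) is primary in reports for
   fidelity to the published procedure.
6. **Structural observables.** `kinkProfile()` fits cylinders
   (Levenberg–Marquardt on $\sum(d_i - r)^2$, initialized from the
   principal axis) to 6-residue windows on both sides of each residue;
   the kink angle is the inter-axis angle and the wobble azimuth the bend
   direction measured from the helix radial vector. The straight/kinked
   classifier applies a strict 35-degree threshold to the maximum kink
   angle. Where the source protocol uses "kink" and "wobble" angle
   interchangeably, this package thresholds the inter-axis (kink) angle.
   `detectHBond()` applies the geometric criterion — donor–acceptor
   distance < 0.35 nm and hydrogen deviation < 30 degrees, both strict.
   Per-macrostate percentages are MSM-weighted through the MCMC protocol
   rather than raw frame counts. The odds ratio
   $(B_s/B_k)/(NB_s/NB_k)$ quantifies kink/H-bond coupling;
   `blockBootstrap()` (contiguous blocks, resampled with replacement to
   the original length) provides intervals that respect temporal
   correlation.

# The synthetic generator as study conditions

No reference trajectories are distributed with the analysis this package
systematizes, so the generator module defines the study conditions under
which everything is validated:

* **Langevin trajectories** (`simulateOverdamped()`): Euler–Maruyama,
  $x \leftarrow x - (D/kT)\,\nabla U\,dt + \sqrt{2D\,dt}\,\xi$. The
  default $dt = 10^{-3}$ keeps the discretization error of a harmonic
  stationary variance ($\approx \kappa D\,dt/2kT$) below 1% for
  curvatures to $\sim 20\,kT$/length². Non-finite gradients abort with
  the offending coordinate.
* **The default landscape** (`makeLandscape("triple-well-2d")`) places
  three Gaussian wells (depths 6.2, 6.9, 6.0 kT, width 0.35) on a bent
  path inside harmonic confinement ($\kappa = 3$), with a 7 kT Gaussian
  hill at the bend center. These constants are documented design choices,
  fixed once: barriers of roughly 3.5–5 kT separate inter-well hopping
  (slowest timescales of order 2–4 time units) from intra-basin
  relaxation (< 0.3), the unequal depths make the middle (midway-state
  analogue) well dominant, and the hill blocks the direct 1→3 corridor so
  the topology is a single unbranching channel — the landscape shape being
  emulated. They were not fitted to any published number.
* **Discrete chains** (`sampleMarkovChain()`), **helices**
  (`makeHelix()`, canonical geometry: rise 1.5 Å, twist 100°, radius
  2.3 Å; kinks rotate the downstream segment rigidly about an axis
  perpendicular to the local helix axis anchored at the kink residue's
  C-alpha, so the requested angle is exact by construction), and
  **H-bond geometries** (`makeHBondGeometry()`, exact round-trip).

What the generator does *not* emulate: molecular force fields, solvent,
anisotropic diffusion, non-equilibrium initial transients beyond what the
Boltzmann-sampled starts remove, helix uncoiling (kinks are rigid
rotations, not partial unwinding), and correlated noise between residues.
Passing tests therefore demonstrate the correctness of the estimators and
operators under controlled conditions, not the adequacy of any particular
molecular model.

# Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| tICA lag | 2 (external) / 0.1 (synthetic) | time units | published protocol value for MD-scale data; diffusive-unit match for the synthetic landscape |
| microstates | 800 / 150 | — | published protocol value; desk-scale equivalent |
| MSM lag | 45 / 0.25 | time units | published protocol value; below the slow timescales but past intra-basin relaxation for the synthetic landscape |
| GMRQ splits | 5 at 1:1 | — | published protocol |
| GMRQ eigenvalues $m$ | 5 | — | unstated in the protocol; top-five covers the slow block |
| residence states / multiples | 12 / 0,1,2 | — | published protocol |
| start spacing | lag/10 | frames | the published 4.5 ns at 45 ns lag |
| MCMC chains | 10 × 10⁵, 20% burn-in | steps | published protocol |
| kink threshold | 35 | degrees | published classifier threshold |
| H-bond criterion | 0.35 / 30 | nm / degrees | standard geometric criterion |
| bootstrap | 1000 resamples, 95% | — | published protocol |
| `minCounts` | 100 (pipeline) | counts | ergodic floor; ~0.05% of frames at the synthetic problem size |

The synthetic-mode pipeline sizes (20 trajectories × 10⁵ steps, stride 10
→ 2 × 10⁵ frames) are the package's canonical demonstration conditions;
they give a few hundred well-to-well hops, enough for populations to
converge to the quadrature weights within the across-trajectory sampling
error the tests use.

# Numerical choices

* **tICA**: default ridge $\epsilon = 10^{-10}\,\mathrm{tr}(C_0)/d$;
  rank-deficient $C_0$ with $\epsilon = 0$ is rejected with instructions.
  Components are sign-fixed (largest-magnitude entry positive).
  Eigenvalues marginally above 1 are clipped after a warning.
* **k-centers**: ties in the farthest-point step and in assignment go to
  the lowest index; determinism is part of the contract.
* **MSM**: rows renormalized after estimation so stochasticity holds to
  1e-12; $\pi T = \pi$ enforced to 1e-10 (non-reversible mode polishes the
  fixed point by power iteration).
* **Gap confidence**: the selected macrostate count is flagged
  low-confidence unless the retained and discarded processes are separated
  in timescale ($t_k / t_{k+1} \ge 2$); eigenvalue *ratios* alone mislead
  in the small-eigenvalue tail of smooth spectra.
* **Residence band**: trajectory-level bootstrap at a simultaneous 95%
  level. Two small-sample corrections are deliberate: (i) the verdict
  aggregates ~24 comparisons (12 states × 2 nonzero multiples), so the
  band quantile is Bonferroni-adjusted to keep the family-wise false-alarm
  rate of the whole report near 5%; (ii) with ~10 trajectories the extreme
  percentiles of the resample distribution saturate at its range, so the
  band pairs the bootstrap SE with a $t_{n-1}$ quantile instead of raw
  percentiles. Pointwise percentile bands would both over-reject globally
  and under-cover in the tails.
* **Cylinder fits**: axis direction parameterized by spherical angles in a
  rotated frame centred on the initial (principal-axis) guess, keeping the
  optimizer away from the pole singularity; the radius is profiled out
  ($r = \bar d$). Axis orientation follows residue order. Collinear point
  sets are rejected.
* **Kink localization**: because the two 6-residue windows share the
  central residue, a constructed kink at residue $r$ is recovered at $r$
  or $r \pm 1$ (the mixed window smears by one residue); tests and
  reports treat ±1 as exact recovery, matching the behaviour of
  window-based kink detectors.
* **Strict inequalities** at all classification boundaries (0.35 nm, 30°,
  35°): boundary cases are measure-zero and the convention is documented
  rather than load-bearing.
* **Pathway extraction** asserts acyclicity implicitly through the
  committor ordering and caps iterations at $10k$ as a safety net against
  numerically degenerate net-flux residues.

# Open design decisions

* **Estimator**: the protocol source never states reversible vs
  non-reversible maximum likelihood. Reversible-by-symmetrization is the
  default because spectral lumping and TPT (with $q^- = 1 - q^+$) require
  a real, detailed-balanced spectrum; this is flagged as a deviation risk
  when comparing against analyses that used a non-reversible estimator.
* **Residence-test propagation** uses the working-lag matrix raised to
  powers (the "propagated twice using the transition probability matrix"
  reading), not re-estimated matrices at longer lags.
* **Macrostate labelling**: populations order macrostates in
  `spectralLump()`; the pipeline relabels them along the first tIC so
  that state 1 → state $n$ reads along the translocation coordinate.
* **Stage caching** by content hash was considered and dropped: at the
  problem sizes the package targets, every stage is seconds, and the GMRQ
  grid already reuses in-memory projections.
* **Command-line interface**: the package functions are the primary
  interface; a thin `run-all` wrapper over a YAML config ships in
  `inst/scripts/run_pipeline.R` for shell use.

# Limitations

* The reversible estimator is biased when the underlying process is
  genuinely irreversible; use `reversible = FALSE` diagnostically.
* MCMC MFPTs average first-passage segments from each entry into the
  source set; for multi-state sources this entry-weighting differs from
  the $\pi$-restricted average of the linear solve (they coincide for
  single-state sources, which is how the cross-validation tests are run).
* TPT at the microstate level counts within-one-lag pass-throughs of an
  intermediate as direct transitions; at lags comparable to an
  intermediate's residence time this inflates direct-pathway flux. The
  default synthetic conditions keep the lag ~10× below the intermediate
  residence time for this reason.
* Kink profiling needs 6-residue windows on both sides, so the first and
  last five residues of a helix carry no angle; hinge maps must stay
  within that support.
* The generator's helices kink rigidly; detectors tuned to partial
  uncoiling would need real structural ensembles.
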