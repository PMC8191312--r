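# msmhelix

Markov state model (MSM) analysis of slow conformational dynamics, with the
structural observables used to study how epigenetic template modifications
such as 5-carboxylcytosine (5caC) pause RNA polymerase II translocation:
bridge-helix kinking and specific hydrogen bonds, quantified through an
MSM-weighted kinetic network.

The package is aimed at computational biophysicists who build MSMs from
molecular simulation data (or want a fully testable, self-contained stack
to prototype against). It implements the complete analysis chain:

1. **Dimensionality reduction** — time-lagged independent component
   analysis (tICA): solve `C_tau v = lambda (C_0 + eps I) v` with
   symmetrized covariance estimators; the top components (tICs)
   approximate the slowest collective motions.
2. **Discretization** — greedy k-centers clustering in tIC space
   (2-approximation on the covering radius) and nearest-center assignment.
3. **MSM estimation** — sliding-window transition counts at lag `tau`,
   strong-connectivity (ergodic) trimming, reversible maximum-likelihood
   estimation via count symmetrization; implied timescales
   `t_k = -tau / ln lambda_k`.
4. **Validation** — GMRQ (generalized matrix Rayleigh quotient)
   cross-validation over hyperparameter grids with 1:1 trajectory splits,
   and the residence-probability test comparing `(T^k)_ii` against
   trajectory-estimated residence with a bootstrap band.
5. **Coarse-graining** — macrostate count from the transition-matrix
   eigenvalue gap; spectral lumping by k-means on the slow eigenvectors.
6. **Kinetics** — transition path theory: committors `q+` by linear solve,
   gross flux `f_ij = pi_i q-_i T_ij q+_j`, net fluxes, bottleneck pathway
   decomposition to 95% coverage, and mean first-passage times both by
   linear solve and by the 10 x 1e5-step MCMC protocol (20% burn-in).
7. **Structural observables** — cylinder-fit per-residue helix kink and
   wobble angles with the 35-degree straight/kinked classifier and hinge
   aggregation; the geometric hydrogen-bond criterion (donor-acceptor
   distance < 0.35 nm, hydrogen deviation < 30 degrees); MSM-weighted
   per-macrostate percentages; the kink/H-bond odds ratio
   `OR = (B_s/B_k)/(NB_s/NB_k)`; tIC shift histograms for perturbation
   (mutant) runs; block-bootstrap confidence intervals.

A first-class synthetic-data module generates every input with known
ground truth — overdamped Langevin trajectories on multi-well landscapes
(Euler-Maruyama), discrete Markov chains from given transition matrices,
ideal and kinked alpha-helix C-alpha ensembles, and hydrogen-bond test
geometries — so the whole pipeline is validated against closed forms,
brute-force enumeration and trapezoid-quadrature Boltzmann oracles.

## Worked example

The default synthetic configuration simulates twenty Langevin trajectories
on a 2D landscape with three metastable wells of unequal depth arranged
along a bent path (the topology of a paused-translocation free-energy
surface), then runs the full analysis:

```r
library(msmhelix)

res <- runPipeline(runConfig("synthetic", seed = 5))
rep <- res$report
rep$nMacro                     # 3
round(100 * rep$macroPopulations, 1)
rep$pathways$sequences[[1]]    # 1 2 3
rep$mfptMCMC[1, 3]
```

Output from this exact run:

```
macrostates: 3
populations: 23.8%, 58.9%, 17.3%
quadrature Boltzmann weights: 20.9%, 61.2%, 17.8%
dominant pathway: 1 -> 2 -> 3 carrying 99.4% of the reactive flux
MFPT state 1 -> 3: 22.1 +/- 0.9 time units (MCMC), 22.1 (linear solve)
slowest implied timescales: 3.77, 2.16
```

The MSM recovers three macrostates whose populations match the independent
quadrature of `exp(-U/kT)` over the landscape within sampling error, the
kinetic network is the designed single unbranching 1 -> 2 -> 3 channel,
and the stochastic (MCMC) first-passage estimate agrees with the exact
linear solve.

Structural observables work the same way on helix ensembles:

```r
kp <- kinkProfile(makeHelix(30, kinks = list(c(15, 40, 60))))
kp
#> KinkProfile: residues 6 - 25 ; max kink 40 deg; kinked (threshold 35)

detectHBond(makeHBondGeometry(0.34, 29))   # TRUE: inside both thresholds
oddsRatio(20, 10, 30, 60)                  # 4
```

A YAML-driven command-line entry point is installed under
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R run-all --config run.yaml`).

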