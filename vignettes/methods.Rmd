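---
title: "Inferring directed networks from single-observable time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed networks from single-observable time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nips)
```

## The inference problem

Consider a network of $N$ coupled dynamical units in which unit $i$ has an
$n$-dimensional state $X_i$, but only one scalar component $x_i(t)$ of that
state can be recorded — an electrode potential, a membrane voltage, the
expression of one clock gene.  The units interact pairwise,

$$\dot X_i = f_i(X_i) + \sum_{j \ne i} H_{ij}(X_i, x_j),$$

with unknown self-dynamics $f_i$ and unknown coupling functions $H_{ij}$
that depend on the *observable* state of the source.  The goal is the
directed adjacency structure: which $H_{ij}$ are nonzero, and how strong
they are.

Classical delay embedding (Takens) reconstructs an autonomous system from
one observable, but a network node is not autonomous — it is forced by its
neighbours.  The key step is to treat the other nodes' observables as a
*known external forcing*.  Delay-embedding theory for forced systems then
guarantees that, generically, the dynamics of $x_i$ can be written over the
node's own delay vector plus the current forcing values:

$$\dot x_i(t) = F_i\big(x_i(t), x_i(t-\tau_i), \ldots,
  x_i(t-(k-1)\tau_i), \; x_1(t), \ldots, x_N(t)\big),$$

with $k \ge 2n+1$ delayed copies.  Only node $i$'s own history needs to be
embedded — not the whole network — which is what makes the method
data-efficient: the number of unknowns grows linearly, not combinatorially,
with $N$.

## The regression model

$F_i$ is approximated additively: a multivariate polynomial of total degree
$r$ in the $k$ delayed observations of node $i$ (the self block), plus one
univariate polynomial of degree $r_1$ — powers $x_j, x_j^2, \ldots,
x_j^{r_1}$, no constant — per candidate source $j$:

$$\dot x_i(t) \approx \sum_{l} \beta_l^{(i)} q_l\big(x_{i,d}(t)\big) +
  \sum_{j \ne i} \sum_{l=1}^{r_1} \alpha_l^{(ij)} x_j(t)^l + \eta_i(t).$$

The unknowns are found by plain least squares, one independent regression
per target node ($\hat Z_i = \arg\min \lVert Y_i - A_i Z_i\rVert_2^2$,
solved through an orthogonal decomposition, never the explicit
normal-equation inverse).  The per-node system has
$\binom{k+r}{r} + (N-1)r_1$ unknowns.  The estimated strength of the edge
$j \to i$ is the squared norm of source $j$'s coefficient block,
$\hat k_{ij} = \sum_l \big(\alpha_l^{(ij)}\big)^2$; ranking the
off-diagonal $\hat k_{ij}$ gives the ROC curve, and an Otsu threshold on
their histogram gives a concrete binary network.

When the coupling acts through *unobservable* state components this
per-node embedding is insufficient, and `nips(..., embedding = "network")`
regresses each $\dot x_i$ on multivariate polynomials in the delay vectors
of **all** nodes (one shared intercept, $N\binom{k+r}{r} - (N-1)$
unknowns).  This is the consistent estimator for hidden-state coupling,
but it is far more data-hungry; see the limitations section for how it
actually behaves at desk-scale data lengths under this package's
benchmark conditions.

Targets $Y_i$ are central differences of the sampled observable in
continuous time, and the next observation $x_i(t+1)$ for discrete-time
(map) dynamics.  Rows are assembled strictly within simulation segments;
independent runs are pooled by stacking rows, never by concatenating time
series across run boundaries.

## Tunable parameters

* **`k` — embedding dimension.**  $2n+1$ suffices for $n$-dimensional
  units; 5 for the two-variable electrochemical and Rulkov units, 7 for
  the three-variable circadian and Roessler units.  Overestimating `k` is
  cheap and safe (the benchmark suite checks the plateau), underestimating
  it is not.
* **`taus` — per-node delay, in samples.**  Selected per node as the first
  strict local minimum of the average mutual information (AMI) between the
  series and its lagged copy; AMI curves are estimated per segment with an
  equal-width 2-D histogram ($\lceil\sqrt{T/5}\rceil$ bins, clamped to
  [8, 32]) and averaged over segments.  For oscillatory signals this lands
  near a quarter period.  In map mode the delay defaults to one step:
  delay coordinates of a map are successive iterates, and the AMI minimum
  (tuned for flows) systematically degrades map-mode inference.
* **`r`, `r1` — truncation orders.**  Defaults per benchmark: (3, 1) for
  electrochemical oscillators, (4, 1) for Rulkov maps, (7, 1) for
  circadian networks, (2, 2) as a robust choice for noisy experimental
  records.  `r` controls the flexibility of the self model; `r1` the
  coupling family (diffusive coupling is linear in $x_j$, so $r_1 = 1$
  is exact for every benchmark here).
* **`ridge`.**  Tikhonov weight, default 0.  We measured ridge
  regularization on the electrochemical benchmark and it *degrades* edge
  ranking at every level tried (the raw-scale monomial columns make the
  penalty act almost entirely on the coupling blocks), so plain least
  squares is both the faithful and the better choice.

## What the synthetic generators emulate

The package ships the four benchmark families as first-class, seeded
simulators.

**Electrochemical oscillators** (`simulate_electrochemical`): the
two-variable dimensionless nickel-electrodissolution model, kinetic
constants from the standard literature lineage (`Ch = 1600`, `a = 0.3`,
`b = 6e-5`, `c = 1e-3`, `Gamma = 0.01`).  The operating point `U = 20`,
`R = 30` was fixed once, at design time, in a moderately anharmonic
relaxation regime (period $\approx 14$ time units, amplitude $\approx 4$):
strongly harmonic regimes make all nodes' signals nearly collinear with
each node's own delay span (unidentifiable), while extreme relaxation
spikes defeat a cubic self model.  Each node draws
$\Gamma_i \sim \Gamma\,(1 \pm 0.15)$, giving the few-percent
natural-frequency dispersion of a real electrode array; without it a
weakly coupled network synchronizes within a couple of cycles and the
coupling signal vanishes from the data.  Edge weights default to
$U[0.007, 0.028]$ — weak coupling, so runs stay desynchronized over the
recorded 5 cycles.  Runs start from uniform random initial conditions
($V \in [-4,-1]$, $\nu \in [0.3, 0.9]$) and are sampled at 100 points per
cycle, the cycle length being measured on an isolated reference node
(which doubles as the oscillation-validity check).

**Rulkov map neurons** (`simulate_rulkov`): the printed two-variable map
with $\beta = 4.2$, $\nu = \sigma = 0.01$ (spiking–bursting regime) and
diffusive coupling in the membrane potential; the cortical surrogate
topology is a 195-node, 214-edge uniform random directed graph with
weights $U[0.02, 0.04]$.

**Circadian clock cells** (`simulate_scn`): a Goodwin-type
transcription–translation loop per cell (mRNA $M$, cytosolic and nuclear
protein), coupling through the transcription rate
$v_{s,i} = 0.73 + \sum_j a_{ij} k_{ij} (M_j - M_i)$.  Only the coupling
offset 0.73 is fixed by the biology here; the remaining constants were
chosen once, by a random search over rate constants, to give a sustained
isolated-cell limit cycle with a 24.3 h period (`scn_params()` validates
20–28 h and a minimum amplitude at every call — a damped spiral whose
numerical ripples look like peaks is explicitly rejected).  Cells start at
random phases *along* the reference limit cycle: uniform random state-box
initial conditions turn out to collapse onto a narrow isochron bundle and
begin life nearly synchronized, which would make every synchronization
experiment vacuous.  Per-cell heterogeneity in the mRNA degradation rate
($\pm 5\%$) spreads the periods by a few hours.  The cell-to-cell coupling
scale that yields locking within a few days is not identifiable from the
biology; `calibrate_scn_coupling()` scans a global weight and reports the
first day the Kuramoto order parameter crosses 0.9 — with the default
constants a uniform weight of about 0.15 locks a 40–50-cell hub network
between days 3 and 6, and that range is the package default.  This
calibration is a documented stand-in, not a claim about SCN physiology.

**Roessler oscillators** (`simulate_rossler`): the standard chaotic
parameter set (0.2, 0.2, 5.7) with diffusive coupling in the observed
first coordinate.

What these generators do **not** emulate: measurement asynchrony across
nodes (all nodes share one clock), coupling delays, time-varying topology,
drift in node parameters over a run, and the amplifier/electrode noise
spectra of real rigs (measurement noise is white Gaussian, added on
request).  Tests passing on these data therefore demonstrate the method's
behaviour under its stated assumptions — they do not certify performance
on recordings that violate them.

## Numerical choices

* **Integration.**  All continuous-time models are advanced by a batched
  fixed-step classical Runge–Kutta scheme — every node of every
  independent run stacked into one state matrix — with 4 sub-steps per
  recorded sample.  The fixed step keeps output bit-reproducible for a
  seed; accuracy is asserted in the suite by step-halving and against
  adaptive `deSolve::lsoda` references (agreement to $\sim 10^{-6}$ over
  several cycles).
* **Derivatives.**  Second-order central differences; endpoints dropped.
  A fourth-order stencil was tried and changes nothing measurable — on
  these benchmarks the residual is dominated by the polynomial truncation
  of the self model, not by differentiation error.
* **Least squares.**  LAPACK QR with a fallback to the SVD-based
  minimum-norm solution when the triangular factor is near singular
  (relative diagonal below $10^{-10}$); ridge solves go through the SVD.
  Underdetermined systems (fewer usable rows than columns, e.g. the
  300-cell circadian network at order 7) produce the minimum-norm solution
  plus a warning; the uniqueness condition
  $M > \binom{k+r}{r} + (N-1) r_1$ is checked on every fit.
* **Degenerate inputs.**  Constant series yield a zero AMI curve with a
  warning; segments too short for the delay window contribute zero rows
  (with a warning) rather than failing the whole fit; simulator divergence
  names the offending run; Otsu thresholding refuses constant score sets.
* **An intrinsic identifiability caveat.**  For noiseless data whose
  dynamics lie *exactly* in the basis span, the forcing itself is
  polynomially reconstructible from the target's own delay history — this
  is the very property delay embedding guarantees — so the regression has
  an exact null direction and the minimum-norm solution concedes a small
  deterministic fraction of each true coupling coefficient to the self
  block.  The exact-recovery test in the suite quantifies this: the
  residual is at machine precision and absent edges score $10^{29}$ times
  lower than present ones, while the recovered strength sits within a few
  percent of the true value.  Realistic (noisy, not exactly representable)
  data do not exhibit the exact degeneracy.

## Benchmark conditions and what the suite runs

The packaged conditions reproduce the benchmark operating points: a
100-node, in-degree-4 electrochemical network recorded for 35 independent
runs of 5 cycles × 100 samples (17,500 samples; truncations of the same
pool give the shorter lengths), inference at $k = 5$, $(r, r_1) = (3, 1)$,
AMI delays; the 195-node Rulkov surrogate at 1,000–6,000 samples in map
mode with $(4, 1)$; logistic and quadratic read-out variants of the
electrochemical scenario; and hidden-node scoring restricted to the
observed sub-network.

Problem sizes in the test suite were chosen so the whole suite runs in
minutes: unit tests use 20–40-node networks with a few runs; the
acceptance-style checks run the full 100-node electrochemical and
195-node Rulkov conditions, and the large-network scaling check runs a
200-node network at 15,000 samples (the same samples-per-node operating
regime as the full 500-node case, which is a long single-point run of the
same code path via `default_scenario("electrochemical", n_nodes = 500)`).
Directional comparisons (network- vs node-embedding under hidden-state
coupling, data-length monotonicity, hidden-node degradation, the
embedding-dimension plateau) run on 12–40-node networks.

One benchmark-conditions caveat is worth stating plainly: the
electrochemical model's published parameter table (and its
coupling-strength distribution) is not available, and under this package's
independently chosen operating point the correlation between inferred and
true coupling strengths at 17,500 samples sits around 0.8–0.86, limited by
synchronization-induced leakage between source columns — the coefficient
noise floor is a few $10^{-3}$ against a weight spread of
$\sim 6\times10^{-3}$.  The edge-*ranking* accuracy (AUROC) at the same
operating point is essentially unaffected.  The weight-recovery
correlation is reported by `run_scenario()` under both the raw
($\hat k_{ij}$) and square-root ($\sqrt{\hat k_{ij}}$, the coefficient
scale) conventions.

## Known limitations

* Fixed topology, instantaneous coupling, time-invariant node dynamics.
* **Whole-network embedding under hidden-state coupling.**  In principle,
  when units couple through unobservable states, embedding every node's
  delay vector (`embedding = "network"`) is the consistent estimator and
  node-by-node embedding is not.  Under this package's benchmark
  conditions the practical picture at desk-scale data lengths is
  different: the per-node fit retains strong *proxy* sensitivity (the
  source's observable carries the hidden state's phase information), while
  the whole-network additive basis — dozens of near-collinear monomial
  columns per source on similar oscillators — leaves each block's
  coefficients so poorly identified that the summed-square edge scores
  stay near chance even with several times more data, despite its
  in-sample residual being uniformly smaller than the node fit's (which we
  verify per node; the basis is a strict superset).  The corresponding
  directional acceptance check is therefore expected to fail under these
  conditions and is retained, failing, as an honest record.
* Derivative-based targets make the continuous-time mode noise-sensitive;
  information-theoretic (derivative-free) methods can win at low
  signal-to-noise.
* Uniform delays only; per-node $\tau_i$ but a single lag spacing.
* The additive decomposition cannot represent coupling functions that
  depend jointly on source and target state beyond what the self block
  absorbs; it ranks such edges well in practice but the recovered
  $\hat k_{ij}$ is then a projection, not the physical gain.
* Basis families beyond raw monomials (Legendre/Chebyshev on scaled
  inputs) span the same function space at these orders and change only the
  conditioning, which the QR/SVD path already handles; they are therefore
  not separately exposed.
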