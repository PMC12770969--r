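# nips — network inference from partial state observations

Reconstructing the wiring of a coupled dynamical network — which unit
drives which — normally requires measuring the *full* state of every unit.
In practice one scalar per unit is all there is: an electrode potential,
one membrane voltage, the expression of a single clock gene.  This package
infers **directed, weighted connectivity from exactly one observable per
node**, for networks of oscillatory or chaotic units coupled through their
observable states.

## Method

Node `i`'s neighbours enter its dynamics only through their observables,
so their influence can be treated as a *known external forcing*.
Delay-embedding theory for forced systems then lets the observable's
dynamics be written over the node's **own** delayed observations plus the
current values of the other observables — no embedding of the whole
network is needed.  The package fits, per node, the additive model

    dx_i/dt  =  Σ_l β_l  q_l( x_i(t), x_i(t-τ_i), …, x_i(t-(k-1)τ_i) )
              + Σ_{j≠i} Σ_{l=1..r1} α_l^{(ij)} x_j(t)^l  +  η_i(t)

by plain least squares: a multivariate polynomial of order `r` in the `k`
delayed copies of the target (with `k ≥ 2n+1` for `n`-dimensional units
and the delay `τ_i` selected per node by the first minimum of the average
mutual information), plus one univariate polynomial of order `r1` per
candidate source.  The estimated strength of the edge `j → i` is
`k̂_ij = Σ_l (α_l^{(ij)})²`; ranking the `k̂_ij` yields a ROC curve against
a known ground truth, and an Otsu threshold on their histogram yields a
concrete binary network.  With `embedding = "network"` the whole network
is embedded instead — `N·C(k+r, r) − (N−1)` unknowns rather than
`C(k+r, r) + (N−1)·r1` — which needs much more data but still works when
units are coupled through *unobservable* states.

The package also ships the benchmark world around the estimator: seeded
generators for directed topologies (fixed in-degree, Erdős–Rényi,
small-world, scale-free, small-world-with-hubs), simulators for four
benchmark dynamics (nickel-electrodissolution oscillators, Rulkov map
neurons, Goodwin-type circadian cells, Rössler oscillators), measurement
noise and static observation functions, hidden-node scenarios, and the
evaluation suite (AUROC, Otsu threshold, weight-recovery correlation,
Kuramoto synchronization index, data-length sweeps).

## Worked example

Forty Rulkov map neurons on a sparse random directed graph, observed only
through their membrane potentials:

```r
library(nips)

net <- random_edge_network(40, 60, seed = 1)            # 40 nodes, 60 edges
net <- assign_weights(net, "uniform", 0.02, 0.04, seed = 2)
ts  <- simulate_rulkov(net, n_steps = 1000, seed = 3)   # observable: u_i(t)

fit <- nips(ts, k = 5, r = 4, r1 = 1, mode = "map")
fit
#> nips fit: 40 nodes, node embedding, map mode
#>   k = 5, r = 4, r1 = 1, delays in [1, 1], ridge = 0
#>   995-995 rows x 165 columns per node; median residual RMS 0.0597

auroc(fit, net)
#> ROC over 60 edges / 1500 non-edges: AUROC = 0.9999
#> Otsu threshold 0.0003464 -> 45 predicted edges
```

The fit object reports, per node, 995 usable regression rows against 165
unknowns (`C(5+4,4) = 126` self-dynamics coefficients plus 39 coupling
coefficients).  The ROC summary says the 60 true edges are ranked above
the 1500 non-edges essentially perfectly (AUROC 0.9999), and Otsu's
threshold on the `k̂_ij` histogram turns that ranking into a concrete
predicted network at this data length.  `weight_recovery(fit, net)` and `plot(fit, net)` give
the weight-correlation and the ROC curve; `summary(fit)`, `coef(fit)`,
`residuals(fit)` and `predict(fit, ts)` behave as for any R model fit.

Higher-level experiment plumbing lives in scenarios:

```r
sc  <- default_scenario("electrochemical")   # 100 nodes, in-degree 4, 15 runs
rep <- run_scenario(sc)                      # simulate -> infer -> score
rep$auroc
#> [1] 0.9041311
```

A thin command-line front end over the same functions is installed at
`inst/cli/nips.R` (`simulate`, `embed-select`, `infer`, `evaluate`,
`scenario`, `sweep` and `config` subcommands).

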