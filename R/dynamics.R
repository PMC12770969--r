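## Benchmark network simulators.
##
## All continuous-time models are integrated with a batched fixed-step
## classical Runge-Kutta scheme: the states of every node in every
## independent run are stacked into matrices (nodes x runs) so one
## integration sweep advances all runs simultaneously.  The step is a fixed
## fraction of the sampling interval (`substeps` sub-steps per recorded
## sample), which keeps the output bit-reproducible for a given seed;
## accuracy under step refinement is asserted by the test suite against
## adaptive solutions from deSolve.

## One RK4 step of size h for a state stored as a list of matrices.
rk4_step <- function(rhs, state, h) {
  k1 <- rhs(state)
  k2 <- rhs(Map(function(s, k) s + h / 2 * k, state, k1))
  k3 <- rhs(Map(function(s, k) s + h / 2 * k, state, k2))
  k4 <- rhs(Map(function(s, k) s + h * k, state, k3))
  Map(function(s, a, b, c, d) s + h / 6 * (a + 2 * b + 2 * c + d),
      state, k1, k2, k3, k4)
}

advance <- function(rhs, state, h, nsub) {
  for (i in seq_len(nsub)) state <- rk4_step(rhs, state, h)
  state
}

check_finite_state <- function(state, sample, model) {
  bad <- !is.finite(state[[1]])
  if (any(bad)) {
    runs <- sort(unique(col(state[[1]])[bad]))
    stop_param("%s simulation diverged at sample %d in run(s) %s",
               model, sample, paste(runs, collapse = ", "))
  }
}

## Peak indices of a numeric vector (strict local maxima).
find_peaks <- function(x) which(diff(sign(diff(x))) == -2) + 1L

# ---------------------------------------------------------------------------
# Electrochemical oscillators (nickel electrodissolution)
# ---------------------------------------------------------------------------

#' Parameters of the dimensionless nickel electrodissolution model
#'
#' Two-variable model of the nickel electrodissolution reaction in sulfuric
#' acid: `V` is the (dimensionless) electrode potential, `nu` the surface
#' coverage of the passivating oxide.  The kinetic constants `Ch`, `a`, `b`,
#' `c` and the coverage time-scale `Gamma` follow the standard literature
#' values for this model family; the circuit potential `U` and series
#' resistance `R` are set in a moderately anharmonic relaxation-oscillation
#' regime (period about 14 time units, amplitude about 4).
#'
#' `gamma_spread` draws a per-node `Gamma_i` uniformly from
#' `Gamma * (1 +/- gamma_spread)`, giving the population a few-percent
#' natural-frequency dispersion like a real electrode array; this
#' heterogeneity is what keeps a weakly coupled network from collapsing onto
#' a fully synchronized orbit within a run.
#'
#' @param U Circuit potential.
#' @param R Series resistance.
#' @param Ch,a,b,c Kinetic constants.
#' @param Gamma Oxide-coverage time-scale.
#' @param gamma_spread Relative half-width of the per-node `Gamma_i` draw.
#' @param gamma_values Optional explicit per-node `Gamma_i` vector; when
#'   supplied it overrides the random draw (useful to keep one network's
#'   heterogeneity fixed while extending its set of simulated runs).
#' @return List of class `electrochem_params`.
#' @export
electrochem_params <- function(U = 20, R = 30, Ch = 1600, a = 0.3,
                               b = 6e-5, c = 1e-3, Gamma = 0.01,
                               gamma_spread = 0.15, gamma_values = NULL) {
  p <- list(U = U, R = R, Ch = Ch, a = a, b = b, c = c, Gamma = Gamma,
            gamma_spread = gamma_spread, gamma_values = gamma_values)
  pos <- c("U", "R", "Ch", "a", "b", "c", "Gamma")
  if (any(!vapply(p[pos], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, TRUE)))
    stop_param("electrochemical parameters must be positive scalars")
  if (gamma_spread < 0 || gamma_spread >= 1)
    stop_param("gamma_spread must be in [0, 1)")
  structure(p, class = "electrochem_params")
}

## RHS of the electrodissolution model for V, nu stored as nodes x runs
## matrices.  gam is the per-node Gamma vector (recycled down columns).
## coupling() returns the additive (dV, dnu) coupling terms.
electrochem_rhs <- function(p, gam, coupling) {
  function(state) {
    V <- state[[1]]; nu <- state[[2]]
    eV <- exp(V); e5 <- exp(0.5 * V); om <- 1 - nu
    cp <- coupling(V, nu)
    dV <- (p$U - V) / p$R -
      (p$Ch * e5 / (1 + p$Ch * eV) + p$a * eV) * om + cp[[1]]
    dnu <- e5 / (gam * (1 + p$Ch * eV)) * om -
      p$b * p$Ch * exp(2 * V) / (gam * (p$c * p$Ch + eV)) * nu + cp[[2]]
    list(dV, dnu)
  }
}

## Simulate one isolated node and return its sampled potential trace.
electrochem_single <- function(p, h, n_steps, V0 = -2, nu0 = 0.5) {
  rhs <- electrochem_rhs(p, p$Gamma,
                         function(V, nu) list(0, 0))
  st <- list(matrix(V0), matrix(nu0))
  out <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    st <- rk4_step(rhs, st, h)
    out[s] <- st[[1]][1, 1]
  }
  out
}

## Validate sustained oscillations of an isolated node and measure the
## period (mean peak-to-peak interval after discarding the transient).
electrochem_period <- function(p, min_peaks = 3L) {
  h <- 0.02
  tr <- electrochem_single(p, h, 20000L)  # 400 time units
  tail_tr <- tr[6667:20000]
  pk <- find_peaks(tail_tr)
  amp <- diff(range(tail_tr))
  if (length(pk) < min_peaks + 1L || amp < 0.01)
    stop_param(paste0("electrochemical parameters are non-oscillatory ",
                      "(found %d peaks, amplitude %.3g)"),
               length(pk), amp)
  mean(diff(pk)) * h
}

#' Simulate a network of electrochemical oscillators
#'
#' Integrates the two-variable electrodissolution model on a weighted
#' directed network and records the electrode potential `V` on a uniform
#' grid of `samples_per_cycle` samples per oscillation cycle for
#' `cycles_per_run` cycles, in `n_runs` independent runs from random initial
#' conditions.  The cycle length is measured on an isolated reference node,
#' which also validates that the chosen parameters oscillate at all.
#'
#' The default `coupling_variant = "observable"` adds
#' `sum_j k_ij a_ij (V_j - V_i)` to the potential equation, i.e. coupling
#' through the observable state.  Variants `"a"`-`"d"` couple through the
#' unobservable coverage difference and/or mix both differences into both
#' equations, the scenario where node-by-node embedding is insufficient and
#' whole-network embedding is required:
#' `"a"`: `Delta-nu` into the `nu` equation; `"b"`: `Delta-nu` into the `V`
#' equation; `"c"`: `Delta-V` into `V` and `Delta-nu` into `nu`;
#' `"d"`: `Delta-nu` into `V` and `Delta-V` into `nu`.
#'
#' @param net A [directed_network()] whose weights are the coupling
#'   strengths `k_ij`.
#' @param params An [electrochem_params()] object.
#' @param n_runs Number of independent runs (segments).
#' @param cycles_per_run,samples_per_cycle Recorded cycles per run and
#'   samples per cycle.
#' @param coupling_variant `"observable"`, or `"a"`-`"d"` (see Details).
#' @param seed RNG seed (initial conditions and per-node heterogeneity).
#' @param substeps Integrator sub-steps per recorded sample.
#' @param period Known oscillation period; when `NULL` it is measured on an
#'   isolated reference node (which also validates the oscillation
#'   precondition).
#' @param return_state Attach the full hidden state as attribute
#'   `"full_state"` (a list with arrays `V` and `nu`).
#' @param init Optional explicit initial conditions: list with `V` and `nu`
#'   matrices (nodes x runs), overriding the random draw.
#' @return A [trajectory_set()] of the recorded potentials.
#' @export
simulate_electrochemical <- function(net, params = electrochem_params(),
                                     n_runs = 35, cycles_per_run = 5,
                                     samples_per_cycle = 100,
                                     coupling_variant = c("observable", "a",
                                                          "b", "c", "d"),
                                     seed = 1L, substeps = 4L,
                                     period = NULL,
                                     return_state = FALSE, init = NULL) {
  stopifnot(inherits(net, "directed_network"),
            inherits(params, "electrochem_params"))
  coupling_variant <- match.arg(coupling_variant)
  n_runs <- check_count(n_runs, "n_runs", 1L)
  cycles_per_run <- check_count(cycles_per_run, "cycles_per_run", 1L)
  samples_per_cycle <- check_count(samples_per_cycle, "samples_per_cycle", 2L)

  period <- period %||% electrochem_period(params,
                                           min_peaks = cycles_per_run)
  dt <- period / samples_per_cycle
  n_samp <- cycles_per_run * samples_per_cycle
  N <- net$n_nodes

  KW <- net$weights * net$adjacency
  rs <- rowSums(KW)
  coupling <- switch(coupling_variant,
    observable = function(V, nu) list(KW %*% V - rs * V, 0),
    a = function(V, nu) list(0, KW %*% nu - rs * nu),
    b = function(V, nu) list(KW %*% nu - rs * nu, 0),
    c = function(V, nu) list(KW %*% V - rs * V, KW %*% nu - rs * nu),
    d = function(V, nu) list(KW %*% nu - rs * nu, KW %*% V - rs * V))

  draws <- with_seed(seed, list(
    gam = params$gamma_values %||%
      (params$Gamma * (1 + stats::runif(N, -params$gamma_spread,
                                        params$gamma_spread))),
    V0 = matrix(stats::runif(N * n_runs, -4, -1), N, n_runs),
    nu0 = matrix(stats::runif(N * n_runs, 0.3, 0.9), N, n_runs)))
  if (length(draws$gam) != N)
    stop_param("gamma_values must have one entry per node")
  if (!is.null(init)) {
    draws$V0 <- matrix(init$V, N, n_runs)
    draws$nu0 <- matrix(init$nu, N, n_runs)
  }

  rhs <- electrochem_rhs(params, draws$gam, coupling)
  h <- dt / substeps
  st <- list(draws$V0, draws$nu0)
  Vout <- array(NA_real_, c(n_samp, N, n_runs))
  nuout <- if (return_state) array(NA_real_, c(n_samp, N, n_runs))
  Vout[1, , ] <- st[[1]]
  if (return_state) nuout[1, , ] <- st[[2]]
  for (s in 2:n_samp) {
    st <- advance(rhs, st, h, substeps)
    check_finite_state(st, s, "electrochemical")
    Vout[s, , ] <- st[[1]]
    if (return_state) nuout[s, , ] <- st[[2]]
  }
  segs <- lapply(seq_len(n_runs), function(r) Vout[, , r])
  ts <- trajectory_set(segs, dt = dt, observable_name = "V",
                       model = "electrochemical",
                       params = list(U = params$U, R = params$R,
                                     Ch = params$Ch, a = params$a,
                                     b = params$b, c = params$c,
                                     Gamma = params$Gamma,
                                     gamma_spread = params$gamma_spread,
                                     coupling_variant = coupling_variant,
                                     period = period, seed = seed))
  if (return_state)
    attr(ts, "full_state") <- list(V = Vout, nu = nuout, gamma = draws$gam)
  ts
}

# ---------------------------------------------------------------------------
# Rulkov map neurons
# ---------------------------------------------------------------------------

#' Simulate a network of Rulkov map neurons
#'
#' Iterates the two-variable Rulkov map with diffusive coupling through the
#' membrane potential `u` (the observable state):
#' `u(t+1) = beta / (1 + u(t)^2) + v(t) + sum_j k_ij a_ij (u_j - u_i)`,
#' `v(t+1) = v(t) - nu u(t) - sigma`.
#' With the default constants the isolated map produces spiking-bursting
#' activity.
#'
#' @param net A [directed_network()].
#' @param beta,nu,sigma Map constants.
#' @param n_steps Samples per run.
#' @param seed RNG seed for the initial conditions.
#' @param n_runs Number of independent runs (segments).
#' @return A [trajectory_set()] of membrane potentials with `dt = 1` step;
#'   the recovery variable is attached as `"full_state"` when
#'   `return_state = TRUE`.
#' @param return_state Attach hidden state.
#' @param init Optional explicit initial conditions: list with `u` and `v`.
#' @export
simulate_rulkov <- function(net, beta = 4.2, nu = 0.01, sigma = 0.01,
                            n_steps = 1000, seed = 1L, n_runs = 1L,
                            return_state = FALSE, init = NULL) {
  stopifnot(inherits(net, "directed_network"))
  n_steps <- check_count(n_steps, "n_steps", 2L)
  n_runs <- check_count(n_runs, "n_runs", 1L)
  N <- net$n_nodes
  KW <- net$weights * net$adjacency
  rs <- rowSums(KW)
  ics <- with_seed(seed, list(
    u = matrix(stats::runif(N * n_runs, -2, 2), N, n_runs),
    v = matrix(stats::runif(N * n_runs, -3.5, -2.5), N, n_runs)))
  if (!is.null(init)) {
    ics$u <- matrix(init$u, N, n_runs)
    ics$v <- matrix(init$v, N, n_runs)
  }
  u <- ics$u; v <- ics$v
  U <- array(NA_real_, c(n_steps, N, n_runs))
  Vh <- if (return_state) array(NA_real_, c(n_steps, N, n_runs))
  for (t in seq_len(n_steps)) {
    U[t, , ] <- u
    if (return_state) Vh[t, , ] <- v
    un <- beta / (1 + u^2) + v + KW %*% u - rs * u
    v <- v - nu * u - sigma
    u <- un
    if (any(abs(u) > 1e6))
      stop_param("Rulkov simulation diverged at step %d", t)
  }
  segs <- lapply(seq_len(n_runs), function(r) U[, , r])
  ts <- trajectory_set(segs, dt = 1, observable_name = "u",
                       model = "rulkov",
                       params = list(beta = beta, nu = nu, sigma = sigma,
                                     seed = seed))
  if (return_state) attr(ts, "full_state") <- list(u = U, v = Vh)
  ts
}

# ---------------------------------------------------------------------------
# Circadian clock cells (suprachiasmatic nucleus)
# ---------------------------------------------------------------------------

#' Parameters of the three-variable circadian cell model
#'
#' Goodwin-type transcriptional oscillator for a single clock cell: mRNA
#' `M`, cytosolic protein `Pc` and nuclear protein `Pn`:
#' `M' = vs K1^n / (K1^n + Pn^n) - vm M / (M + Km)`,
#' `Pc' = ks M - vd Pc / (kd + Pc) - k1 Pc + k2 Pn`,
#' `Pn' = k1 Pc - k2 Pn`,
#' with time in hours and Hill coefficient `hill_n`.  Intercellular coupling
#' acts on the transcription rate: `vs_i = vs_base + sum_j a_ij k_ij
#' (M_j - M_i)`.  The defaults give an isolated-cell period close to 24 h;
#' per-cell heterogeneity in the mRNA degradation rate `vm_i` (uniform,
#' relative half-width `vm_spread`) produces the few-hour period dispersion
#' seen in recorded slices.
#'
#' @param vs_base Baseline transcription rate (nM/h).
#' @param K1 Repression threshold (nM).
#' @param hill_n Hill coefficient.
#' @param Km,vm_mean mRNA degradation Michaelis constant and mean rate.
#' @param vm_spread Relative half-width of the per-cell `vm_i` draw.
#' @param ks Translation rate.
#' @param vd,kd Protein degradation rate and Michaelis constant.
#' @param k1,k2 Cytosol/nucleus exchange rates.
#' @return List of class `scn_params`.
#' @export
scn_params <- function(vs_base = 0.73, K1 = 1, hill_n = 4, Km = 0.18,
                       vm_mean = 0.34, vm_spread = 0.05, ks = 0.35,
                       vd = 0.53, kd = 0.18, k1 = 0.30, k2 = 0.20) {
  p <- list(vs_base = vs_base, K1 = K1, hill_n = hill_n, Km = Km,
            vm_mean = vm_mean, vm_spread = vm_spread, ks = ks, vd = vd,
            kd = kd, k1 = k1, k2 = k2)
  if (any(vapply(p, function(v) !is.numeric(v) || v < 0, TRUE)))
    stop_param("circadian parameters must be nonnegative numbers")
  if (hill_n < 1) stop_param("hill_n must be >= 1")
  structure(p, class = "scn_params")
}

scn_rhs <- function(p, vm, KW, rs) {
  Kn <- p$K1^p$hill_n
  function(state) {
    M <- state[[1]]; Pc <- state[[2]]; Pn <- state[[3]]
    vs <- p$vs_base + KW %*% M - rs * M
    dM <- vs * Kn / (Kn + Pn^p$hill_n) - vm * M / (M + p$Km)
    dPc <- p$ks * M - p$vd * Pc / (p$kd + Pc) - p$k1 * Pc + p$k2 * Pn
    dPn <- p$k1 * Pc - p$k2 * Pn
    list(dM, dPc, dPn)
  }
}

## Isolated-cell limit cycle: validates the circadian period (20-28 h) and
## returns one period of reference states, used to seed desynchronized
## initial conditions at random phases along the cycle.
scn_reference_cycle <- function(p) {
  rhs <- scn_rhs(p, p$vm_mean, matrix(0), 0)
  st <- list(matrix(0.1), matrix(0.1), matrix(0.1))
  h <- 0.1
  n <- 4800L  # 480 h
  tr <- matrix(NA_real_, n, 3L)
  for (s in seq_len(n)) {
    st <- rk4_step(rhs, st, h)
    tr[s, ] <- c(st[[1]][1, 1], st[[2]][1, 1], st[[3]][1, 1])
  }
  pk <- find_peaks(tr[1601:n, 1]) + 1600L
  amp <- diff(range(tr[1601:n, 1]))
  if (length(pk) < 3L || amp < 0.05)
    stop_param("circadian parameters are non-oscillatory (amplitude %.3g)",
               amp)
  per <- mean(diff(pk)) * h
  if (per < 20 || per > 28)
    stop_param("isolated-cell period %.1f h outside the 20-28 h window", per)
  cycle <- tr[pk[1]:pk[2], , drop = FALSE]
  list(period = per, cycle = cycle)
}

scn_period <- function(p) scn_reference_cycle(p)$period

#' Simulate a network of coupled circadian clock cells
#'
#' Integrates the three-variable cell model of [scn_params()] on a weighted
#' directed network, with coupling through the mRNA-dependent transcription
#' rate, and records the mRNA level `M` every `sample_minutes` minutes for
#' `days` days.  Cells start desynchronized (random initial conditions).
#'
#' @param net A [directed_network()].
#' @param params An [scn_params()] object (validated to give a circadian
#'   isolated-cell period).
#' @param days Simulated duration in days.
#' @param sample_minutes Sampling interval in minutes.
#' @param seed RNG seed (initial conditions, per-cell `vm_i`).
#' @param substeps Integrator sub-steps per recorded sample.
#' @param return_state Attach the protein states as `"full_state"`.
#' @param init Optional explicit initial conditions: list with `M`, `Pc`,
#'   `Pn`.
#' @return A [trajectory_set()] with `dt` in hours and
#'   `floor(days * 24 * 60 / sample_minutes) + 1` samples per segment.
#' @export
simulate_scn <- function(net, params = scn_params(), days = 8,
                         sample_minutes = 20, seed = 1L, substeps = 4L,
                         return_state = FALSE, init = NULL) {
  stopifnot(inherits(net, "directed_network"),
            inherits(params, "scn_params"))
  N <- net$n_nodes
  dt <- sample_minutes / 60  # hours
  n_samp <- floor(days * 24 * 60 / sample_minutes) + 1L
  KW <- net$weights * net$adjacency
  rs <- rowSums(KW)
  ref <- scn_reference_cycle(params)
  draws <- with_seed(seed, list(
    vm = params$vm_mean * (1 + stats::runif(N, -params$vm_spread,
                                            params$vm_spread)),
    phase = sample.int(nrow(ref$cycle), N, replace = TRUE)))
  ic <- ref$cycle[draws$phase, , drop = FALSE]
  draws$M0 <- matrix(ic[, 1], N, 1)
  draws$Pc0 <- matrix(ic[, 2], N, 1)
  draws$Pn0 <- matrix(ic[, 3], N, 1)
  if (!is.null(init)) {
    draws$M0 <- matrix(init$M, N, 1)
    draws$Pc0 <- matrix(init$Pc, N, 1)
    draws$Pn0 <- matrix(init$Pn, N, 1)
  }
  rhs <- scn_rhs(params, draws$vm, KW, rs)
  st <- list(draws$M0, draws$Pc0, draws$Pn0)
  h <- dt / substeps
  M <- matrix(NA_real_, n_samp, N)
  full <- if (return_state)
    list(Pc = matrix(NA_real_, n_samp, N), Pn = matrix(NA_real_, n_samp, N))
  M[1, ] <- st[[1]]
  if (return_state) {
    full$Pc[1, ] <- st[[2]]; full$Pn[1, ] <- st[[3]]
  }
  for (s in 2:n_samp) {
    st <- advance(rhs, st, h, substeps)
    check_finite_state(st, s, "circadian")
    M[s, ] <- st[[1]]
    if (return_state) {
      full$Pc[s, ] <- st[[2]]; full$Pn[s, ] <- st[[3]]
    }
  }
  ts <- trajectory_set(list(M), dt = dt, observable_name = "M",
                       model = "scn",
                       params = c(unclass(params), list(seed = seed)))
  if (return_state) attr(ts, "full_state") <- c(full, list(vm = draws$vm))
  ts
}

# ---------------------------------------------------------------------------
# Roessler oscillators
# ---------------------------------------------------------------------------

#' Simulate a network of chaotic Roessler oscillators
#'
#' Three-variable Roessler system per node in the standard chaotic regime,
#' with diffusive coupling in the observed first coordinate:
#' `x' = -y - z + sum_j k_ij a_ij (x_j - x_i)`, `y' = x + a y`,
#' `z' = b + z (x - c)`.
#'
#' @param net A [directed_network()].
#' @param params Named list with `a`, `b`, `c` (defaults 0.2, 0.2, 5.7).
#' @param duration Simulated time span.
#' @param dt Sampling interval.
#' @param seed RNG seed for initial conditions.
#' @param n_runs Number of independent runs.
#' @param substeps Integrator sub-steps per sample (default chosen so the
#'   internal step is at most 0.05).
#' @param return_state Attach hidden coordinates as `"full_state"`.
#' @param init Optional explicit initial conditions: list with `x`, `y`,
#'   `z`.
#' @return A [trajectory_set()] of the first coordinates.
#' @export
simulate_rossler <- function(net, params = list(a = 0.2, b = 0.2, c = 5.7),
                             duration = 250, dt = 0.25, seed = 1L,
                             n_runs = 1L,
                             substeps = max(1L, ceiling(dt / 0.05)),
                             return_state = FALSE, init = NULL) {
  stopifnot(inherits(net, "directed_network"))
  n_runs <- check_count(n_runs, "n_runs", 1L)
  N <- net$n_nodes
  n_samp <- floor(duration / dt) + 1L
  if (n_samp < 2L) stop_param("duration too short for the sampling interval")
  KW <- net$weights * net$adjacency
  rs <- rowSums(KW)
  a <- params$a %||% 0.2; b <- params$b %||% 0.2; cc <- params$c %||% 5.7
  rhs <- function(state) {
    x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
    list(-y - z + KW %*% x - rs * x, x + a * y, b + z * (x - cc))
  }
  ics <- with_seed(seed, list(
    x = matrix(stats::runif(N * n_runs, -5, 5), N, n_runs),
    y = matrix(stats::runif(N * n_runs, -5, 5), N, n_runs),
    z = matrix(stats::runif(N * n_runs, 0, 1), N, n_runs)))
  if (!is.null(init)) {
    ics$x <- matrix(init$x, N, n_runs)
    ics$y <- matrix(init$y, N, n_runs)
    ics$z <- matrix(init$z, N, n_runs)
  }
  st <- list(ics$x, ics$y, ics$z)
  h <- dt / substeps
  X <- array(NA_real_, c(n_samp, N, n_runs))
  full <- if (return_state)
    list(y = array(NA_real_, c(n_samp, N, n_runs)),
         z = array(NA_real_, c(n_samp, N, n_runs)))
  X[1, , ] <- st[[1]]
  if (return_state) {
    full$y[1, , ] <- st[[2]]; full$z[1, , ] <- st[[3]]
  }
  for (s in 2:n_samp) {
    st <- advance(rhs, st, h, substeps)
    check_finite_state(st, s, "Roessler")
    X[s, , ] <- st[[1]]
    if (return_state) {
      full$y[s, , ] <- st[[2]]; full$z[s, , ] <- st[[3]]
    }
  }
  segs <- lapply(seq_len(n_runs), function(r) X[, , r])
  ts <- trajectory_set(segs, dt = dt, observable_name = "x",
                       model = "rossler",
                       params = list(a = a, b = b, c = cc, seed = seed))
  if (return_state) attr(ts, "full_state") <- full
  ts
}

#' Calibrate the global circadian coupling strength for realistic synchrony
#'
#' The benchmark requires a population that starts desynchronized and locks
#' within a few days.  This helper scans an ascending grid of uniform
#' coupling weights, simulates each, and returns the first weight whose
#' Kuramoto order parameter first exceeds `sync_threshold` inside
#' `target_window` (in days).  It is a coarse stand-in for a proper
#' calibration of cell-to-cell coupling, which the underlying biology does
#' not pin down.
#'
#' @param net A [directed_network()] (weights are overridden).
#' @param params An [scn_params()] object.
#' @param weight_grid Ascending candidate weights.
#' @param target_window Acceptable first-crossing window in days.
#' @param days,sample_minutes,seed Simulation settings.
#' @param sync_threshold Kuramoto order level defining "synchronized".
#' @return List with `weight`, `crossing_day` and the scanned `crossing`
#'   days (NA where the threshold was never reached); `weight` is NA when
#'   no grid point lands in the window.
#' @export
calibrate_scn_coupling <- function(net, params = scn_params(),
                                   weight_grid = c(0.05, 0.1, 0.15, 0.2,
                                                   0.3),
                                   target_window = c(3, 6), days = 8,
                                   sample_minutes = 30, seed = 1L,
                                   sync_threshold = 0.9) {
  crossing <- rep(NA_real_, length(weight_grid))
  for (g in seq_along(weight_grid)) {
    n2 <- assign_weights(net, "constant", weight_grid[g])
    ts <- simulate_scn(n2, params, days = days,
                       sample_minutes = sample_minutes, seed = seed)
    R <- kuramoto_order(ts, window = 9L)
    hit <- which(R > sync_threshold)[1]
    if (!is.na(hit)) crossing[g] <- (hit - 1) * sample_minutes / 60 / 24
    if (!is.na(crossing[g]) && crossing[g] >= target_window[1] &&
        crossing[g] <= target_window[2])
      return(list(weight = weight_grid[g], crossing_day = crossing[g],
                  crossing = crossing[seq_len(g)]))
  }
  list(weight = NA_real_, crossing_day = NA_real_, crossing = crossing)
}
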