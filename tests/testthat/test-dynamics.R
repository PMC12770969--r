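single_node_net <- function() directed_network(matrix(0, 1, 1))

test_that("the Rulkov map reproduces hand-iterated values", {
  ts <- simulate_rulkov(single_node_net(), n_steps = 3, seed = 1,
                        init = list(u = 0, v = 0), return_state = TRUE)
  u <- ts$segments[[1]][, 1]
  v <- attr(ts, "full_state")$v[, 1, 1]
  expect_equal(u, c(0, 4.2, 4.2 / (1 + 4.2^2) - 0.01), tolerance = 1e-12)
  expect_equal(v, c(0, -0.01, -0.062), tolerance = 1e-12)
})

test_that("simulators are deterministic and decouple on empty networks", {
  net0 <- directed_network(matrix(0, 3, 3))
  ## bit-reproducibility for a fixed seed
  a <- simulate_rulkov(net0, n_steps = 100, seed = 4)
  b <- simulate_rulkov(net0, n_steps = 100, seed = 4)
  expect_identical(a$segments, b$segments)
  expect_false(identical(
    a$segments, simulate_rulkov(net0, n_steps = 100, seed = 5)$segments))
  ## zero coupling: each node equals its own single-node simulation
  V0 <- c(-3, -2, -1.5); nu0 <- c(0.4, 0.5, 0.6)
  pars <- electrochem_params(gamma_values = rep(0.01, 3))
  many <- simulate_electrochemical(net0, pars, n_runs = 1,
                                   cycles_per_run = 2, seed = 1,
                                   init = list(V = V0, nu = nu0))
  for (i in 1:3) {
    one <- simulate_electrochemical(
      single_node_net(), electrochem_params(gamma_values = 0.01),
      n_runs = 1, cycles_per_run = 2, seed = 1,
      init = list(V = V0[i], nu = nu0[i]))
    expect_equal(many$segments[[1]][, i], one$segments[[1]][, 1],
                 tolerance = 1e-12)
  }
  ## identical initial conditions, zero coupling: identical trajectories
  twin <- simulate_rulkov(directed_network(matrix(0, 2, 2)), n_steps = 50,
                          seed = 1, init = list(u = c(0.3, 0.3),
                                                v = c(-3, -3)))
  expect_identical(twin$segments[[1]][, 1], twin$segments[[1]][, 2])
})

test_that("electrochemical runs have the advertised shape and stay bounded", {
  fx <- small_electro()
  expect_length(fx$ts$segments, 8)
  expect_equal(dim(fx$ts$segments[[1]]), c(500, 20))
  expect_true(all(abs(unlist(fx$ts$segments)) < 50))
  ## non-oscillatory parameters are rejected up front
  expect_error(simulate_electrochemical(
    single_node_net(), electrochem_params(U = 30, R = 20), n_runs = 1),
    "non-oscillatory")
})

test_that("integrator output converges under step refinement", {
  net <- assign_weights(fixed_in_degree_network(5, 2, seed = 11),
                        "constant", 0.01)
  pars <- electrochem_params(gamma_values = rep(0.01, 5))
  ic <- list(V = rep(-2, 5), nu = rep(0.5, 5))
  coarse <- simulate_electrochemical(net, pars, n_runs = 1,
                                     cycles_per_run = 2, substeps = 4,
                                     seed = 1, init = ic)
  fine <- simulate_electrochemical(net, pars, n_runs = 1,
                                   cycles_per_run = 2, substeps = 8,
                                   seed = 1, init = ic)
  rel <- max(abs(coarse$segments[[1]] - fine$segments[[1]])) /
    max(abs(fine$segments[[1]]))
  expect_lt(rel, 1e-6)
  ## and against an adaptive reference for a single node
  p <- electrochem_params()
  rhs1 <- nips:::electrochem_rhs(p, p$Gamma, function(V, nu) list(0, 0))
  sol <- deSolve::ode(
    c(V = -2, nu = 0.5), seq(0, 10, by = 0.05),
    function(t, y, q) {
      d <- rhs1(list(matrix(y[1]), matrix(y[2])))
      list(c(d[[1]][1, 1], d[[2]][1, 1]))
    }, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  mine <- nips:::electrochem_single(p, h = 0.05 / 4, n_steps = 800)
  expect_lt(max(abs(mine[seq(4, 800, by = 4)] - sol[-1, "V"])), 1e-5)
})

test_that("circadian cells oscillate with a circadian period and synchronize", {
  per <- nips:::scn_period(scn_params())
  expect_gt(per, 20); expect_lt(per, 28)
  expect_error(nips:::scn_period(scn_params(vm_mean = 2)),
               "non-oscillatory|outside")
  net <- assign_weights(small_world_hub_network(40, 4, 0.1, 2, 8,
                                                seed = 12),
                        "constant", 0.15)
  ts <- simulate_scn(net, days = 8, sample_minutes = 30, seed = 13)
  expect_equal(nrow(ts$segments[[1]]), floor(8 * 24 * 60 / 30) + 1)
  R <- kuramoto_order(ts, window = 9)
  expect_lt(mean(R[5:20], na.rm = TRUE), 0.4)       # desynchronized start
  expect_gt(mean(utils::tail(R[!is.na(R)], 20)), 0.8)  # locked by day 8
  ## zero coupling, identical cells and initial states: identical columns
  net0 <- directed_network(matrix(0, 3, 3))
  tw <- simulate_scn(net0, scn_params(vm_spread = 0), days = 1,
                     sample_minutes = 60, seed = 1,
                     init = list(M = rep(0.4, 3), Pc = rep(0.6, 3),
                                 Pn = rep(0.8, 3)))
  expect_identical(tw$segments[[1]][, 1], tw$segments[[1]][, 3])
})

test_that("Roessler nodes are chaotic and refinement-stable", {
  ## two nearby trajectories diverge exponentially (positive Lyapunov)
  d0 <- 1e-8
  a <- simulate_rossler(single_node_net(), duration = 150, dt = 0.25,
                        seed = 1, init = list(x = 1, y = 1, z = 0.5))
  b <- simulate_rossler(single_node_net(), duration = 150, dt = 0.25,
                        seed = 1, init = list(x = 1 + d0, y = 1, z = 0.5))
  gap <- abs(a$segments[[1]][, 1] - b$segments[[1]][, 1])
  expect_gt(max(gap) / d0, 1e3)
  expect_true(all(abs(a$segments[[1]]) < 100))
  ## step refinement
  f <- simulate_rossler(single_node_net(), duration = 60, dt = 0.25,
                        substeps = 10, seed = 1,
                        init = list(x = 1, y = 1, z = 0.5))
  c5 <- simulate_rossler(single_node_net(), duration = 60, dt = 0.25,
                         substeps = 20, seed = 1,
                         init = list(x = 1, y = 1, z = 0.5))
  ## compare over the first ten cycles (~60 time units is ~10 orbits)
  expect_lt(max(abs(f$segments[[1]][1:120] - c5$segments[[1]][1:120])) /
              max(abs(c5$segments[[1]][1:120])), 1e-4)
})

test_that("divergence is reported with the offending run", {
  net <- assign_weights(fixed_in_degree_network(4, 3, seed = 14),
                        "constant", 50)
  expect_error(simulate_rulkov(net, n_steps = 200, seed = 15), "diverged")
})

test_that("coupling variants add the stated terms", {
  ## variant "b" feeds the coverage difference into the potential equation:
  ## with identical potentials but different coverages, only variants with
  ## a Delta-nu term in dV differ from the uncoupled run at the first step
  net <- directed_network(rbind(c(0, 1), c(0, 0)))
  net <- assign_weights(net, "constant", 0.05)
  pars <- electrochem_params(gamma_values = rep(0.01, 2))
  ic <- list(V = c(-2, -2), nu = c(0.4, 0.8))
  runs <- lapply(c("observable", "a", "b", "c", "d"), function(cv)
    simulate_electrochemical(net, pars, n_runs = 1, cycles_per_run = 1,
                             samples_per_cycle = 2000,
                             coupling_variant = cv,
                             seed = 1, init = ic, return_state = TRUE))
  names(runs) <- c("observable", "a", "b", "c", "d")
  net0 <- directed_network(matrix(0, 2, 2))
  un <- simulate_electrochemical(net0, pars, n_runs = 1,
                                 cycles_per_run = 1,
                                 samples_per_cycle = 2000, seed = 1,
                                 init = ic, return_state = TRUE)
  dev1 <- function(r) abs(r$segments[[1]][2, 1] - un$segments[[1]][2, 1])
  ## initial potentials are equal, coverages are not: Delta-V coupling
  ## starts from zero while Delta-nu coupling acts immediately, so the
  ## variants that feed Delta-nu into the potential equation ("b", "d")
  ## leave the uncoupled trajectory much faster than "observable"/"c"
  expect_gt(dev1(runs$b), 10 * dev1(runs$observable))
  expect_gt(dev1(runs$d), 10 * dev1(runs$observable))
  ## variant "a" touches the potential only through the hidden coverage
  expect_gt(dev1(runs$b), 10 * dev1(runs$a))
  nu_a <- attr(runs$a, "full_state")$nu[, 1, 1]
  nu_o <- attr(un, "full_state")$nu[, 1, 1]
  expect_false(isTRUE(all.equal(nu_a, nu_o)))
})
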