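## Reproducible end-to-end scenarios: topology -> dynamics -> (noise,
## observation function) -> inference -> scoring.  A scenario is a plain
## named list, serializable to YAML, so benchmark conditions live in
## configuration rather than code.

#' Default benchmark scenario for a model
#'
#' Returns the scenario list encoding the package's standard benchmark
#' conditions for one of the simulators; every field can be overridden
#' before passing the list to [run_scenario()] or [samples_to_target()].
#'
#' @param model `"electrochemical"`, `"rulkov"`, `"scn"` or `"rossler"`.
#' @param n_nodes Network size (defaults per model).
#' @return Named list with components `model`, `topology`, `weights`,
#'   `simulation`, `noise_variance`, `observe`, `inference`, `seed`.
#' @export
default_scenario <- function(model = c("electrochemical", "rulkov", "scn",
                                       "rossler"), n_nodes = NULL) {
  model <- match.arg(model)
  switch(model,
    electrochemical = list(
      model = "electrochemical",
      topology = list(kind = "fixed_in_degree",
                      n_nodes = n_nodes %||% 100L, d_in = 4L),
      weights = list(law = "uniform", lo = 0.007, hi = 0.028),
      simulation = list(n_runs = 15L, cycles_per_run = 5L,
                        samples_per_cycle = 100L,
                        coupling_variant = "observable"),
      noise_variance = 0, observe = "identity",
      inference = list(k = 5L, r = 3L, r1 = 1L, mode = "continuous",
                       embedding = "node", ridge = 0),
      seed = 1L),
    rulkov = list(
      model = "rulkov",
      topology = list(kind = "random_edges",
                      n_nodes = n_nodes %||% 195L, n_edges = 214L),
      weights = list(law = "uniform", lo = 0.02, hi = 0.04),
      simulation = list(n_runs = 1L, n_steps = 1000L,
                        beta = 4.2, nu = 0.01, sigma = 0.01),
      noise_variance = 0, observe = "identity",
      inference = list(k = 5L, r = 4L, r1 = 1L, mode = "map",
                       embedding = "node", ridge = 0),
      seed = 1L),
    scn = list(
      model = "scn",
      topology = list(kind = "ws_hub", n_nodes = n_nodes %||% 300L,
                      ring_k = 4L, p_rewire = 0.1, n_hubs = 5L,
                      hub_out_degree = 60L),
      weights = list(law = "uniform", lo = 0.1, hi = 0.2),
      simulation = list(n_runs = 1L, days = 8, sample_minutes = 20),
      noise_variance = 0, observe = "identity",
      inference = list(k = 7L, r = 7L, r1 = 1L, mode = "continuous",
                       embedding = "node", ridge = 0),
      seed = 1L),
    rossler = list(
      model = "rossler",
      topology = list(kind = "fixed_in_degree",
                      n_nodes = n_nodes %||% 30L, d_in = 4L),
      weights = list(law = "uniform", lo = 0.02, hi = 0.08),
      simulation = list(n_runs = 4L, duration = 250, dt = 0.25),
      noise_variance = 0, observe = "identity",
      inference = list(k = 7L, r = 3L, r1 = 1L, mode = "continuous",
                       embedding = "node", ridge = 0),
      seed = 1L))
}

## Build the ground-truth network of a scenario.
scenario_network <- function(scenario, seed) {
  tp <- scenario$topology
  net <- switch(tp$kind,
    fixed_in_degree = fixed_in_degree_network(tp$n_nodes, tp$d_in, seed),
    random_edges = random_edge_network(tp$n_nodes, tp$n_edges, seed),
    ws_hub = small_world_hub_network(tp$n_nodes, tp$ring_k, tp$p_rewire,
                                     tp$n_hubs, tp$hub_out_degree, seed),
    ER = , WS = , BA = standard_topology(tp$kind, tp$n_nodes,
                                         tp[setdiff(names(tp),
                                                    c("kind", "n_nodes"))],
                                         seed),
    stop_param("unknown topology kind '%s'", tp$kind))
  w <- scenario$weights
  assign_weights(net, w$law, w$lo, w$hi %||% w$lo,
                 seed = child_seed(seed, 99L))
}

#' Sparse random directed network with a fixed edge count
#'
#' Exactly `n_edges` directed edges placed uniformly at random among the
#' off-diagonal pairs; a surrogate for sparse anatomical connectomes.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @param seed RNG seed.
#' @export
random_edge_network <- function(n_nodes, n_edges, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes", 2L)
  n_edges <- check_count(n_edges, "n_edges", 0L)
  if (n_edges > n_nodes * (n_nodes - 1L))
    stop_param("too many edges")
  adj <- matrix(0, n_nodes, n_nodes)
  offdiag <- which(diag(n_nodes) == 0)
  adj[with_seed(seed, sample(offdiag, n_edges))] <- 1
  directed_network(adj, topology_label = sprintf("random_%d_edges",
                                                 n_edges))
}

## Simulate `n_runs` runs of a scenario's dynamics on `net`.
scenario_simulate <- function(scenario, net, n_runs, seed, period = NULL,
                              gamma_values = NULL) {
  sm <- scenario$simulation
  ts <- switch(scenario$model,
    electrochemical = {
      pr <- do.call(electrochem_params,
                    c(scenario$params %||% list(),
                      list(gamma_values = gamma_values)))
      simulate_electrochemical(net, pr, n_runs = n_runs,
                               cycles_per_run = sm$cycles_per_run,
                               samples_per_cycle = sm$samples_per_cycle,
                               coupling_variant = sm$coupling_variant %||%
                                 "observable",
                               seed = seed, period = period)
    },
    rulkov = simulate_rulkov(net, beta = sm$beta %||% 4.2,
                             nu = sm$nu %||% 0.01,
                             sigma = sm$sigma %||% 0.01,
                             n_steps = sm$n_steps, seed = seed,
                             n_runs = n_runs),
    scn = simulate_scn(net, do.call(scn_params, scenario$params %||%
                                      list()),
                       days = sm$days, sample_minutes = sm$sample_minutes,
                       seed = seed),
    rossler = simulate_rossler(net, scenario$params %||%
                                 list(a = 0.2, b = 0.2, c = 5.7),
                               duration = sm$duration, dt = sm$dt,
                               seed = seed, n_runs = n_runs),
    stop_param("unknown model '%s'", scenario$model))
  ts <- add_measurement_noise(ts, scenario$noise_variance %||% 0,
                              child_seed(seed, 7L))
  observe(ts, scenario$observe %||% "identity")
}

## Samples contributed by one run of the scenario.
samples_per_run <- function(scenario) {
  sm <- scenario$simulation
  switch(scenario$model,
    electrochemical = sm$cycles_per_run * sm$samples_per_cycle,
    rulkov = sm$n_steps,
    scn = floor(sm$days * 24 * 60 / sm$sample_minutes) + 1L,
    rossler = floor(sm$duration / sm$dt) + 1L)
}

## One replicate of a scenario at a given total sample count, with lazy
## extension of the simulated run pool (used by samples_to_target).
scenario_realization <- function(scenario, seed, cache, n_samples) {
  spr <- samples_per_run(scenario)
  runs_needed <- ceiling(n_samples / spr)
  if (is.null(cache)) {
    net <- scenario_network(scenario, child_seed(seed, 1L))
    cache <- list(net = net, segments = list(), period = NULL,
                  gamma_values = NULL)
    if (scenario$model == "electrochemical") {
      pr <- do.call(electrochem_params, scenario$params %||% list())
      cache$period <- electrochem_period(pr)
      cache$gamma_values <- with_seed(child_seed(seed, 2L),
        pr$Gamma * (1 + stats::runif(net$n_nodes, -pr$gamma_spread,
                                     pr$gamma_spread)))
    }
  }
  have <- length(cache$segments)
  if (runs_needed > have) {
    ts_new <- scenario_simulate(scenario, cache$net, runs_needed - have,
                                child_seed(seed, 100L + have),
                                period = cache$period,
                                gamma_values = cache$gamma_values)
    cache$segments <- c(cache$segments, ts_new$segments)
    cache$dt <- ts_new$dt
    cache$observable_name <- ts_new$observable_name
    cache$model_name <- ts_new$model
  }
  ts <- trajectory_set(cache$segments[seq_len(runs_needed)],
                       dt = cache$dt,
                       observable_name = cache$observable_name,
                       model = cache$model_name)
  inf <- scenario$inference
  fit <- nips(ts, k = inf$k, r = inf$r, r1 = inf$r1, mode = inf$mode,
              embedding = inf$embedding %||% "node",
              taus = inf$taus, ridge = inf$ridge %||% 0)
  cache$auroc <- auroc(fit, cache$net)$auroc
  cache$fit <- fit
  cache
}

#' Run a complete benchmark scenario
#'
#' Builds the ground-truth network, simulates the dynamics, applies
#' measurement noise and the observation function, infers the coupling
#' matrix and scores it.  Identical configurations give identical reports.
#'
#' @param scenario Scenario list, see [default_scenario()].
#' @param out_dir Optional directory; when given, the estimated coupling
#'   matrix (`khat.tsv`), the ground truth edge list (`truth.tsv`), the ROC
#'   curve (`roc.tsv`) and a JSON `report.json` (with the resolved
#'   configuration) are written there.
#' @return Report list: `auroc`, `r_squared_raw`, `r_squared_sqrt`,
#'   `otsu_threshold`, `n_rows`, `n_cols`, `taus`, plus the `fit`,
#'   `network`, `roc` and `trajectories` objects.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  seed <- scenario$seed %||% 1L
  net <- scenario_network(scenario, child_seed(seed, 1L))
  ts <- scenario_simulate(scenario, net,
                          scenario$simulation$n_runs %||% 1L,
                          child_seed(seed, 100L))
  if (!is.null(scenario$hide_fraction) && scenario$hide_fraction > 0) {
    hid <- hide_nodes(net, scenario$hide_fraction, child_seed(seed, 3L))
    ts$segments <- lapply(ts$segments, function(m)
      m[, hid$observed_ids, drop = FALSE])
    ts$node_ids <- hid$observed_ids
    net <- hid$sub_truth
  }
  inf <- scenario$inference
  fit <- nips(ts, k = inf$k, r = inf$r, r1 = inf$r1, mode = inf$mode,
              embedding = inf$embedding %||% "node",
              taus = inf$taus, ridge = inf$ridge %||% 0)
  roc <- auroc(fit, net)
  rep <- list(
    model = scenario$model,
    n_nodes = net$n_nodes,
    n_edges = sum(net$adjacency),
    n_samples = total_samples(ts),
    auroc = roc$auroc,
    otsu_threshold = roc$otsu_threshold,
    r_squared_raw = tryCatch(weight_recovery(fit, net, "raw"),
                             error = function(e) NA_real_),
    r_squared_sqrt = tryCatch(weight_recovery(fit, net, "sqrt"),
                              error = function(e) NA_real_),
    taus = fit$taus,
    n_rows = fit$n_rows,
    n_cols = fit$n_cols,
    seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fit$khat, file.path(out_dir, "khat.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    write_edge_list(net, file.path(out_dir, "truth.tsv"))
    utils::write.table(
      data.frame(threshold = roc$thresholds[-1],
                 fpr = roc$fpr[-1], tpr = roc$tpr[-1]),
      file.path(out_dir, "roc.tsv"), sep = "\t", row.names = FALSE)
    jsonlite::write_json(c(rep, list(config = scenario)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(rep, list(fit = fit, network = net, roc = roc, trajectories = ts))
}

#' Read / write a scenario as YAML
#'
#' @param path YAML file.
#' @param scenario Scenario list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  required <- c("model", "topology", "simulation", "inference")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop_param("scenario is missing field(s): %s",
               paste(missing, collapse = ", "))
  sc
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario, path)
  invisible(path)
}
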