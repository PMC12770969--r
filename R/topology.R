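## Ground-truth directed networks for the benchmark scenarios.
##
## Orientation convention used throughout the package: `adjacency[i, j] = 1`
## means there is a directed edge from source node j to target node i, i.e.
## rows index targets and columns index sources.  Coupling weights follow the
## same layout.

#' Construct a directed network object
#'
#' A `directed_network` holds a binary adjacency matrix and a matching
#' nonnegative weight matrix, with rows indexing target nodes and columns
#' indexing source nodes.  Self-loops are excluded.
#'
#' @param adjacency Square binary matrix; `adjacency[i, j] = 1` encodes an
#'   edge from source `j` to target `i`.
#' @param weights Optional nonnegative weight matrix of the same shape.
#'   Defaults to unit weight on every edge.
#' @param topology_label Free-text provenance tag.
#' @return An object of class `directed_network` with fields `n_nodes`,
#'   `adjacency`, `weights` and `topology_label`.
#' @export
directed_network <- function(adjacency, weights = NULL, topology_label = "") {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop_param("adjacency must be square")
  if (!all(adjacency %in% c(0, 1)))
    stop_param("adjacency must be binary")
  if (any(diag(adjacency) != 0))
    stop_param("self-loops are not allowed (diagonal must be zero)")
  if (is.null(weights)) weights <- adjacency * 1.0
  weights <- as.matrix(weights)
  if (!identical(dim(weights), dim(adjacency)))
    stop_param("weights must have the same shape as adjacency")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop_param("weights must be finite and nonnegative")
  if (any(weights > 0 & adjacency == 0))
    stop_param("positive weight on a non-edge")
  storage.mode(adjacency) <- "double"
  structure(
    list(n_nodes = n, adjacency = adjacency, weights = weights * adjacency,
         topology_label = as.character(topology_label)),
    class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges%s\n", x$n_nodes,
              sum(x$adjacency),
              if (nzchar(x$topology_label)) paste0(" [", x$topology_label, "]")
              else ""))
  invisible(x)
}

#' Random directed network with fixed in-degree
#'
#' Every node receives exactly `d_in` incoming edges whose sources are drawn
#' uniformly without replacement from the other nodes.
#'
#' @param n_nodes Number of nodes.
#' @param d_in In-degree of every node; must not exceed `n_nodes - 1`.
#' @param seed RNG seed.
#' @return A [directed_network()] with unit edge weights.
#' @export
fixed_in_degree_network <- function(n_nodes, d_in, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes", 1L)
  d_in <- check_count(d_in, "d_in", 0L)
  if (d_in > n_nodes - 1L)
    stop_param("d_in must be <= n_nodes - 1")
  adj <- matrix(0, n_nodes, n_nodes)
  with_seed(seed, {
    for (i in seq_len(n_nodes)) {
      src <- sample((seq_len(n_nodes))[-i], d_in)
      adj[i, src] <- 1
    }
  })
  directed_network(adj, topology_label = sprintf("fixed_in_degree_%d", d_in))
}

## Turn an undirected igraph into the package's directed convention: each
## undirected edge becomes two directed edges, then each direction is
## independently dropped with probability `drop_direction_prob` (kept only if
## the reverse survives, so no edge disappears entirely unless both are
## dropped).
directionalize <- function(g, drop_direction_prob = 0) {
  und <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  und <- (und + t(und)) > 0
  diag(und) <- FALSE
  adj <- und * 1.0
  if (drop_direction_prob > 0) {
    drop <- matrix(stats::runif(length(adj)) < drop_direction_prob,
                   nrow(adj))
    adj[drop] <- 0
  }
  adj
}

#' Standard random-network topologies
#'
#' Generates Erdős–Rényi (`"ER"`), Watts–Strogatz small-world (`"WS"`) or
#' Barabási–Albert scale-free (`"BA"`) networks.  ER networks are generated
#' as directed graphs; the undirected WS and BA generators are
#' directionalized by replacing each undirected edge with two directed edges
#' and optionally dropping each direction independently.
#'
#' @param kind One of `"ER"`, `"WS"`, `"BA"`.
#' @param n_nodes Number of nodes.
#' @param density_params Named list of generator parameters:
#'   ER: `p` (edge probability) or `mean_in_degree`;
#'   WS: `ring_k` (total ring neighbours, even) and `p_rewire`;
#'   BA: `m` (edges attached per new node) and optional `power`.
#' @param seed RNG seed.
#' @param drop_direction_prob For WS/BA, probability of dropping each
#'   direction of a directionalized edge (default 0: symmetric).
#' @return A [directed_network()].
#' @export
standard_topology <- function(kind = c("ER", "WS", "BA"), n_nodes,
                              density_params = list(), seed,
                              drop_direction_prob = 0) {
  kind <- match.arg(kind)
  n_nodes <- check_count(n_nodes, "n_nodes", 2L)
  dp <- density_params
  adj <- with_seed(seed, {
    switch(kind,
      ER = {
        p <- dp$p %||% (dp$mean_in_degree %||%
                          stop_param("ER needs 'p' or 'mean_in_degree'"))
        if (!is.null(dp$mean_in_degree) && is.null(dp$p))
          p <- dp$mean_in_degree / (n_nodes - 1)
        g <- igraph::sample_gnp(n_nodes, p, directed = TRUE)
        a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
        diag(a) <- 0
        a * 1.0
      },
      WS = {
        ring_k <- check_count(dp$ring_k %||% stop_param("WS needs 'ring_k'"),
                              "ring_k", 2L)
        p_rewire <- check_prob(dp$p_rewire %||% 0, "p_rewire")
        g <- igraph::sample_smallworld(1, n_nodes, ring_k %/% 2L, p_rewire)
        directionalize(g, drop_direction_prob)
      },
      BA = {
        m <- check_count(dp$m %||% stop_param("BA needs 'm'"), "m", 1L)
        g <- igraph::sample_pa(n_nodes, power = dp$power %||% 1, m = m,
                               directed = FALSE)
        directionalize(g, drop_direction_prob)
      })
  })
  directed_network(adj, topology_label = kind)
}

#' Small-world network with high out-degree hub nodes
#'
#' A Watts–Strogatz backbone (directionalized symmetrically) in which
#' `n_hubs` randomly chosen nodes have their out-degree raised to
#' `hub_out_degree` by adding outgoing edges to uniformly chosen new targets.
#' Mirrors the connectivity reported for the suprachiasmatic nucleus:
#' small-world with a minority of strongly projecting cells.
#'
#' @param n_nodes,ring_k,p_rewire Backbone parameters as in
#'   [standard_topology()].
#' @param n_hubs Number of hub nodes (may be 0 for a plain small world).
#' @param hub_out_degree Target out-degree for each hub.
#' @param seed RNG seed.
#' @return A [directed_network()].
#' @export
small_world_hub_network <- function(n_nodes, ring_k, p_rewire, n_hubs,
                                    hub_out_degree, seed) {
  n_nodes <- check_count(n_nodes, "n_nodes", 3L)
  n_hubs <- check_count(n_hubs, "n_hubs", 0L)
  if (n_hubs >= n_nodes) stop_param("n_hubs must be < n_nodes")
  if (n_hubs > 0L) {
    hub_out_degree <- check_count(hub_out_degree, "hub_out_degree", 1L)
    if (hub_out_degree > n_nodes - 1L)
      stop_param("hub_out_degree must be <= n_nodes - 1")
  }
  base <- standard_topology("WS", n_nodes,
                            list(ring_k = ring_k, p_rewire = p_rewire),
                            seed = child_seed(seed, 1L))
  adj <- base$adjacency
  if (n_hubs > 0L) {
    with_seed(child_seed(seed, 2L), {
      hubs <- sample(n_nodes, n_hubs)
      for (h in hubs) {
        ## out-edges of h live in column h
        missing <- which(adj[, h] == 0 & seq_len(n_nodes) != h)
        need <- hub_out_degree - sum(adj[, h])
        if (need > 0) {
          tgt <- sample(missing, min(need, length(missing)))
          adj[tgt, h] <- 1
        }
      }
    })
  }
  directed_network(adj, topology_label = sprintf("WS_hub_%d", n_hubs))
}

#' Assign coupling weights to the edges of a network
#'
#' @param net A [directed_network()].
#' @param law `"uniform"` draws i.i.d. weights from `[lo, hi]`; `"constant"`
#'   sets every edge weight to `lo`.
#' @param lo,hi Weight bounds, `0 <= lo <= hi`.
#' @param seed RNG seed (used by the uniform law).
#' @return The network with new weights.
#' @export
assign_weights <- function(net, law = c("uniform", "constant"), lo, hi = lo,
                           seed = 1L) {
  stopifnot(inherits(net, "directed_network"))
  law <- match.arg(law)
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || hi < lo)
    stop_param("need 0 <= lo <= hi")
  w <- matrix(0, net$n_nodes, net$n_nodes)
  idx <- which(net$adjacency == 1)
  if (length(idx)) {
    w[idx] <- if (law == "constant") lo else
      with_seed(seed, stats::runif(length(idx), lo, hi))
  }
  directed_network(net$adjacency, w, net$topology_label)
}

#' Restrict a network to a random observed subset of nodes
#'
#' Samples `round(n_nodes * (1 - fraction_hidden))` observed nodes uniformly
#' and returns their identities together with the sub-network induced on
#' them, which is the ground truth against which inference from the observed
#' nodes alone is scored (links involving hidden nodes are not recoverable
#' and are excluded from scoring).
#'
#' @param net A [directed_network()].
#' @param fraction_hidden Fraction of nodes to hide, in `[0, 1)`.
#' @param seed RNG seed.
#' @return List with `observed_ids` (sorted node indices) and `sub_truth`
#'   (the induced [directed_network()]).
#' @export
hide_nodes <- function(net, fraction_hidden, seed) {
  stopifnot(inherits(net, "directed_network"))
  fraction_hidden <- check_prob(fraction_hidden, "fraction_hidden")
  if (fraction_hidden >= 1) stop_param("fraction_hidden must be < 1")
  n_obs <- round(net$n_nodes * (1 - fraction_hidden))
  if (n_obs < 2) stop_param("fewer than 2 observed nodes")
  obs <- if (n_obs == net$n_nodes) seq_len(net$n_nodes) else
    sort(with_seed(seed, sample(net$n_nodes, n_obs)))
  sub <- directed_network(net$adjacency[obs, obs, drop = FALSE],
                          net$weights[obs, obs, drop = FALSE],
                          paste0(net$topology_label, "_observed"))
  list(observed_ids = obs, sub_truth = sub)
}

#' Relabel the nodes of a network by a permutation
#'
#' Node `i` of the input becomes node `perm[i]` of the output; adjacency and
#' weights are permuted consistently.
#'
#' @param net A [directed_network()].
#' @param perm Permutation of `1:n_nodes`.
#' @return The relabelled [directed_network()].
#' @export
permute_network <- function(net, perm) {
  stopifnot(inherits(net, "directed_network"))
  if (!identical(sort(as.integer(perm)), seq_len(net$n_nodes)))
    stop_param("perm must be a permutation of 1:n_nodes")
  inv <- order(perm)
  directed_network(net$adjacency[inv, inv, drop = FALSE],
                   net$weights[inv, inv, drop = FALSE],
                   net$topology_label)
}

#' Write / read a network as a tab-separated edge list
#'
#' The file has header `source\ttarget\tweight` and 0-based integer node
#' ids; the reader restores the exact weights.
#'
#' @param net A [directed_network()].
#' @param path File path.
#' @param n_nodes Node count for the reader (needed because isolated nodes
#'   do not appear in an edge list).
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns a [directed_network()].
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(source = idx[, 2] - 1L, target = idx[, 1] - 1L,
                   weight = net$weights[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_nodes) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!identical(names(df), c("source", "target", "weight")))
    stop_param("edge list must have header 'source\\ttarget\\tweight'")
  n_nodes <- check_count(n_nodes, "n_nodes", 1L)
  adj <- matrix(0, n_nodes, n_nodes)
  w <- matrix(0, n_nodes, n_nodes)
  ii <- cbind(df$target + 1L, df$source + 1L)
  adj[ii] <- 1
  w[ii] <- df$weight
  directed_network(adj, w)
}

#' Write a network's weight matrix as dense delimited text
#'
#' Rows index target nodes, columns source nodes (tab-separated, no header).
#'
#' @param net A [directed_network()].
#' @param path File path.
#' @export
write_network_matrix <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  utils::write.table(format(net$weights, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense weight-matrix file back into a network
#'
#' Counterpart of [write_network_matrix()]; every strictly positive entry
#' is taken as an edge.
#'
#' @param path File path.
#' @export
read_network_matrix <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(w) <- NULL
  directed_network((w > 0) * 1.0, w)
}
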